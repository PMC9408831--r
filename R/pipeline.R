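#' Run the full founder analysis
#'
#' End-to-end inference on a parsed tree: role annotation, founder
#' detection with the f criterion, rho/Saillard dating under the linear
#' clock, the migration-time scan with its peaks, allocation between
#' fixed migration epochs, source-region attribution, region-by-epoch
#' composition and per-population epoch frequencies. Everything
#' downstream of parsing is deterministic.
#'
#' @param tree A `founder_tree` from [parse_tree()].
#' @param source_regions,sink_regions Region labels defining the
#'   hypothetical source and sink (see [annotate_roles()]).
#' @param f Founder diversity criterion (default 1, the f1 criterion).
#' @param clock A [clock_model()].
#' @param grid A [scan_grid()].
#' @param epochs An [epoch_model()].
#' @param weights Founder weighting in the scan, `"size"` or `"equal"`.
#' @return A `founder_analysis` object bundling every stage's result:
#'   `$tree`, `$candidates`, `$clusters`, `$dated`, `$scan`, `$peaks`,
#'   `$allocation`, `$epoch_summary`, `$attribution`, `$composition`,
#'   `$population_frequency`, `$config`.
#' @export
run_founder_analysis <- function(tree, source_regions, sink_regions,
                                 f = 1, clock = clock_model(),
                                 grid = scan_grid(), epochs = epoch_model(),
                                 weights = "size") {
  tree <- annotate_roles(tree, source_regions, sink_regions)
  candidates <- apply_f_criterion(find_founder_nodes(tree), f)
  clusters <- build_clusters(tree, f)
  if (nrow(clusters) == 0) rlang::abort("no founder clusters detected")
  dated <- date_clusters(clusters, clock)
  scan <- aggregate_scan(dated, grid, weights = weights)
  peaks <- find_peaks(scan)
  allocation <- allocate_epochs(dated, epochs, sigma_floor = grid$step)
  epoch_summary <- aggregate_allocation(allocation)
  attribution <- infer_source_region(clusters, tree)
  composition <- epoch_region_composition(attribution, allocation)
  pop_freq <- population_epoch_frequency(tree$metadata, clusters, allocation)
  structure(list(
    tree = tree, candidates = candidates, clusters = clusters,
    dated = dated, scan = scan, peaks = peaks,
    allocation = allocation, epoch_summary = epoch_summary,
    attribution = attribution, composition = composition,
    population_frequency = pop_freq,
    config = list(source_regions = source_regions,
                  sink_regions = sink_regions, f = f,
                  years_per_mutation = clock$years_per_mutation,
                  grid = grid[c("t_min", "t_max", "step")],
                  epoch_times = epochs$times, epoch_labels = epochs$labels,
                  weights = weights)
  ), class = "founder_analysis")
}

#' @export
print.founder_analysis <- function(x, ...) {
  cat("<founder_analysis>\n")
  cat("  sink lineages analysed: ", sum(x$dated$n), " in ",
      nrow(x$dated), " founder clusters (f = ", x$config$f, ")\n", sep = "")
  pk <- utils::head(x$peaks, 3)
  cat("  scan peaks (years): ",
      if (nrow(pk)) paste(pk$time_years, collapse = ", ") else "none", "\n", sep = "")
  es <- x$epoch_summary
  cat("  epoch allocation: ",
      paste(sprintf("%s %.1f%%", es$epoch, 100 * es$proportion), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_founder_analysis
#' @param x,object A `founder_analysis`.
#' @param ... Unused.
#' @export
tidy.founder_analysis <- function(x, ...) {
  out <- dplyr::left_join(dating_table(x$dated),
                          dplyr::select(x$attribution, "founder_id", "region",
                                        "support", "ambiguous"),
                          by = "founder_id")
  dplyr::left_join(out,
                   dplyr::select(tibble::as_tibble(x$allocation), -"n", -"age_years"),
                   by = "founder_id")
}

#' @rdname run_founder_analysis
#' @export
glance.founder_analysis <- function(x, ...) {
  es <- x$epoch_summary
  g <- glance(x$scan)
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_founders = nrow(x$dated),
    n_sink_lineages = sum(x$dated$n),
    n_peaks = g$n_peaks,
    peak1_years = g$peak1_years,
    peak2_years = g$peak2_years,
    !!!stats::setNames(as.list(es$proportion), paste0("prop_", es$epoch))
  )
}

#' @rdname run_founder_analysis
#' @export
autoplot.founder_analysis <- function(object, ...) {
  autoplot(object$scan, ...)
}

#' Run the analysis from files and write every result table
#'
#' File-level front end: reads the Newick tree and metadata TSV, runs
#' [run_founder_analysis()], and writes one TSV per stage plus a JSON
#' manifest (config echo, stage counts, peaks, epoch proportions,
#' package version) sufficient to reproduce the run. On any failure the
#' partially written outputs are removed.
#'
#' @param tree_file Newick file (integer branch lengths).
#' @param metadata_file Metadata TSV.
#' @param out_dir Output directory.
#' @inheritParams run_founder_analysis
#' @return The `founder_analysis` object, invisibly.
#' @export
run_founder_files <- function(tree_file, metadata_file, out_dir,
                              source_regions, sink_regions, f = 1,
                              clock = clock_model(), grid = scan_grid(),
                              epochs = epoch_model(), weights = "size") {
  metadata <- read_sample_metadata(metadata_file)
  tree <- parse_tree(tree_file, metadata)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    rlang::abort(paste0("founder analysis failed: ", conditionMessage(e)),
                 parent = e)
  }
  fa <- tryCatch(
    run_founder_analysis(tree, source_regions, sink_regions, f,
                         clock, grid, epochs, weights),
    error = on_fail
  )
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    written <<- c(written, p)
  }
  tryCatch({
    emit(founder_table(fa$clusters), "founders.tsv")
    emit(dating_table(fa$dated), "dating.tsv")
    emit(tidy(fa$scan), "scan.tsv")
    emit(fa$peaks, "peaks.tsv")
    emit(tibble::as_tibble(fa$allocation), "allocation.tsv")
    emit(fa$epoch_summary, "allocation_summary.tsv")
    emit(fa$attribution, "attribution.tsv")
    emit(fa$composition, "composition.tsv")
    emit(fa$population_frequency, "population_frequency.tsv")
    manifest <- list(
      tree_file = tree_file, metadata_file = metadata_file,
      config = fa$config,
      counts = list(candidates = nrow(fa$candidates),
                    f_passed = sum(fa$candidates$f_passed),
                    founders = nrow(fa$dated),
                    sink_lineages = sum(fa$dated$n)),
      peaks = fa$peaks,
      epoch_proportions = stats::setNames(as.list(fa$epoch_summary$proportion),
                                          fa$epoch_summary$epoch),
      package_version = as.character(utils::packageVersion("founderscan"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = on_fail)
  invisible(fa)
}

#' Simulate a dataset, analyse it, and score the recovery
#'
#' Generates a dataset with [simulate_founder_dataset()], runs the full
#' pipeline on it, and compares the inferred peaks, epoch allocation
#' and region attributions against the simulation's ground truth.
#'
#' @param config A [sim_config()].
#' @param f,clock,grid,weights Passed to [run_founder_analysis()].
#' @param epochs Epoch model; by default the distinct true event times
#'   (oldest first) so the allocation is scored against the truth.
#' @return A `recovery_report` list: `$analysis`, `$truth`, and
#'   `$recovery` with per-epoch peak errors (years), true vs inferred
#'   lineage proportions, and region-attribution accuracy.
#' @export
simulate_and_run <- function(config = sim_config(), f = 1,
                             clock = clock_model(config$years_per_mutation),
                             grid = scan_grid(), epochs = NULL,
                             weights = "size") {
  sim <- simulate_founder_dataset(config)
  tree <- parse_tree(sim$newick, sim$metadata)
  true_times <- sort(unique(sim$truth$true_time_years), decreasing = TRUE)
  if (is.null(epochs)) {
    if (length(true_times) < 2) {
      rlang::abort("need >= 2 distinct true event times for the default epoch model")
    }
    epochs <- epoch_model(true_times, paste0("epoch_", true_times))
  }
  src_regions <- unique(sim$truth$true_region)
  fa <- run_founder_analysis(tree, src_regions, config$sink_region,
                             f = f, clock = clock, grid = grid,
                             epochs = epochs, weights = weights)

  # peak recovery: nearest of the top-k scan peaks to each true time
  top <- utils::head(fa$peaks, length(true_times))
  peak_error <- vapply(true_times, function(t0) {
    if (nrow(top) == 0) return(NA_real_)
    min(abs(top$time_years - t0))
  }, numeric(1))

  # allocation recovery: true lineage share per epoch time
  true_share <- vapply(epochs$times, function(t0) {
    sum(sim$truth$n_sink[sim$truth$true_time_years == t0]) / sum(sim$truth$n_sink)
  }, numeric(1))
  alloc <- fa$epoch_summary

  # region recovery: inferred vs true source region per founder
  cmp <- dplyr::inner_join(
    dplyr::select(fa$attribution, "founder_id", inferred_region = "region"),
    dplyr::select(sim$truth, founder_id = "node_label", "true_region"),
    by = "founder_id"
  )
  region_accuracy <- if (nrow(cmp) > 0) {
    mean(cmp$inferred_region == cmp$true_region)
  } else NA_real_

  structure(list(
    analysis = fa, truth = sim$truth, sim = sim,
    recovery = list(
      true_times = true_times,
      peak_error_years = peak_error,
      epoch = tibble::tibble(epoch = epochs$labels,
                             epoch_years = epochs$times,
                             true_proportion = true_share,
                             inferred_proportion = alloc$proportion,
                             abs_error = abs(true_share - alloc$proportion)),
      region_accuracy = region_accuracy,
      n_founders_true = nrow(sim$truth),
      n_founders_inferred = nrow(fa$dated)
    )
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  r <- x$recovery
  cat("<recovery_report> ", r$n_founders_inferred, "/", r$n_founders_true,
      " founders recovered\n", sep = "")
  cat("  peak errors (y): ",
      paste(sprintf("%s: %g", r$true_times, r$peak_error_years), collapse = ", "),
      "\n", sep = "")
  e <- r$epoch
  cat("  allocation: ",
      paste(sprintf("%s %.1f%% (true %.1f%%)", e$epoch,
                    100 * e$inferred_proportion, 100 * e$true_proportion),
            collapse = ", "), "\n", sep = "")
  cat("  region accuracy: ", sprintf("%.1f%%", 100 * r$region_accuracy), "\n", sep = "")
  invisible(x)
}
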