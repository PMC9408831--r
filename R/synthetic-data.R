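#' Configuration for the synthetic founder-event generator
#'
#' The generator emulates the data structure founder analysis consumes:
#' a source phylogeny with founder events injected at specified times,
#' each sink lineage accumulating Poisson-distributed mutations under
#' the linear clock. Defaults encode a two-episode history — 30
#' founders arriving 500 years ago out of West Africa and 10 arriving
#' 8,000 years ago out of Eastern Africa, 10 sink lineages each — the
#' synthetic counterpart of a recent/Holocene twin-peak scenario.
#'
#' @param seed Integer RNG seed.
#' @param years_per_mutation Linear clock rate (default 2565).
#' @param epochs Data frame with one row per migration episode:
#'   `time_years`, `n_founders`, `sink_samples_per_founder`,
#'   `source_region`. An empty data frame yields a source-only dataset.
#' @param source_depth_years Within-clade time depth of the source
#'   diversity attached to each founder node, in years.
#' @param source_leaves_per_founder Source leaves per founder clade
#'   (>= 2: one identical to the founder haplotype, the rest derived).
#' @param sink_shape `"star"` (sink leaves hang directly off the
#'   founder node) or `"cherry-star"` (half of them paired into
#'   cherries, exercising the general Saillard formula).
#' @param sink_region,sink_population Labels stamped on sink samples.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       years_per_mutation = 2565,
                       epochs = data.frame(
                         time_years = c(500, 8000),
                         n_founders = c(30L, 10L),
                         sink_samples_per_founder = c(10L, 10L),
                         source_region = c("West Africa", "Eastern Africa")
                       ),
                       source_depth_years = 5000,
                       source_leaves_per_founder = 3,
                       sink_shape = c("star", "cherry-star"),
                       sink_region = "Sink",
                       sink_population = "SinkPop") {
  sink_shape <- match.arg(sink_shape)
  epochs <- tibble::as_tibble(epochs)
  if (nrow(epochs) > 0) {
    need <- c("time_years", "n_founders", "sink_samples_per_founder", "source_region")
    miss <- setdiff(need, names(epochs))
    if (length(miss) > 0) {
      rlang::abort(paste0("epochs is missing column(s): ", paste(miss, collapse = ", ")))
    }
    if (any(epochs$n_founders < 1) || any(epochs$sink_samples_per_founder < 1)) {
      rlang::abort("founder and sink sample counts must be positive")
    }
    if (any(epochs$time_years < 0) || any(epochs$time_years > 25000)) {
      rlang::abort("epoch times must lie within [0, 25000] years")
    }
  }
  if (source_leaves_per_founder < 2) {
    rlang::abort("source_leaves_per_founder must be >= 2 (one identical, one derived)")
  }
  if (years_per_mutation <= 0) rlang::abort("years_per_mutation must be positive")
  if (source_depth_years <= 0) rlang::abort("source_depth_years must be positive")
  structure(list(
    seed = as.integer(seed),
    years_per_mutation = years_per_mutation,
    epochs = epochs,
    source_depth_years = source_depth_years,
    source_leaves_per_founder = as.integer(source_leaves_per_founder),
    sink_shape = sink_shape,
    sink_region = sink_region,
    sink_population = sink_population
  ), class = "sim_config")
}

# internal tree representation: list(label, length, children)
sim_node <- function(label, length, children = NULL) {
  list(label = label, length = length, children = children)
}

#' @keywords internal
render_newick <- function(node, root = FALSE) {
  body <- if (is.null(node$children)) {
    node$label
  } else {
    inner <- vapply(node$children, render_newick, character(1))
    paste0("(", paste(inner, collapse = ","), ")", node$label)
  }
  if (root) paste0(body, ";") else paste0(body, ":", node$length)
}

#' @keywords internal
# source clades with a founder node each; no seeding here so the
# two-step and one-step simulation paths share one RNG stream
sim_source_clades <- function(config) {
  ypm <- config$years_per_mutation
  lam_src <- config$source_depth_years / ypm
  plan <- if (nrow(config$epochs) > 0) {
    tidyr::uncount(config$epochs, .data$n_founders, .remove = FALSE)
  } else {
    config$epochs
  }
  n_f <- nrow(plan)
  meta <- list()
  clades <- vector("list", max(n_f, 1))
  if (n_f == 0) {
    # source-only dataset: a small star of source haplotypes
    leaves <- lapply(1:4, function(j) {
      sim_node(sprintf("S000_%d", j), if (j == 1) 0L else max(1L, stats::rpois(1, lam_src)))
    })
    clades <- list(sim_node("F000", 0L, leaves))
    meta[[1]] <- tibble::tibble(
      sample_id = sprintf("S000_%d", 1:4),
      region = "West Africa",
      population = "West Africa pop"
    )
    plan <- tibble::tibble(founder_id = character(0), time_years = numeric(0),
                           source_region = character(0), k = integer(0))
    return(list(clades = clades, plan = plan,
                metadata = dplyr::bind_rows(meta)))
  }
  plan$founder_id <- sprintf("F%03d", seq_len(n_f))
  for (i in seq_len(n_f)) {
    n_src <- config$source_leaves_per_founder
    labs <- sprintf("S%03d_%d", i, seq_len(n_src))
    # one zero-mutation source leaf attests the founder haplotype; the
    # rest carry >= 1 mutation so the f1 criterion holds by construction
    lens <- c(0L, pmax(1L, stats::rpois(n_src - 1, lam_src)))
    leaves <- purrr::map2(labs, lens, sim_node)
    clades[[i]] <- sim_node(plan$founder_id[i], 1L + stats::rpois(1, lam_src), leaves)
    meta[[i]] <- tibble::tibble(
      sample_id = labs,
      region = plan$source_region[i],
      population = paste(plan$source_region[i], "pop")
    )
  }
  list(clades = clades,
       plan = dplyr::select(plan, "founder_id", "time_years",
                            "source_region", k = "sink_samples_per_founder"),
       metadata = dplyr::bind_rows(meta))
}

#' @keywords internal
sim_attach_sinks <- function(source, config) {
  ypm <- config$years_per_mutation
  meta <- list(source$metadata)
  truth <- list()
  clades <- source$clades
  plan <- source$plan
  for (i in seq_len(nrow(plan))) {
    k <- plan$k[i]
    t_years <- plan$time_years[i]
    labs <- sprintf("K%03d_%d", i, seq_len(k))
    if (config$sink_shape == "star") {
      sinks <- purrr::map2(labs, stats::rpois(k, t_years / ypm), sim_node)
    } else {
      # cherry-star: pair up half the leaves; time split between the
      # cherry stem and its tips keeps E[path] = t / ypm
      n_ch <- floor(k / 4)      # cherries built from the first 2*n_ch leaves
      sinks <- list()
      j <- 1
      for (c_i in seq_len(n_ch)) {
        stem <- stats::rpois(1, t_years / (2 * ypm))
        tips <- purrr::map2(labs[j:(j + 1)], stats::rpois(2, t_years / (2 * ypm)), sim_node)
        sinks[[length(sinks) + 1]] <- sim_node("", stem, tips)
        j <- j + 2
      }
      for (jj in j:k) {
        sinks[[length(sinks) + 1]] <- sim_node(labs[jj], stats::rpois(1, t_years / ypm))
      }
    }
    clades[[i]]$children <- c(clades[[i]]$children, sinks)
    meta[[length(meta) + 1]] <- tibble::tibble(
      sample_id = labs, region = config$sink_region,
      population = config$sink_population
    )
    truth[[i]] <- tibble::tibble(
      founder_id = plan$founder_id[i],
      node_label = plan$founder_id[i],
      true_time_years = t_years,
      true_region = plan$source_region[i],
      n_sink = k,
      sink_sample_ids = paste(labs, collapse = ",")
    )
  }
  root <- sim_node("root", 0L, clades)
  structure(list(
    newick = render_newick(root, root = TRUE),
    metadata = dplyr::bind_rows(meta),
    truth = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
      founder_id = character(0), node_label = character(0),
      true_time_years = numeric(0), true_region = character(0),
      n_sink = integer(0), sink_sample_ids = character(0)),
    config = config
  ), class = "founder_sim")
}

#' Simulate a source phylogeny with designated founder nodes
#'
#' Builds a random source tree in which every planned founder node
#' carries one source leaf identical to its haplotype (zero-mutation
#' branch) and at least one derived source branch, so founder detection
#' and the f1 criterion succeed by construction. Branch mutation counts
#' are Poisson in branch duration under the linear clock.
#'
#' @param config A [sim_config()]. Its `seed` is applied.
#' @return A `source_sim` list: `$clades`, founder `$plan`, `$metadata`.
#' @export
simulate_source_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  structure(sim_source_clades(config), class = "source_sim")
}

#' Attach sink subtrees at the planned founder nodes
#'
#' For each planned founder at time `T`, attaches `k` sink lineages
#' whose mutation counts are Poisson with mean `T / years_per_mutation`
#' per lineage, so the cluster's expected rho equals `T` on the clock.
#' Continues the RNG stream of [simulate_source_tree()].
#'
#' @param source A `source_sim` from [simulate_source_tree()].
#' @param config The same [sim_config()].
#' @return A `founder_sim` list: `$newick`, `$metadata`, `$truth`.
#' @export
inject_founders <- function(source, config) {
  stopifnot(inherits(source, "source_sim"), inherits(config, "sim_config"))
  sim_attach_sinks(source, config)
}

#' Simulate a complete founder-analysis dataset
#'
#' One-call wrapper: seeds the RNG, simulates the source tree and
#' injects the planned founder events. Identical config and seed give
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A `founder_sim` list with `$newick` (tree), `$metadata`
#'   (sample table) and `$truth` (per-founder ground truth).
#' @export
simulate_founder_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_attach_sinks(sim_source_clades(config), config)
}

#' @export
print.founder_sim <- function(x, ...) {
  cat("<founder_sim> ", nrow(x$truth), " founder events, ",
      nrow(x$metadata), " samples (seed ", x$config$seed, ")\n", sep = "")
  if (nrow(x$truth) > 0) {
    tab <- table(x$truth$true_time_years)
    cat("  events: ", paste(sprintf("%s @ %s y", tab, names(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' @param sim A `founder_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths (`tree`,
#'   `metadata`, `truth`), invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "founder_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(sim$newick, paths["tree"])
  readr::write_tsv(sim$metadata, paths["metadata"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
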