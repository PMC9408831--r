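#' @keywords internal
descendant_tips <- function(tree, node) {
  nodes <- tree$nodes
  if (nodes$is_tip[node]) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- tree$children[[as.character(v)]]
    if (is.null(ch)) out <- c(out, v) else stack <- c(stack, ch)
  }
  out
}

#' @keywords internal
# mutation-count distance between two nodes along the tree path, using
# rootward walks to their most recent common ancestor
path_mutations <- function(tree, a, b) {
  nodes <- tree$nodes
  anc <- function(v) {
    path <- v
    while (!is.na(nodes$parent[v])) {
      v <- nodes$parent[v]
      path <- c(path, v)
    }
    path
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)
  mrca <- common[1]
  up <- function(v) {
    s <- 0
    while (v != mrca) {
      s <- s + nodes$mutations[v]
      v <- nodes$parent[v]
    }
    s
  }
  up(a) + up(b)
}

#' Attribute a founder cluster to a source region
#'
#' Collects the source leaves descending from the founder node (falling
#' back, when re-assignment left none, to the nearest rootward
#' source-attested ancestor) and attributes the founder to the region
#' holding the most of them. Ties are broken by the smallest mean
#' tree-path mutation distance to the founder node; a persistent tie is
#' resolved lexicographically and flagged ambiguous.
#'
#' @param clusters A `founder_clusters` tibble.
#' @param tree The role-annotated `founder_tree` the clusters came from.
#' @return Tibble `founder_id`, `region`, `support` (fraction of
#'   qualifying source leaves in the winning region), `ambiguous`,
#'   `n_source_leaves`.
#' @export
infer_source_region <- function(clusters, tree) {
  assert_annotated(tree)
  nodes <- tree$nodes
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    fnode <- clusters$node[i]
    v <- fnode
    src <- integer(0)
    while (!is.na(v)) {
      if (nodes$n_source[v] > 0) {
        tips <- descendant_tips(tree, v)
        src <- tips[!is.na(nodes$role[tips]) & nodes$role[tips] == "source"]
        break
      }
      v <- nodes$parent[v]
    }
    if (length(src) == 0) {
      return(tibble::tibble(founder_id = clusters$founder_id[i],
                            region = "unknown", support = NA_real_,
                            ambiguous = FALSE, n_source_leaves = 0L))
    }
    regions <- nodes$region[src]
    counts <- sort(table(regions), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    ambiguous <- FALSE
    if (length(top) > 1) {
      dist <- vapply(src, function(tip) path_mutations(tree, fnode, tip), numeric(1))
      meand <- vapply(top, function(r) mean(dist[regions == r]), numeric(1))
      top <- top[meand == min(meand)]
      if (length(top) > 1) {
        ambiguous <- TRUE
        top <- sort(top)
      }
    }
    tibble::tibble(
      founder_id = clusters$founder_id[i],
      region = top[1],
      support = as.numeric(counts[top[1]] / length(src)),
      ambiguous = ambiguous,
      n_source_leaves = length(src)
    )
  })
  dplyr::bind_rows(rows)
}

#' Region-by-epoch composition of migrations
#'
#' For each epoch, the fraction of allocated sink lineages whose founder
#' traces to each source region:
#' `entry(r, j) = sum_{i: region_i = r} n_i P_i(j) / sum_i n_i P_i(j)`.
#' Every epoch column sums to 1.
#'
#' @param attribution Output of [infer_source_region()].
#' @param allocation An `epoch_allocation` tibble for the same founders.
#' @return Tibble with a `region` column and one column per epoch label.
#' @export
epoch_region_composition <- function(attribution, allocation) {
  epochs <- attr(allocation, "epochs")
  stopifnot(!is.null(epochs))
  joined <- dplyr::inner_join(attribution, tibble::as_tibble(allocation),
                              by = "founder_id")
  if (nrow(joined) != nrow(allocation)) {
    rlang::abort("every founder needs both an attribution and an allocation")
  }
  out <- lapply(epochs$labels, function(lab) {
    w <- joined$n * joined[[lab]]
    agg <- tapply(w, joined$region, sum)
    col <- tibble::tibble(region = names(agg), value = as.numeric(agg) / sum(w))
    names(col)[2] <- lab
    col
  })
  comp <- purrr::reduce(out, dplyr::full_join, by = "region")
  comp <- dplyr::mutate(comp, dplyr::across(-"region", ~ tidyr::replace_na(.x, 0)))
  dplyr::arrange(comp, .data$region)
}

#' Per-population epoch frequencies
#'
#' For each sampling population, the frequency of lineages statistically
#' allocated to each migration epoch, relative to the population's total
#' sample count in the metadata (analysed or not):
#' `frequency(pop, j) = sum_clusters (cluster sink leaves in pop) * P(j)
#' / total samples in pop`. The per-population epoch frequencies plus
#' the non-analysed remainder sum to 1.
#'
#' @param metadata Full metadata table (all sampled individuals).
#' @param clusters A `founder_clusters` tibble.
#' @param allocation Matching `epoch_allocation` tibble.
#' @param populations Populations to report; defaults to every
#'   population in the metadata. A requested population absent from the
#'   metadata is an error.
#' @return Tibble `population`, `n_samples`, one frequency column per
#'   epoch label, and `unassigned`.
#' @export
population_epoch_frequency <- function(metadata, clusters, allocation,
                                       populations = NULL) {
  metadata <- validate_metadata(metadata)
  epochs <- attr(allocation, "epochs")
  stopifnot(!is.null(epochs))
  if (is.null(populations)) {
    populations <- sort(unique(metadata$population))
  } else {
    missing <- setdiff(populations, metadata$population)
    if (length(missing) > 0) {
      rlang::abort(paste0("population absent from metadata: ",
                          paste(missing, collapse = ", ")))
    }
  }
  pop_of <- stats::setNames(metadata$population, metadata$sample_id)
  totals <- table(metadata$population)

  # expected allocated-lineage count per (population, epoch)
  counts <- matrix(0, nrow = length(populations), ncol = length(epochs$labels),
                   dimnames = list(populations, epochs$labels))
  P <- as.matrix(tibble::as_tibble(allocation)[, epochs$labels, drop = FALSE])
  idx <- match(clusters$founder_id, allocation$founder_id)
  for (i in seq_len(nrow(clusters))) {
    pops <- pop_of[clusters$sink_samples[[i]]]
    tab <- table(pops[pops %in% populations])
    if (length(tab) == 0) next
    counts[names(tab), ] <- counts[names(tab), , drop = FALSE] +
      as.integer(tab) %o% P[idx[i], ]
  }
  freq <- counts / as.numeric(totals[populations])
  out <- tibble::tibble(population = populations,
                        n_samples = as.integer(totals[populations]))
  for (lab in epochs$labels) out[[lab]] <- as.numeric(freq[, lab])
  out$unassigned <- as.numeric(1 - rowSums(freq))
  out
}
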