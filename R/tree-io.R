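#' Read and validate a sample metadata table
#'
#' The metadata sidecar binds every tip of the phylogeny to a sampling
#' location. It is a tab-separated table with (at least) the columns
#' `sample_id`, `region` and `population`.
#'
#' @param path Path to a TSV file with a header line
#'   `sample_id<TAB>region<TAB>population`.
#' @return A tibble with character columns `sample_id`, `region`,
#'   `population`. `sample_id` is guaranteed unique and `region` non-empty.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_metadata(meta)
}

#' @keywords internal
validate_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "region", "population")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    rlang::abort(paste0("metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  metadata <- dplyr::mutate(metadata, dplyr::across(dplyr::all_of(need), as.character))
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate sample_id in metadata: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- is.na(metadata$region) | !nzchar(metadata$region)
  if (any(bad)) {
    rlang::abort(paste0("empty region for sample_id: ",
                        paste(metadata$sample_id[bad], collapse = ", ")))
  }
  metadata
}

#' Parse a mutation-annotated phylogeny
#'
#' Reads a rooted Newick tree whose branch lengths are integer mutation
#' counts and binds every leaf to a row of the sample metadata. Internal
#' nodes may be unlabeled inferred ancestral haplotypes; polytomies are
#' permitted.
#'
#' @param newick Either a path to a Newick file or a Newick string
#'   (one tree, branch lengths mandatory on all non-root branches).
#' @param metadata A metadata table as returned by
#'   [read_sample_metadata()], covering every leaf label of the tree.
#' @return A `founder_tree` object: a list with the `ape::phylo` tree
#'   (`$phylo`), a per-node tibble (`$nodes`) with parent pointers,
#'   branch mutation counts and leaf metadata bindings, and the metadata
#'   table itself (`$metadata`).
#' @details Branch lengths within 1e-6 of an integer are rounded to that
#'   integer; anything else is rejected, as are negative lengths,
#'   duplicate leaf labels and leaves with no metadata row.
#' @export
parse_tree <- function(newick, metadata) {
  metadata <- validate_metadata(metadata)
  phy <- if (length(newick) == 1 && !grepl("[(;]", newick) && file.exists(newick)) {
    ape::read.tree(newick)
  } else {
    ape::read.tree(text = paste(newick, collapse = ""))
  }
  if (is.null(phy)) rlang::abort("could not parse Newick input")

  n_tip <- length(phy$tip.label)
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge)) {
    rlang::abort("branch lengths (mutation counts) are required on every branch")
  }
  if (any(phy$edge.length < 0)) rlang::abort("negative branch length in tree")
  rounded <- round(phy$edge.length)
  if (any(abs(phy$edge.length - rounded) > 1e-6)) {
    off <- which(abs(phy$edge.length - rounded) > 1e-6)[1]
    rlang::abort(paste0("branch length ", phy$edge.length[off],
                        " is not an integer mutation count"))
  }
  phy$edge.length <- as.numeric(rounded)

  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate leaf labels: ", paste(unique(dup), collapse = ", ")))
  }
  unbound <- setdiff(phy$tip.label, metadata$sample_id)
  if (length(unbound) > 0) {
    rlang::abort(paste0("leaf without metadata row: ", paste(unbound, collapse = ", ")))
  }

  new_founder_tree(phy, metadata)
}

#' @keywords internal
new_founder_tree <- function(phy, metadata) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_all)
  mutations <- rep(0L, n_all)
  parent[phy$edge[, 2]] <- as.integer(phy$edge[, 1])
  mutations[phy$edge[, 2]] <- as.integer(round(phy$edge.length))
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(root) != 1) rlang::abort("tree must have exactly one root")

  label <- character(n_all)
  label[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label)) label[n_tip + seq_len(phy$Nnode)] <- phy$node.label

  # breadth-first order from the root: parents always precede children
  depth <- rep(NA_integer_, n_all)
  depth[root] <- 0L
  order <- integer(n_all)
  order[1] <- root
  head <- 1L; filled <- 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  while (head <= filled) {
    v <- order[head]
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) {
      depth[ch] <- depth[v] + 1L
      order[filled + seq_along(ch)] <- ch
      filled <- filled + length(ch)
    }
    head <- head + 1L
  }

  is_tip <- seq_len(n_all) <= n_tip
  idx <- match(label, metadata$sample_id)
  idx[!is_tip] <- NA_integer_
  nodes <- tibble::tibble(
    node = seq_len(n_all),
    parent = parent,
    mutations = mutations,
    label = label,
    is_tip = is_tip,
    depth = depth,
    sample_id = ifelse(is_tip, label, NA_character_),
    region = metadata$region[idx],
    population = metadata$population[idx]
  )

  structure(
    list(phylo = phy, nodes = nodes, metadata = metadata,
         root = root, preorder = order, children = kids),
    class = "founder_tree"
  )
}

#' @export
print.founder_tree <- function(x, ...) {
  n_tip <- sum(x$nodes$is_tip)
  cat("<founder_tree> ", n_tip, " leaves, ", nrow(x$nodes) - n_tip,
      " internal nodes, ", sum(x$nodes$mutations), " mutations\n", sep = "")
  if (!is.null(x$roles)) {
    cat("  roles: source = {", paste(x$roles$source, collapse = ", "),
        "}; sink = {", paste(x$roles$sink, collapse = ", "), "}\n", sep = "")
    cat("  ", sum(x$nodes$role == "source", na.rm = TRUE), " source leaves, ",
        sum(x$nodes$role == "sink", na.rm = TRUE), " sink leaves\n", sep = "")
  }
  invisible(x)
}

#' Write a founder tree back to Newick
#'
#' @param tree A `founder_tree`.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Assign source/sink roles and tally descendants
#'
#' Marks every leaf as source, sink, or unassigned according to its
#' metadata region, and annotates every node with the counts `n_source`
#' and `n_sink` of descendant leaves in each role (a leaf counts
#' itself). Also precomputes haplotype-identity components (maximal sets
#' of nodes connected by zero-mutation branches), which drive founder
#' attestation downstream.
#'
#' @param tree A `founder_tree` from [parse_tree()].
#' @param source_regions Character vector of region labels forming the
#'   hypothetical source.
#' @param sink_regions Character vector of region labels forming the
#'   hypothetical sink. Must be disjoint from `source_regions`; regions
#'   in neither set are retained in the tree but ignored in all tallies.
#' @return The tree with role annotations added to `$nodes` (`role`,
#'   `n_source`, `n_sink`, `zero_attested`, `attested`,
#'   `derived_source_branches`) and `$roles` recording the assignment.
#' @export
annotate_roles <- function(tree, source_regions, sink_regions) {
  stopifnot(inherits(tree, "founder_tree"))
  source_regions <- as.character(source_regions)
  sink_regions <- as.character(sink_regions)
  if (length(source_regions) == 0 || length(sink_regions) == 0) {
    rlang::abort("source and sink region sets must both be non-empty")
  }
  overlap <- intersect(source_regions, sink_regions)
  if (length(overlap) > 0) {
    rlang::abort(paste0("source and sink regions overlap: ",
                        paste(overlap, collapse = ", ")))
  }

  nodes <- tree$nodes
  role <- rep(NA_character_, nrow(nodes))
  role[nodes$is_tip & nodes$region %in% source_regions] <- "source"
  role[nodes$is_tip & nodes$region %in% sink_regions] <- "sink"
  if (!any(role == "sink", na.rm = TRUE)) rlang::abort("no sink lineages to analyse")
  if (!any(role == "source", na.rm = TRUE)) rlang::abort("no source lineages to analyse")

  n_all <- nrow(nodes)
  n_source <- as.integer(!is.na(role) & role == "source")
  n_sink <- as.integer(!is.na(role) & role == "sink")
  for (v in rev(tree$preorder)) {        # children before parents
    p <- nodes$parent[v]
    if (!is.na(p)) {
      n_source[p] <- n_source[p] + n_source[v]
      n_sink[p] <- n_sink[p] + n_sink[v]
    }
  }

  # haplotype-identity components: union-find over zero-mutation branches
  comp <- seq_len(n_all)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  zero_children <- which(!is.na(nodes$parent) & nodes$mutations == 0L)
  for (v in zero_children) {
    a <- find(v); b <- find(nodes$parent[v])
    if (a != b) comp[a] <- b
  }
  comp_id <- vapply(seq_len(n_all), find, integer(1))
  src_comps <- unique(comp_id[!is.na(role) & role == "source"])
  zero_attested <- comp_id %in% src_comps

  # attestation: same haplotype sampled in the source (zero-mutation path
  # to a source leaf), or an inferred ancestral node with source descendants
  attested <- zero_attested | (!nodes$is_tip & n_source > 0)

  # derived source diversity: child branches with >=1 mutation leading to
  # >=1 source leaf (the f-criterion counts these per founder node)
  derived <- integer(n_all)
  src_derived_child <- which(!is.na(nodes$parent) & nodes$mutations >= 1L & n_source > 0)
  if (length(src_derived_child) > 0) {
    tab <- table(nodes$parent[src_derived_child])
    derived[as.integer(names(tab))] <- as.integer(tab)
  }

  tree$nodes$role <- role
  tree$nodes$n_source <- n_source
  tree$nodes$n_sink <- n_sink
  tree$nodes$zero_attested <- zero_attested
  tree$nodes$attested <- attested
  tree$nodes$derived_source_branches <- derived
  tree$roles <- list(source = source_regions, sink = sink_regions)
  tree
}
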