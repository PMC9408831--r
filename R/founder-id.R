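#' Find candidate founder nodes
#'
#' For each sink leaf, walks rootward from the leaf (the leaf itself
#' included) and stops at the most recent node whose haplotype is
#' attested in the source population: either a source leaf is reachable
#' through a path of total mutation count zero (the same haplotype was
#' sampled in the source), or the node is an inferred ancestor with at
#' least one source-leaf descendant. Distinct stopping nodes become
#' founder candidates; sink leaves with no source-attested ancestor are
#' reported with `node = NA`.
#'
#' @param tree A role-annotated `founder_tree` (see [annotate_roles()]).
#' @return A tibble with one row per candidate founder node:
#'   `node`, `node_label`, `n_sink`, `sink_samples` (list column of
#'   sample ids), `source_derived_branches` (count of child branches
#'   carrying >= 1 mutation that lead to source leaves), plus a final
#'   row per orphan sink leaf with `node = NA` if any exist.
#' @export
find_founder_nodes <- function(tree) {
  assert_annotated(tree)
  nodes <- tree$nodes
  sink_tips <- which(!is.na(nodes$role) & nodes$role == "sink")

  founder_of <- vapply(sink_tips, function(tip) {
    v <- tip
    while (!is.na(v)) {
      if (nodes$attested[v]) return(v)
      v <- nodes$parent[v]
    }
    NA_integer_
  }, integer(1))

  out <- tibble::tibble(
    node = founder_of,
    sink_sample = nodes$sample_id[sink_tips]
  )
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$node),
    sink_samples = list(.data$sink_sample),
    n_sink = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    node_label = ifelse(is.na(.data$node), NA_character_,
                        node_name(tree, .data$node)),
    source_derived_branches = ifelse(
      is.na(.data$node), NA_integer_,
      nodes$derived_source_branches[pmax(.data$node, 1L)]),
    .after = "node"
  )
  dplyr::arrange(out, is.na(.data$node), .data$node)
}

#' @keywords internal
node_name <- function(tree, node) {
  lab <- tree$nodes$label[node]
  ifelse(nzchar(lab) & !is.na(lab), lab, paste0("node_", node))
}

#' @keywords internal
assert_annotated <- function(tree) {
  stopifnot(inherits(tree, "founder_tree"))
  if (is.null(tree$roles)) {
    rlang::abort("tree has no role annotation; call annotate_roles() first")
  }
  invisible(tree)
}

#' Apply the f diversity criterion to founder candidates
#'
#' A founder match must display some derived diversity in the source
#' population: the candidate node must have at least `f` source-leading
#' child branches carrying one or more mutations. `f = 1` is the
#' classical f1 criterion, guarding against back-migrated or erroneous
#' matches; `f = 0` accepts any source-attested match.
#'
#' @param candidates Candidate tibble from [find_founder_nodes()].
#' @param f Non-negative integer threshold (default 1).
#' @return The tibble with a logical `f_passed` column appended.
#' @export
apply_f_criterion <- function(candidates, f = 1) {
  f <- check_f(f)
  dplyr::mutate(candidates,
                f_passed = !is.na(.data$node) & .data$source_derived_branches >= f)
}

#' @keywords internal
check_f <- function(f) {
  if (length(f) != 1 || is.na(f) || f < 0 || f != round(f)) {
    rlang::abort("f must be a single non-negative integer")
  }
  as.integer(f)
}

#' Group sink leaves into founder clusters
#'
#' Builds one cluster per founder node surviving the f criterion. A sink
#' leaf whose most recent source-attested ancestor fails the criterion is
#' re-assigned to the next source-attested ancestor rootward that passes
#' it, or dropped if none exists. For each cluster the per-leaf mutation
#' paths from the founder node and the per-branch `(n_b, m_b)` table of
#' the sink-restricted subtree are recorded; these feed the rho and
#' Saillard estimators. Mutations on the branch into the founder node
#' itself are excluded: rho dates the divergence of the sink lineages
#' from the founder haplotype.
#'
#' @param tree A role-annotated `founder_tree`.
#' @param f Non-negative integer diversity threshold (default 1).
#' @return A tibble of class `founder_clusters`, one row per cluster:
#'   `founder_id`, `node`, `n`, `sink_samples` (list), `path_counts`
#'   (list of per-leaf mutation counts), `branches` (list of tibbles
#'   with `node`, `n_b`, `m_b` over the sink-restricted subtree).
#' @export
build_clusters <- function(tree, f = 1) {
  assert_annotated(tree)
  f <- check_f(f)
  nodes <- tree$nodes
  passing <- nodes$attested & nodes$derived_source_branches >= f
  sink_tips <- which(!is.na(nodes$role) & nodes$role == "sink")

  founder_of <- vapply(sink_tips, function(tip) {
    v <- tip
    while (!is.na(v)) {
      if (passing[v]) return(v)
      v <- nodes$parent[v]
    }
    NA_integer_
  }, integer(1))

  keep <- !is.na(founder_of)
  if (!any(keep)) {
    rlang::warn("no sink leaf has a source-attested founder passing the criterion")
    return(empty_clusters())
  }

  groups <- split(sink_tips[keep], founder_of[keep])
  rows <- purrr::map2(names(groups), groups, function(fnode, tips) {
    fnode <- as.integer(fnode)
    # per-leaf rootward paths up to (excluding) the founder node
    paths <- lapply(tips, function(tip) {
      v <- tip; path <- integer(0)
      while (v != fnode) {
        path <- c(path, v)
        v <- nodes$parent[v]
      }
      path
    })
    branch_nodes <- unlist(paths)
    tab <- table(branch_nodes)
    bnode <- as.integer(names(tab))
    branches <- tibble::tibble(
      node = bnode,
      n_b = as.integer(tab),
      m_b = nodes$mutations[bnode]
    )
    tibble::tibble(
      founder_id = node_name(tree, fnode),
      node = fnode,
      n = length(tips),
      sink_samples = list(nodes$sample_id[tips]),
      path_counts = list(vapply(paths, function(p) sum(nodes$mutations[p]), numeric(1))),
      branches = list(branches)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$node)
  class(out) <- c("founder_clusters", class(out))
  out
}

#' @keywords internal
empty_clusters <- function() {
  out <- tibble::tibble(
    founder_id = character(0), node = integer(0), n = integer(0),
    sink_samples = list(), path_counts = list(), branches = list()
  )
  class(out) <- c("founder_clusters", class(out))
  out
}

#' Export the founder table
#'
#' @param clusters A `founder_clusters` tibble.
#' @return A flat tibble suitable for TSV export: `founder_id`, `node`,
#'   `n_sink`, `sink_sample_ids` (comma-joined).
#' @export
founder_table <- function(clusters) {
  tibble::tibble(
    founder_id = clusters$founder_id,
    node = clusters$node,
    n_sink = clusters$n,
    sink_sample_ids = vapply(clusters$sink_samples, paste, character(1), collapse = ",")
  )
}
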