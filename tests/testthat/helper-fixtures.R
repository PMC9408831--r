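# Fixtures and independent oracles shared across the suite.
# Oracles deliberately use ape primitives (dist.nodes, raw edge walks),
# never the package's own path bookkeeping.

meta_for <- function(ids, regions, populations = regions) {
  tibble::tibble(sample_id = ids, region = regions, population = populations)
}

# five-leaf reference tree used throughout the founder-id tests:
# founder F1 groups one zero-path source leaf with one sink leaf
tree_basic <- function() {
  parse_tree("((S1:0,K1:1):2,S2:3);",
             meta_for(c("S1", "K1", "S2"),
                      c("Src", "Snk", "Src")))
}

annotate_basic <- function() {
  annotate_roles(tree_basic(), "Src", "Snk")
}

# independent per-leaf path-count oracle: mutation distance on the phylo
oracle_path_counts <- function(tree, founder_node, tips) {
  d <- ape::dist.nodes(tree$phylo)
  as.numeric(d[founder_node, tips])
}

# brute-force founder assignment: enumerate every (sink leaf, ancestor)
# pair and apply the attestation rule directly
oracle_founders <- function(tree) {
  nodes <- tree$nodes
  d <- ape::dist.nodes(tree$phylo)
  src_tips <- which(!is.na(nodes$role) & nodes$role == "source")
  desc_tips <- function(v) {
    if (nodes$is_tip[v]) return(v)
    out <- integer(0)
    todo <- v
    while (length(todo)) {
      x <- todo[1]; todo <- todo[-1]
      ch <- nodes$node[!is.na(nodes$parent) & nodes$parent == x]
      if (length(ch) == 0) out <- c(out, x) else todo <- c(todo, ch)
    }
    out
  }
  attested <- function(v) {
    if (length(src_tips) && any(d[v, src_tips] == 0)) return(TRUE)
    !nodes$is_tip[v] && any(desc_tips(v) %in% src_tips)
  }
  sink_tips <- which(!is.na(nodes$role) & nodes$role == "sink")
  vapply(sink_tips, function(tip) {
    v <- tip
    while (!is.na(v)) {
      if (attested(v)) return(v)
      v <- nodes$parent[v]
    }
    NA_integer_
  }, integer(1))
}

# random small tree with integer mutation counts and random roles
random_role_tree <- function(n_tips, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_tips, br = function(n) sample(0:3, n, replace = TRUE))
  regions <- sample(c("Src", "Snk", "Other"), n_tips, replace = TRUE)
  # guarantee both roles occur
  regions[1] <- "Src"
  regions[2] <- "Snk"
  md <- meta_for(phy$tip.label, regions)
  parse_tree(ape::write.tree(phy), md)
}

# star clusters simulated directly (no tree plumbing): one row per
# founder, as date_clusters() would emit
sim_star_dated <- function(t_years, n_founders, n, ypm = 2565) {
  rows <- lapply(seq_len(n_founders), function(i) {
    draws <- stats::rpois(n, t_years / ypm)
    rho <- mean(draws)
    sigma <- sqrt(sum(draws)) / n
    tibble::tibble(founder_id = sprintf("T%d_%d", t_years, i),
                   node = i, n = n, rho = rho, sigma_rho = sigma,
                   age_years = rho * ypm, sigma_years = sigma * ypm,
                   sink_samples = list(character(0)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dated_clusters", class(out))
  out
}
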