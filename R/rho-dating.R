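#' Linear molecular clock
#'
#' The founder-analysis machinery requires a linear clock: ages in years
#' are mutation counts times a constant. The default, one substitution
#' per 2565 years, is the mitogenome rate near the present after
#' correcting for purifying selection.
#'
#' @param years_per_mutation Positive number of years per substitution.
#' @return A `clock_model` object.
#' @export
clock_model <- function(years_per_mutation = 2565) {
  if (!is.numeric(years_per_mutation) || length(years_per_mutation) != 1 ||
      is.na(years_per_mutation) || years_per_mutation <= 0) {
    rlang::abort("years_per_mutation must be a single positive number")
  }
  structure(list(years_per_mutation = as.numeric(years_per_mutation)),
            class = "clock_model")
}

#' The rho statistic
#'
#' Mean number of mutations from the founder node to its sink leaves,
#' computed as the branch-weighted sum `sum(n_b * m_b) / n` over the
#' sink-restricted subtree. Identical to the mean of the per-leaf path
#' counts (a conservation identity the test suite asserts).
#'
#' @param branches Tibble with columns `n_b` (sink leaves below the
#'   branch) and `m_b` (mutations on the branch).
#' @param n Number of sink leaves in the cluster.
#' @return Non-negative number, mean mutations per sink lineage.
#' @export
rho_statistic <- function(branches, n) {
  stopifnot(n >= 1)
  sum(branches$n_b * branches$m_b) / n
}

#' Saillard standard error of rho
#'
#' `sigma^2 = sum over branches b of (n_b / n)^2 * m_b`, where `n_b` is
#' the number of cluster sink leaves below branch `b` and `m_b` its
#' mutation count. For a star cluster this reduces to `sqrt(total)/n`.
#'
#' @inheritParams rho_statistic
#' @return Non-negative standard error of rho.
#' @export
saillard_se <- function(branches, n) {
  stopifnot(n >= 1)
  sqrt(sum((branches$n_b / n)^2 * branches$m_b))
}

#' Convert a rho estimate to an age in years
#'
#' @param rho,sigma_rho Non-negative rho estimate and its standard error.
#' @param clock A [clock_model()].
#' @return A one-row tibble: `rho`, `sigma_rho`, `age_years`,
#'   `sigma_years`. Ages scale exactly linearly with the clock rate.
#' @export
to_age <- function(rho, sigma_rho, clock = clock_model()) {
  stopifnot(inherits(clock, "clock_model"), rho >= 0, sigma_rho >= 0)
  tibble::tibble(
    rho = rho,
    sigma_rho = sigma_rho,
    age_years = rho * clock$years_per_mutation,
    sigma_years = sigma_rho * clock$years_per_mutation
  )
}

#' Date founder clusters
#'
#' Applies [rho_statistic()], [saillard_se()] and the linear clock to
#' every cluster.
#'
#' @param clusters A `founder_clusters` tibble from [build_clusters()].
#' @param clock A [clock_model()].
#' @return A tibble of class `dated_clusters`: `founder_id`, `node`,
#'   `n`, `rho`, `sigma_rho`, `age_years`, `sigma_years`, carrying the
#'   `sink_samples` list column through for downstream tabulations.
#' @export
date_clusters <- function(clusters, clock = clock_model()) {
  stopifnot(inherits(clock, "clock_model"))
  rho <- vapply(seq_len(nrow(clusters)), function(i) {
    rho_statistic(clusters$branches[[i]], clusters$n[i])
  }, numeric(1))
  sigma <- vapply(seq_len(nrow(clusters)), function(i) {
    saillard_se(clusters$branches[[i]], clusters$n[i])
  }, numeric(1))
  out <- tibble::tibble(
    founder_id = clusters$founder_id,
    node = clusters$node,
    n = clusters$n,
    rho = rho,
    sigma_rho = sigma,
    age_years = rho * clock$years_per_mutation,
    sigma_years = sigma * clock$years_per_mutation,
    sink_samples = clusters$sink_samples
  )
  class(out) <- c("dated_clusters", class(out))
  out
}

#' Export the dating table
#'
#' @param dated A `dated_clusters` tibble.
#' @return Flat tibble: `founder_id`, `n`, `rho`, `sigma_rho`,
#'   `age_years`, `sigma_years`.
#' @export
dating_table <- function(dated) {
  dplyr::select(tibble::as_tibble(dated), "founder_id", "n", "rho",
                "sigma_rho", "age_years", "sigma_years")
}
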