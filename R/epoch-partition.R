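#' Fixed migration-epoch model
#'
#' The two-migration default places one event at 8 ka (the peak of the
#' Holocene Climate Optimum, apportioning prehistoric arrivals) and a
#' second at 0.5 ka (roughly the start of the Atlantic slave trade,
#' statistically absorbing all recent events).
#'
#' @param times Numeric vector (length >= 2) of distinct non-negative
#'   epoch times in years.
#' @param labels Unique character labels, same length as `times`.
#' @return An `epoch_model` object.
#' @export
epoch_model <- function(times = c(8000, 500),
                        labels = c("prehistoric", "historical")) {
  if (length(times) < 2 || anyDuplicated(times) || any(times < 0)) {
    rlang::abort("epoch times must be >= 2 distinct non-negative values")
  }
  if (length(labels) != length(times) || anyDuplicated(labels)) {
    rlang::abort("labels must be unique and match times in length")
  }
  structure(list(times = as.numeric(times), labels = as.character(labels)),
            class = "epoch_model")
}

#' Posterior allocation of one founder between epochs
#'
#' `P(epoch j)` is proportional to the Gaussian density at the epoch
#' time with mean `age_years` and standard deviation
#' `max(sigma_years, sigma_floor)`, under a uniform prior over epochs.
#' If every density underflows, all mass goes to the epoch nearest in
#' time (split equally on an exact tie).
#'
#' @param age_years,sigma_years Founder age estimate and standard error.
#' @param epochs An [epoch_model()].
#' @param sigma_floor Minimum standard deviation in years; the default
#'   matches the scan grid step so degenerate clusters behave
#'   identically across modules.
#' @return Numeric posterior vector over epochs, summing to 1.
#' @export
epoch_posterior <- function(age_years, sigma_years, epochs = epoch_model(),
                            sigma_floor = 200) {
  stopifnot(inherits(epochs, "epoch_model"))
  sd <- max(sigma_years, sigma_floor)
  d <- stats::dnorm(epochs$times, mean = age_years, sd = sd)
  s <- sum(d)
  if (!is.finite(s) || s <= 0) {
    gap <- abs(epochs$times - age_years)
    d <- as.numeric(gap == min(gap))
    s <- sum(d)
  }
  d / s
}

#' Allocate founder clusters between migration epochs
#'
#' @param dated A `dated_clusters` tibble from [date_clusters()].
#' @param epochs An [epoch_model()].
#' @param sigma_floor Passed to [epoch_posterior()].
#' @return A tibble of class `epoch_allocation`: `founder_id`, `n`,
#'   `age_years`, and one posterior column per epoch label (each row
#'   sums to 1). Carries the model in attribute `epochs`.
#' @export
allocate_epochs <- function(dated, epochs = epoch_model(), sigma_floor = 200) {
  stopifnot(inherits(epochs, "epoch_model"))
  if (nrow(dated) == 0) rlang::abort("no founder clusters to allocate")
  P <- t(vapply(seq_len(nrow(dated)), function(i) {
    epoch_posterior(dated$age_years[i], dated$sigma_years[i], epochs, sigma_floor)
  }, numeric(length(epochs$times))))
  colnames(P) <- epochs$labels
  out <- dplyr::bind_cols(
    tibble::tibble(founder_id = dated$founder_id, n = dated$n,
                   age_years = dated$age_years),
    tibble::as_tibble(P)
  )
  attr(out, "epochs") <- epochs
  class(out) <- c("epoch_allocation", class(out))
  out
}

#' Aggregate epoch posteriors into lineage proportions
#'
#' `proportion(j) = sum_i n_i P_i(j) / sum_i n_i`: founders are weighted
#' by their sink sample count, so the result is the fraction of sink
#' lineages statistically allocated to each migration.
#'
#' @param allocation An `epoch_allocation` tibble.
#' @return Tibble `epoch`, `proportion` (sums to 1), `effective_n`
#'   (expected lineage count per epoch).
#' @export
aggregate_allocation <- function(allocation) {
  epochs <- attr(allocation, "epochs")
  stopifnot(!is.null(epochs))
  eff <- vapply(epochs$labels, function(lab) {
    sum(allocation$n * allocation[[lab]])
  }, numeric(1))
  tibble::tibble(
    epoch = epochs$labels,
    epoch_years = epochs$times,
    proportion = as.numeric(eff / sum(allocation$n)),
    effective_n = as.numeric(eff)
  )
}
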