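#' Candidate-migration-time grid
#'
#' The default grid evaluates candidate migration times every 200 years
#' from 0 to 25,000 years before present, both ends included.
#'
#' @param t_min,t_max Grid limits in years (`t_min < t_max`).
#' @param step Grid spacing in years; `(t_max - t_min)` must be an
#'   exact multiple of `step`.
#' @return A `scan_grid` object with the ordered grid `$times` and
#'   `$step`.
#' @export
scan_grid <- function(t_min = 0, t_max = 25000, step = 200) {
  if (t_min >= t_max) rlang::abort("t_min must be less than t_max")
  if (step <= 0) rlang::abort("step must be positive")
  k <- (t_max - t_min) / step
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort("(t_max - t_min) must be divisible by step")
  }
  structure(list(times = seq(t_min, t_max, by = step),
                 t_min = t_min, t_max = t_max, step = step),
            class = "scan_grid")
}

#' Per-founder weight vector over the scan grid
#'
#' The sampling distribution of a founder's migration time is taken as
#' Gaussian with mean `age_years` and standard deviation
#' `max(sigma_years, sigma_floor)`, evaluated at each grid point and
#' normalized to sum 1 (truncation to the grid's support). The floor,
#' one grid step by default, stops zero-variance clusters (rho = 0)
#' from degenerating into incomparable point masses.
#'
#' @param age_years,sigma_years Age estimate and standard error in years.
#' @param grid A [scan_grid()].
#' @param sigma_floor Minimum standard deviation in years; defaults to
#'   one grid step.
#' @return Numeric weight vector, one entry per grid point, summing to 1.
#' @export
founder_density <- function(age_years, sigma_years, grid = scan_grid(),
                            sigma_floor = grid$step) {
  stopifnot(inherits(grid, "scan_grid"), age_years >= 0, sigma_years >= 0)
  sd <- max(sigma_years, sigma_floor)
  w <- stats::dnorm(grid$times, mean = age_years, sd = sd)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) {
    # complete underflow far off-grid: point mass at the nearest grid time
    w <- numeric(length(grid$times))
    w[which.min(abs(grid$times - age_years))] <- 1
    return(w)
  }
  w / s
}

#' Aggregate founder ages into a migration scan
#'
#' Produces the probabilistic distribution of founder arrivals over the
#' grid: `mass(t) = sum_i n_i w_i(t) / sum_i n_i`, each founder's
#' normalized weight vector weighted by its sink sample count (or
#' equally with `weights = "equal"`).
#'
#' @param dated A `dated_clusters` tibble from [date_clusters()].
#' @param grid A [scan_grid()].
#' @param weights `"size"` (sink-lineage counts, the default) or
#'   `"equal"`.
#' @param sigma_floor Passed to [founder_density()].
#' @param keep_weights Retain the per-founder weight matrix in the result.
#' @return A `migration_scan` object: `$grid`, `$mass` (sums to 1),
#'   `$n_founders`, `$n_lineages`, and `$founder_weights` (founders x
#'   grid matrix) when requested.
#' @export
aggregate_scan <- function(dated, grid = scan_grid(),
                           weights = c("size", "equal"),
                           sigma_floor = grid$step, keep_weights = FALSE) {
  weights <- match.arg(weights)
  if (nrow(dated) == 0) rlang::abort("no founder clusters to scan")
  W <- t(vapply(seq_len(nrow(dated)), function(i) {
    founder_density(dated$age_years[i], dated$sigma_years[i], grid, sigma_floor)
  }, numeric(length(grid$times))))
  wt <- if (weights == "size") dated$n else rep(1, nrow(dated))
  mass <- as.numeric(colSums(W * wt) / sum(wt))
  out <- list(grid = grid, mass = mass,
              n_founders = nrow(dated), n_lineages = sum(dated$n),
              weighting = weights)
  if (keep_weights) {
    rownames(W) <- dated$founder_id
    out$founder_weights <- W
  }
  structure(out, class = "migration_scan")
}

#' @export
print.migration_scan <- function(x, ...) {
  cat("<migration_scan> ", x$n_founders, " founders (", x$n_lineages,
      " sink lineages), grid ", x$grid$t_min, "-", x$grid$t_max,
      " by ", x$grid$step, " y\n", sep = "")
  pk <- utils::head(find_peaks(x), 3)
  if (nrow(pk) > 0) {
    cat("  top peaks (years): ", paste(pk$time_years, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Locate peaks in a migration scan
#'
#' Strict local maxima of the mass vector: interior points greater than
#' both neighbours, grid ends greater than their single neighbour.
#'
#' @param scan A `migration_scan`.
#' @return Tibble `time_years`, `mass`, sorted by mass descending.
#' @export
find_peaks <- function(scan) {
  stopifnot(inherits(scan, "migration_scan"))
  m <- scan$mass
  L <- length(m)
  is_peak <- logical(L)
  if (L >= 2) {
    is_peak[1] <- m[1] > m[2]
    is_peak[L] <- m[L] > m[L - 1]
    if (L > 2) {
      i <- 2:(L - 1)
      is_peak[i] <- m[i] > m[i - 1] & m[i] > m[i + 1]
    }
  }
  out <- tibble::tibble(time_years = scan$grid$times[is_peak], mass = m[is_peak])
  dplyr::arrange(out, dplyr::desc(.data$mass))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname aggregate_scan
#' @param x A `migration_scan`.
#' @param ... Unused.
#' @export
tidy.migration_scan <- function(x, ...) {
  tibble::tibble(time_years = x$grid$times, mass = x$mass)
}

#' @rdname aggregate_scan
#' @export
glance.migration_scan <- function(x, ...) {
  pk <- find_peaks(x)
  tibble::tibble(
    n_founders = x$n_founders,
    n_lineages = x$n_lineages,
    n_peaks = nrow(pk),
    peak1_years = if (nrow(pk) >= 1) pk$time_years[1] else NA_real_,
    peak2_years = if (nrow(pk) >= 2) pk$time_years[2] else NA_real_
  )
}

#' @rdname aggregate_scan
#' @param object A `migration_scan`.
#' @export
autoplot.migration_scan <- function(object, ...) {
  df <- tidy(object)
  pk <- find_peaks(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_years / 1000, y = .data$mass)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(x = .data$time_years / 1000, y = .data$mass),
                        colour = "firebrick", size = 1.5) +
    ggplot2::labs(x = "Migration time (ka)", y = "Probability mass",
                  title = "Migration-time scan") +
    ggplot2::theme_minimal()
}
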