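test_that("the scan grid validates its construction", {
  g <- scan_grid()
  expect_equal(g$times[1], 0)
  expect_equal(g$times[length(g$times)], 25000)
  expect_equal(length(g$times), 126)
  expect_error(scan_grid(t_min = 100, t_max = 100), "less than")
  expect_error(scan_grid(step = -5), "positive")
  expect_error(scan_grid(t_max = 25100), "divisible")
})

test_that("founder weight vectors are normalized grid Gaussians", {
  g <- scan_grid()
  w <- founder_density(5000, 1000, g)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(g$times[which.max(w)], 5000)
  # sigma floor engages for zero-variance clusters
  w0 <- founder_density(5000, 0, g)
  expect_equal(g$times[which.max(w0)], 5000)
  expect_equal(sum(w0 > 1e-6), sum(founder_density(5000, g$step, g) > 1e-6))
  # age at the boundary: truncated half-Gaussian is non-increasing
  wh <- founder_density(0, 500, g)
  expect_true(all(diff(wh) <= 1e-15))
  # off-grid underflow degenerates to a point mass at the nearest time
  wu <- founder_density(24000, 1e-6, g, sigma_floor = 1e-6)
  expect_equal(sum(wu), 1)
})

test_that("scan aggregation weights founders by sink sample count", {
  g <- scan_grid()
  one <- sim_star_dated(8000, 1, 10)
  sc1 <- aggregate_scan(one, g)
  expect_equal(sc1$mass, founder_density(one$age_years, one$sigma_years, g))

  # two well-separated founders with on-grid ages give a bimodal mass
  two <- dplyr::bind_rows(
    tibble::tibble(founder_id = "a", node = 1L, n = 1L, rho = 600 / 2565,
                   sigma_rho = 0, age_years = 600, sigma_years = 100,
                   sink_samples = list("x")),
    tibble::tibble(founder_id = "b", node = 2L, n = 1L, rho = 8000 / 2565,
                   sigma_rho = 0, age_years = 8000, sigma_years = 100,
                   sink_samples = list("y")))
  class(two) <- c("dated_clusters", class(two))
  sc2 <- aggregate_scan(two, g)
  pk <- find_peaks(sc2)
  expect_setequal(pk$time_years, c(600, 8000))

  # identical ages: size weights cancel and aggregate equals either vector
  same <- dplyr::mutate(two, age_years = 4000, n = c(3L, 1L))
  class(same) <- class(two)
  sc3 <- aggregate_scan(same, g)
  expect_equal(sc3$mass, founder_density(4000, 100, g))
  expect_error(aggregate_scan(two[0, ], g), "no founder")
})

test_that("peak finding returns strict local maxima sorted by mass", {
  g <- scan_grid(0, 1000, 200)
  fake <- structure(list(grid = g, mass = rep(1 / 6, 6),
                         n_founders = 1, n_lineages = 1), class = "migration_scan")
  expect_equal(nrow(find_peaks(fake)), 0)   # flat vector: no strict maxima
  fake$mass <- c(0.05, 0.3, 0.1, 0.1, 0.4, 0.05)
  pk <- find_peaks(fake)
  expect_equal(pk$time_years, c(800, 200))  # sorted by mass descending
})

test_that("every weight vector and aggregate mass sums to one (property)", {
  g <- scan_grid()
  set.seed(5)
  dated <- sim_star_dated(3000, 25, 8)
  sc <- aggregate_scan(dated, g, keep_weights = TRUE)
  expect_equal(sum(sc$mass), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(sc$founder_weights)), rep(1, 25), tolerance = 1e-9)
})

test_that("shifting all ages by a grid multiple shifts every peak identically", {
  g <- scan_grid()
  set.seed(6)
  dated <- dplyr::bind_rows(sim_star_dated(4000, 15, 10),
                            sim_star_dated(12000, 15, 10))
  class(dated) <- c("dated_clusters", class(dated))
  delta <- 2000
  shifted <- dplyr::mutate(dated, age_years = age_years + delta)
  class(shifted) <- class(dated)
  p0 <- find_peaks(aggregate_scan(dated, g))
  p1 <- find_peaks(aggregate_scan(shifted, g))
  expect_equal(sort(p1$time_years), sort(p0$time_years) + delta)
})

test_that("twin-peak structure is recovered from ample synthetic founders", {
  # scan-only recovery: star clusters drawn at the two epochs, with
  # enough founders and lineages per founder that the peak sampling
  # error sits well inside two grid steps
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    dated <- dplyr::bind_rows(sim_star_dated(500, 60, 20),
                              sim_star_dated(8000, 60, 20))
    class(dated) <- c("dated_clusters", class(dated))
    pk <- utils::head(find_peaks(aggregate_scan(dated)), 2)
    all(vapply(c(500, 8000), function(t0) min(abs(pk$time_years - t0)) <= 400,
               logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
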