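# shared fixture: one founder clade whose source leaves span regions
region_tree <- function(newick, ids, regions) {
  annotate_roles(parse_tree(newick, meta_for(ids, regions)),
                 setdiff(unique(regions), "Snk"), "Snk")
}

test_that("majority source region wins with its support fraction", {
  tr <- region_tree("((S1:1,S2:2,S3:1,K1:1):1,S4:2);",
                    c("S1", "S2", "S3", "S4", "K1"),
                    c("West", "West", "Eastern", "West", "Snk"))
  cl <- build_clusters(tr, f = 1)
  att <- infer_source_region(cl, tr)
  expect_equal(att$region, "West")
  expect_equal(att$support, 2 / 3)
  expect_false(att$ambiguous)
})

test_that("count ties break by mean mutation distance, then lexicographically", {
  # West at distance 1, Eastern at distance 3
  tr <- region_tree("((S1:1,S2:3,K1:1):1,S3:2);",
                    c("S1", "S2", "S3", "K1"),
                    c("West", "Eastern", "West", "Snk"))
  cl <- build_clusters(tr, f = 1)
  att <- infer_source_region(cl, tr)
  expect_equal(att$region, "West")
  expect_false(att$ambiguous)

  # equal counts at equal distances: lexicographic winner, flagged
  tr2 <- region_tree("((S1:2,S2:2,K1:1):1,S3:2);",
                     c("S1", "S2", "S3", "K1"),
                     c("West", "Eastern", "West", "Snk"))
  cl2 <- build_clusters(tr2, f = 1)
  att2 <- infer_source_region(cl2, tr2)
  expect_equal(att2$region, "Eastern")
  expect_true(att2$ambiguous)
})

test_that("composition matrices are column-stochastic per epoch", {
  d <- dplyr::bind_rows(
    tibble::tibble(founder_id = "a", node = 1L, n = 3L, rho = 0, sigma_rho = 0,
                   age_years = 8000, sigma_years = 100, sink_samples = list("x")),
    tibble::tibble(founder_id = "b", node = 2L, n = 1L, rho = 0, sigma_rho = 0,
                   age_years = 500, sigma_years = 100, sink_samples = list("y")))
  class(d) <- c("dated_clusters", class(d))
  al <- allocate_epochs(d)
  att <- tibble::tibble(founder_id = c("a", "b"),
                        region = c("West", "Eastern"),
                        support = 1, ambiguous = FALSE, n_source_leaves = 3L)
  comp <- epoch_region_composition(att, al)
  expect_equal(sum(comp$prehistoric), 1, tolerance = 1e-9)
  expect_equal(sum(comp$historical), 1, tolerance = 1e-9)
  # posteriors here are near-degenerate: identity-like composition
  expect_gt(comp$prehistoric[comp$region == "West"], 0.999)
  expect_gt(comp$historical[comp$region == "Eastern"], 0.999)

  # same region, sizes 3:1, both prehistoric: weighted tally
  att_same <- dplyr::mutate(att, region = c("West", "Eastern"))
  d2 <- dplyr::mutate(d, age_years = 8000)
  class(d2) <- class(d)
  comp2 <- epoch_region_composition(att_same, allocate_epochs(d2))
  expect_equal(comp2$prehistoric[comp2$region == "West"], 0.75, tolerance = 1e-9)
  expect_equal(comp2$prehistoric[comp2$region == "Eastern"], 0.25, tolerance = 1e-9)
})

test_that("population frequencies are ratios of allocated lineages to totals", {
  # 10-sample population, 2 lineages fully allocated prehistoric
  md <- meta_for(c(paste0("P", 1:10), "S1", "S2"),
                 c(rep("Snk", 10), "Src", "Src"),
                 c(rep("popA", 10), "srcpop", "srcpop"))
  cl <- tibble::tibble(founder_id = "f1", node = 1L, n = 2L,
                       sink_samples = list(c("P1", "P2")),
                       path_counts = list(c(0, 0)), branches = list(NULL))
  d <- tibble::tibble(founder_id = "f1", node = 1L, n = 2L, rho = 0, sigma_rho = 0,
                      age_years = 8000, sigma_years = 50, sink_samples = cl$sink_samples)
  class(d) <- c("dated_clusters", class(d))
  al <- allocate_epochs(d)
  pf <- population_epoch_frequency(md, cl, al)
  a <- pf[pf$population == "popA", ]
  expect_equal(a$prehistoric, 0.2, tolerance = 1e-9)
  expect_equal(a$historical, 0, tolerance = 1e-9)
  expect_equal(a$prehistoric + a$historical + a$unassigned, 1, tolerance = 1e-9)
  # population with no analysed lineages: zero everywhere
  s <- pf[pf$population == "srcpop", ]
  expect_equal(s$prehistoric + s$historical, 0)
  expect_error(population_epoch_frequency(md, cl, al, populations = "nope"),
               "absent")

  # half-and-half posterior splits evenly: 4 of 8 samples at (0.5, 0.5)
  md2 <- meta_for(paste0("Q", 1:8), rep("Snk", 8), rep("popB", 8))
  cl2 <- dplyr::mutate(cl, sink_samples = list(paste0("Q", 1:4)), n = 4L)
  d2 <- dplyr::mutate(d, age_years = 4250, sigma_years = 900,
                      sink_samples = cl2$sink_samples, n = 4L)
  class(d2) <- class(d)
  pf2 <- population_epoch_frequency(md2, cl2, allocate_epochs(d2))
  expect_equal(pf2$prehistoric, 0.25, tolerance = 1e-9)
  expect_equal(pf2$historical, 0.25, tolerance = 1e-9)
})

test_that("attribution recovers the true region on clean synthetic clades", {
  acc <- vapply(1:20, function(s) {
    rep <- simulate_and_run(sim_config(seed = 3000 + s))
    rep$recovery$region_accuracy
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})
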