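test_that("male differences count only jointly-called positions", {
  m1 <- fake_consensus("m1", list(sc = c("A", "C", "G", "T", "N", "A", "-")))
  m2 <- fake_consensus("m2", list(sc = c("A", "C", "T", "T", "A", "N", "A")))
  d <- pairwise_male_differences(m1, m2)
  # positions 5-7 carry N or missing in one male: excluded entirely
  expect_identical(d$n_joint, 4L)
  expect_identical(d$n_diff, 1L)
  expect_equal(d$diff_per_bp, 0.25)

  same <- pairwise_male_differences(m1, m1)
  expect_identical(same$n_diff, 0L)

  empty <- fake_consensus("m3", list(sc = rep("-", 7)))
  dropped <- pairwise_male_differences(m1, empty)
  expect_identical(nrow(dropped), 0L)
  expect_identical(attr(dropped, "dropped"), "sc")
})

test_that("corrected differences subtract per-scaffold diversity", {
  diffs <- tibble::tibble(scaffold = c("a", "b", "c", "d"),
                          n_joint = 1000L, n_diff = c(5L, 0L, 5L, 2L),
                          diff_per_bp = c(0.005, 0, 0.0049, 0.002))
  pis <- tibble::tibble(scaffold = c("a", "b", "c"),
                        pi = c(0.005, 0.004, 0.005))
  cd <- corrected_difference(diffs, pis)
  expect_equal(cd$cd, c(0, -0.004, -1e-4), tolerance = 1e-12)
  expect_identical(attr(cd, "dropped"), "d")
})

test_that("scaffold filters use strict length and inclusive polymorphism cutoffs", {
  tbl <- tibble::tibble(scaffold = c("a", "b", "c", "d"),
                        length = c(100000, 150000, 150000, 150000),
                        S = c(500L, 49L, 200L, 50L))
  kept <- apply_scaffold_filters(tbl, min_length = 1e5, min_S = 50)
  expect_identical(kept$scaffold, c("c", "d"))
})

test_that("the EM fit recovers mixture parameters with a monotone log-likelihood", {
  withr::with_seed(51, {
    x <- c(-0.005 + 0.001 * rt(850, df = 5), 0 + 0.001 * rt(150, df = 5))
  })
  fit <- fit_t_mixture(x, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$mu[1], fit$mu[2])
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_lt(abs(fit$mu[1] - -0.005), 2e-4)
  expect_lt(abs(fit$mu[2] - 0), 4e-4)
  expect_lt(abs(fit$w[1] - 0.85), 0.08)
  # deterministic for a fixed restart seed
  fit2 <- fit_t_mixture(x, seed = 1)
  expect_identical(fit$loglik, fit2$loglik)
  td <- tidy(fit)
  expect_identical(td$component, c("autosome", "X"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("degenerate or insufficient data are flagged or refused", {
  expect_error(fit_t_mixture(rnorm(10)), class = "aphidpop_input_error")
  expect_error(fit_t_mixture(rep(0.5, 30)), class = "aphidpop_input_error")
  withr::with_seed(52, {
    single <- -0.005 + 1e-4 * rt(400, df = 10)
  })
  fit <- suppressWarnings(fit_t_mixture(single, seed = 2))
  expect_true(fit$degenerate || abs(diff(fit$mu)) < 5e-4)
})

test_that("posterior X probability is monotone with the expected limits", {
  fit <- structure(list(w = c(0.85, 0.15), mu = c(-0.005, 0),
                        sigma = c(0.001, 0.001), nu = c(5, 5),
                        loglik = 0, n = 0, iterations = 0, converged = TRUE),
                   class = "t_mixture_fit")
  grid <- seq(-0.005, 0, length.out = 101)
  p <- x_probability(grid, fit)
  # monotone non-decreasing between the component modes
  expect_true(all(diff(p) >= -1e-12))
  # far below the autosomal mode the autosomal component dominates; with
  # equal degrees of freedom the posterior tends to the mixing weights in
  # the extreme tails (both tails decay at the same polynomial rate), so
  # the informative region is around and between the modes
  expect_lt(x_probability(fit$mu[1] - 6 * fit$sigma[1], fit), 0.05)
  expect_lt(x_probability(fit$mu[1], fit), 0.5)
  expect_gt(x_probability(fit$mu[2], fit), 0.5)
  # log-space evaluation cannot underflow far from both modes
  extreme <- x_probability(c(-5, 5), fit)
  expect_true(all(is.finite(extreme) & extreme >= 0 & extreme <= 1))
})

test_that("classification labels follow the posterior threshold exactly", {
  fit <- structure(list(w = c(0.5, 0.5), mu = c(-1, 1), sigma = c(1, 1),
                        nu = c(5, 5)), class = "t_mixture_fit")
  tbl <- tibble::tibble(scaffold = c("a", "b", "c"), cd = c(-2, 2, 0),
                        length = c(10, 10, 10))
  calls <- classify_scaffolds(tbl, fit)
  expect_identical(calls$label, c("A", "X", "unresolved"))
  smry <- attr(calls, "summary")
  expect_identical(sort(smry$label), c("A", "X", "unresolved"))
})

test_that("the depth-ratio check flags one-class classifications", {
  depth <- tibble::tibble(scaffold = c("a", "b"), mean_depth = c(10, 5))
  calls <- tibble::tibble(scaffold = c("a", "b"), label = c("A", "X"))
  ok <- coverage_ratio_check(depth, calls)
  expect_equal(ok$ratio, 2)
  all_a <- tibble::tibble(scaffold = c("a", "b"), label = c("A", "A"))
  flagged <- coverage_ratio_check(depth, all_a)
  expect_true(is.na(flagged$ratio))
  expect_false(flagged$defined)
})

test_that("verification cross-tabs reproduce concordance fractions", {
  pred <- tibble::tibble(scaffold = sprintf("s%02d", 1:52),
                         label = rep(c("X", "A"), c(27, 25)))
  verified <- tibble::tibble(scaffold = sprintf("s%02d", 1:52),
                             label = c(rep("X", 27), rep("A", 21), rep("X", 4)))
  ct <- verification_crosstab(pred, verified)
  conc <- ct$concordance
  expect_equal(conc$concordance[conc$class == "X"], 1.0)
  expect_equal(conc$concordance[conc$class == "A"], 0.84)
  perfect <- verification_crosstab(pred, pred)
  expect_true(all(perfect$concordance$concordance == 1))
  expect_error(
    verification_crosstab(pred, tibble::tibble(scaffold = "zz", label = "X")),
    class = "aphidpop_input_error")
})
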