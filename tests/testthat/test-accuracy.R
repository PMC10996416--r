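# Grid-inversion oracle for the exact binomial interval: scan p on a fine
# grid and invert the tail probabilities directly.
cp_grid_oracle <- function(k, n, level = 0.95, grid = 1e-4) {
  alpha <- 1 - level
  p <- seq(grid, 1 - grid, by = grid)
  lower <- if (k == 0) 0 else {
    min(p[stats::pbinom(k - 1, n, p, lower.tail = FALSE) >= alpha / 2])
  }
  upper <- if (k == n) 1 else {
    max(p[stats::pbinom(k, n, p) >= alpha / 2])
  }
  c(lower = lower, upper = upper)
}

test_that("Clopper-Pearson agrees with binom.test and the grid oracle", {
  cases <- list(c(57, 172), c(3, 27), c(1, 10), c(19, 20), c(100, 1400))
  for (cs in cases) {
    ci <- clopper_pearson(cs[1], cs[2])
    bt <- stats::binom.test(cs[1], cs[2])$conf.int
    expect_equal(ci$lower, bt[1], tolerance = 1e-10)
    expect_equal(ci$upper, bt[2], tolerance = 1e-10)
    g <- cp_grid_oracle(cs[1], cs[2])
    expect_lt(abs(ci$lower - g["lower"]), 2e-4)
    expect_lt(abs(ci$upper - g["upper"]), 2e-4)
  }
})

test_that("Clopper-Pearson endpoints are exact at the boundary counts", {
  expect_identical(clopper_pearson(0, 10)$lower, 0)
  expect_identical(clopper_pearson(10, 10)$upper, 1)
  ci <- clopper_pearson(0, 10)
  expect_lte(ci$point, ci$upper)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(1, 10, level = 1), "level")
})

test_that("exact interval coverage is at least nominal (conservatism)", {
  # empirical coverage can fall below the true coverage only by Monte-Carlo
  # noise; allow 3 binomial SEs below the nominal level
  n_rep <- 2000
  p_true <- 0.3
  for (n in c(20, 172)) {
    ks <- withr::with_seed(400 + n, stats::rbinom(n_rep, n, p_true))
    lo <- ifelse(ks == 0, 0, stats::qbeta(0.025, ks, n - ks + 1))
    hi <- ifelse(ks == n, 1, stats::qbeta(0.975, ks + 1, n - ks))
    coverage <- mean(lo <= p_true & p_true <= hi)
    expect_gte(coverage, 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep))
  }
})

test_that("sensitivity/specificity points match printed percentages and sit in their intervals", {
  ct <- confusion_table(tp = 57, fp = 8, fn = 115, tn = 1224)
  se <- sensitivity(ct)
  sp <- specificity(ct)
  expect_equal(round(100 * se$point, 1), 33.1)
  expect_equal(round(100 * sp$point, 1), 99.4)
  expect_true(se$lower <= se$point && se$point <= se$upper)
  expect_true(sp$lower <= sp$point && sp$point <= sp$upper)

  ai_rib <- confusion_table(tp = 143, fp = 75, fn = 205, tn = 977)
  expect_equal(round(100 * specificity(ai_rib)$point, 1), 92.9)

  expect_equal(sensitivity(confusion_table(0, 1, 5, 3))$point, 0)
  expect_equal(sensitivity(confusion_table(7, 1, 0, 3))$point, 1)
  expect_equal(specificity(confusion_table(1, 0, 1, 3))$point, 1)
  expect_error(sensitivity(confusion_table(0, 2, 0, 3)), "no truth-positive")
})

test_that("prevalence reproduces cohort proportions", {
  ct <- confusion_table(tp = 57, fp = 8, fn = 115, tn = 1224)
  expect_equal(round(100 * prevalence(ct)$point, 1), 12.3)
  rib <- confusion_table(tp = 113, fp = 13, fn = 236, tn = 1042)
  expect_equal(round(100 * prevalence(rib)$point, 1), 24.9)
  expect_equal(prevalence(confusion_table(0, 1, 0, 9))$point, 0)
})

test_that("Cohen's kappa matches the independent oracle on random tables", {
  skip_if_not_installed("e1071")
  tabs <- withr::with_seed(7, replicate(25, rmultinom(1, 500, runif(4, 0.05, 1)),
                                        simplify = FALSE))
  for (tb in tabs) {
    ct <- confusion_table(tb[1], tb[2], tb[3], tb[4])
    m <- matrix(c(tb[1], tb[3], tb[2], tb[4]), 2, 2)
    expect_equal(cohens_kappa(ct)$kappa,
                 e1071::classAgreement(m)$kappa, tolerance = 1e-10)
  }
})

test_that("kappa respects its defining identities and invariances", {
  # chance agreement and perfect agreement
  expect_equal(cohens_kappa(confusion_table(1, 1, 1, 1))$kappa, 0)
  expect_equal(cohens_kappa(confusion_table(5, 0, 0, 9))$kappa, 1)
  est <- cohens_kappa(confusion_table(57, 8, 115, 1224))
  expect_equal(est$kappa, (est$p_o - est$p_e) / (1 - est$p_e))

  tabs <- withr::with_seed(8, replicate(50, rmultinom(1, 200, runif(4, 0.02, 1)),
                                        simplify = FALSE))
  for (tb in tabs) {
    k <- cohens_kappa(confusion_table(tb[1], tb[2], tb[3], tb[4]))$kappa
    expect_gte(k, -1); expect_lte(k, 1)
    # simultaneous positive<->negative label swap for both raters
    k_swap <- cohens_kappa(confusion_table(tb[4], tb[3], tb[2], tb[1]))$kappa
    expect_equal(k, k_swap, tolerance = 1e-12)
  }
})

test_that("degenerate tables give an explicit undefined kappa", {
  est <- cohens_kappa(confusion_table(5, 0, 0, 0))
  expect_true(est$degenerate)
  expect_true(is.na(est$kappa))
  expect_error(kappa_interval(confusion_table(5, 0, 0, 0)), "undefined")
})

test_that("kappa from counts equals kappa from per-case call vectors", {
  skip_if_not_installed("e1071")
  for (seed in 1:5) {
    ds <- random_dataset(300, seed)
    rec <- ds$records
    for (r in ds$readers) {
      k_pkg <- cohens_kappa(confusion_from_calls(ds, r, ds$findings[1]))$kappa
      tab <- table(factor(rec[[r]], c(0, 1)), factor(rec$truth, c(0, 1)))
      expect_equal(k_pkg, e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
    }
  }
})

test_that("kappa intervals are deterministic under seed and methods agree", {
  ct <- confusion_table(tp = 160, fp = 20, fn = 180, tn = 1040)
  b1 <- kappa_interval(ct, "bootstrap", n_boot = 2000, seed = 5)
  b2 <- kappa_interval(ct, "bootstrap", n_boot = 2000, seed = 5)
  expect_identical(b1$ci, b2$ci)

  a <- kappa_interval(ct, "analytic")
  b <- kappa_interval(ct, "bootstrap", n_boot = 5000, seed = 9)
  expect_lt(abs(a$ci$lower - b$ci$lower), 0.02)
  expect_lt(abs(a$ci$upper - b$ci$upper), 0.02)

  perfect <- confusion_table(tp = 12, fp = 0, fn = 0, tn = 28)
  pb <- kappa_interval(perfect, "bootstrap", n_boot = 500, seed = 2)
  expect_equal(pb$ci$lower, 1)
  expect_equal(pb$ci$upper, 1)
})

test_that("implied kappa matches the sample kappa of the expected-count table", {
  for (pars in list(c(0.123, 0.331, 0.994), c(0.25, 0.41, 0.93),
                    c(0.5, 0.9, 0.9))) {
    prev <- pars[1]; se <- pars[2]; sp <- pars[3]
    N <- 1e7
    cells <- round(N * c(prev * se, (1 - prev) * (1 - sp),
                         prev * (1 - se), (1 - prev) * sp))
    k_tab <- cohens_kappa(confusion_table(cells[1], cells[2],
                                          cells[3], cells[4]))$kappa
    expect_lt(abs(implied_kappa(prev, se, sp) - k_tab), 1e-4)
  }
})
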