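test_that("comparing a reader with itself gives a null difference", {
  rec <- toy_six_cases()$records
  rec$ai <- rec$radiologist
  ds <- study_dataset(rec)
  cmp <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", "pneumothorax",
                                     n_boot = 500, seed = 4)
  expect_equal(cmp$delta_median, 0)
  expect_equal(cmp$delta_lower, 0)
  expect_equal(cmp$delta_upper, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("bootstrap is deterministic in the seed and symmetric in the readers", {
  ds <- random_dataset(400, 31)
  a <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                   n_boot = 1000, seed = 17)
  b <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                   n_boot = 1000, seed = 17)
  expect_identical(a[c("delta_median", "delta_lower", "delta_upper", "p_value")],
                   b[c("delta_median", "delta_lower", "delta_upper", "p_value")])
  c_ <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                    n_boot = 1000, seed = 18)
  expect_false(identical(a$delta_median, c_$delta_median))

  # exchanging the readers under the same seed negates the difference and
  # preserves the p-value exactly (identical case draws)
  sw <- paired_bootstrap_kappa_diff(ds, "ai", "radiologist", ds$findings[1],
                                    n_boot = 1000, seed = 17)
  expect_equal(sw$delta_median, -a$delta_median, tolerance = 1e-12)
  expect_equal(sw$delta_lower, -a$delta_upper, tolerance = 1e-12)
  expect_equal(sw$delta_upper, -a$delta_lower, tolerance = 1e-12)
  expect_identical(sw$p_value, a$p_value)
})

test_that("p-value and percentile interval give the same decision at 0.05", {
  for (seed in c(2, 12, 22, 32)) {
    ds <- random_dataset(300, seed)
    cmp <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                       n_boot = 2000, seed = seed)
    excludes_zero <- cmp$delta_lower > 0 || cmp$delta_upper < 0
    expect_equal(cmp$p_value <= 0.05, excludes_zero)
  }
})

test_that("percentile interval narrows as the cohort grows", {
  widths <- sapply(c(200, 1400, 5000), function(n) {
    cfg <- sim_config(n, prevalence = 0.2, se_a = 0.4, sp_a = 0.98,
                      se_b = 0.6, sp_b = 0.97, dep_pos = 0.3, dep_neg = 0.1,
                      seed = 77)
    ds <- simulate_dataset(cfg)
    cmp <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", "finding1",
                                       n_boot = 1000, seed = 5)
    cmp$delta_upper - cmp$delta_lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("doubling n_boot moves the median only by resampling noise", {
  ds <- random_dataset(600, 55)
  m1 <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                    n_boot = 2000, seed = 6)$delta_median
  m2 <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", ds$findings[1],
                                    n_boot = 4000, seed = 6)$delta_median
  expect_lt(abs(m1 - m2), 2 / sqrt(2000))
})

test_that("intersection policy drops unpaired cases; per_reader keeps them", {
  cfg <- sim_config(500, prevalence = 0.3, se_a = 0.6, sp_a = 0.95,
                    se_b = 0.6, sp_b = 0.95, failure_rate_b = 0.1, seed = 91)
  ds <- simulate_dataset(cfg)
  n_unavail <- sum(is.na(ds$records$ai))
  expect_gt(n_unavail, 0)
  cmp_int <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", "finding1",
                                         n_boot = 200, seed = 1,
                                         case_policy = "intersection")
  cmp_per <- paired_bootstrap_kappa_diff(ds, "radiologist", "ai", "finding1",
                                         n_boot = 200, seed = 1,
                                         case_policy = "per_reader")
  expect_equal(cmp_int$n_cases, 500L - n_unavail)
  expect_equal(cmp_per$n_cases, 500L)
})

test_that("hybrid OR combination follows the truth table of OR", {
  ds <- study_dataset(tibble::tibble(
    case_id = paste0("c", 1:5), finding = "f",
    truth       = c(1L, 1L, 0L, 0L, 1L),
    radiologist = c(1L, 0L, 0L, 1L, NA),
    ai          = c(0L, 0L, 0L, 1L, 1L)
  ))
  h <- hybrid_or(ds, "radiologist", "ai", "f")
  expect_equal(h$calls$combined, c(1L, 0L, 0L, 1L, 1L))
  expect_equal(h$confusion$tp, 2L)
  expect_equal(h$confusion$fp, 1L)
})

test_that("hybrid reader dominates each constituent in sensitivity and is dominated in specificity", {
  for (seed in 1:50) {
    ds <- random_dataset(200, seed + 100)
    f <- ds$findings[1]
    h <- hybrid_or(ds, "radiologist", "ai", f)
    se_a <- sensitivity(confusion_from_calls(ds, "radiologist", f))$point
    se_b <- sensitivity(confusion_from_calls(ds, "ai", f))$point
    sp_a <- specificity(confusion_from_calls(ds, "radiologist", f))$point
    sp_b <- specificity(confusion_from_calls(ds, "ai", f))$point
    expect_gte(h$sensitivity$point, max(se_a, se_b))
    expect_lte(h$specificity$point, min(sp_a, sp_b))
  }
})

test_that("hybrid sensitivity matches the conditional-independence closed form", {
  se_a <- 0.33; se_b <- 0.55
  cfg <- sim_config(1e5, prevalence = 0.3, se_a = se_a, sp_a = 0.99,
                    se_b = se_b, sp_b = 0.97, dep_pos = 0, dep_neg = 0,
                    seed = 13)
  ds <- simulate_dataset(cfg)
  h <- hybrid_or(ds, "radiologist", "ai", "finding1")
  expect_lt(abs(h$sensitivity$point - (se_a + se_b - se_a * se_b)), 0.015)
})

test_that("compare_all is reproducible, annotates failures, and nulls out identical readers", {
  cfg <- study_sim_config(n_cases = 300, seed = 61)
  ds <- simulate_dataset(cfg)
  t1 <- compare_all(ds, "radiologist", "ai", n_boot = 300, seed = 9)
  t2 <- compare_all(ds, "radiologist", "ai", n_boot = 300, seed = 9)
  expect_equal(nrow(t1), 7L)
  expect_identical(t1, t2)
  expect_true(all(is.na(t1$error) | nzchar(t1$error)))

  rec <- toy_six_cases()$records
  rec$ai <- rec$radiologist
  same <- study_dataset(rec)
  ts <- compare_all(same, "radiologist", "ai", n_boot = 200, seed = 3)
  expect_true(all(ts$p_value == 1))

  # a finding with no paired cases yields an annotated row, not an abort
  rec2 <- rbind(
    tibble::tibble(case_id = paste0("c", 1:6), finding = "ok",
                   truth = c(1L, 1L, 0L, 0L, 1L, 0L),
                   radiologist = c(1L, 0L, 0L, 1L, 1L, 0L),
                   ai = c(1L, 1L, 0L, 0L, 0L, 1L)),
    tibble::tibble(case_id = paste0("c", 1:6), finding = "broken",
                   truth = c(1L, 1L, 0L, 0L, 1L, 0L),
                   radiologist = c(1L, 0L, 0L, 1L, 1L, 0L),
                   ai = rep(NA_integer_, 6))
  )
  ds2 <- study_dataset(rec2)
  tb <- compare_all(ds2, "radiologist", "ai", n_boot = 200, seed = 3)
  expect_equal(nrow(tb), 2L)
  expect_true(is.na(tb$error[tb$finding == "ok"]))
  expect_false(is.na(tb$error[tb$finding == "broken"]))
})
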