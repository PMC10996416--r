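#' Paired bootstrap for the difference in Cohen's kappa between two readers
#'
#' Resamples cases (the sampling unit) with replacement, keeping both
#' readers' calls and the reference label together within each case, and
#' computes `kappa_B - kappa_A` on every replicate. Because each case is
#' fully described by its joint `(truth, call_A, call_B)` cell, case
#' resampling is carried out as a multinomial draw over the joint cell
#' counts, which is distributionally identical and fast. Returns the
#' replicate median, the 2.5th/97.5th percentiles and a two-sided p-value
#' obtained by inverting the bootstrap distribution:
#' `p = 2 * min(Pr(delta <= 0), Pr(delta >= 0))`, clamped to
#' `[1/n_boot, 1]`, so `p <= 0.05` coincides with the 95% percentile
#' interval excluding zero.
#'
#' Replicates in which either reader's kappa is undefined (a degenerate
#' resampled table) are dropped from the percentiles and counted in
#' `n_degenerate`; more than 10% degenerate replicates is an error.
#'
#' @param ds a [study_dataset].
#' @param reader_a,reader_b reader names; the difference is
#'   `kappa(reader_b) - kappa(reader_a)`.
#' @param finding finding name.
#' @param n_boot number of bootstrap iterations (default 10000).
#' @param seed integer seed; results are deterministic given the seed, and
#'   swapping `reader_a`/`reader_b` under the same seed reuses the same
#'   case draws (so the difference exactly negates).
#' @param case_policy `"intersection"` (default) restricts to cases where
#'   both readers produced output, so pairing is defined for every resampled
#'   case; `"per_reader"` keeps all cases and computes each reader's kappa
#'   on its own available subset within each replicate (reproducing
#'   marginal denominators that differ between readers).
#' @return An object of class `kappa_comparison`: list with `delta_median`,
#'   `delta_lower`, `delta_upper`, `p_value`, `n_boot`, `seed`,
#'   `n_degenerate`, observed `kappa_a`/`kappa_b`, `n_cases`, plus the
#'   reader/finding labels and policy.
#' @export
paired_bootstrap_kappa_diff <- function(ds, reader_a, reader_b, finding,
                                        n_boot = 10000, seed = 1,
                                        case_policy = c("intersection", "per_reader")) {
  stopifnot(inherits(ds, "study_dataset"))
  case_policy <- match.arg(case_policy)
  for (r in c(reader_a, reader_b)) {
    if (!r %in% ds$readers) stop("unknown reader: ", r, call. = FALSE)
  }
  if (!finding %in% ds$findings) {
    stop("unknown finding: ", finding, call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)

  rec <- ds$records[ds$records$finding == finding, ]
  # canonical reader order (by the dataset registry, not argument order) so
  # identical seeds give identical case draws regardless of which reader is
  # "A": exchanging the arguments then exactly negates the difference.
  regs <- ds$readers[ds$readers %in% c(reader_a, reader_b)]
  if (length(regs) == 1) regs <- c(regs, regs)  # reader compared to itself
  c1 <- rec[[regs[1]]]
  c2 <- rec[[regs[2]]]
  truth <- rec$truth

  if (case_policy == "intersection") {
    keep <- !is.na(c1) & !is.na(c2)
    c1 <- c1[keep]; c2 <- c2[keep]; truth <- truth[keep]
  }
  n_cases <- length(truth)
  if (n_cases < 2) {
    stop("fewer than 2 cases available under policy '", case_policy,
         "' for finding '", finding, "'", call. = FALSE)
  }

  # joint (truth, call1, call2) cells; unavailable coded as its own state
  code <- function(x) ifelse(is.na(x), 2L, x)
  cell <- truth * 9L + code(c1) * 3L + code(c2)
  counts <- tabulate(cell + 1L, nbins = 18L)
  present <- which(counts > 0)
  counts <- counts[present]
  cell_truth <- (present - 1L) %/% 9L
  cell_c1 <- ((present - 1L) %% 9L) %/% 3L
  cell_c2 <- (present - 1L) %% 3L

  draws <- withr::with_seed(seed,
                            stats::rmultinom(n_boot, n_cases, counts))

  cells_for <- function(call_state) {
    m <- rbind(
      tp = as.integer(cell_truth == 1L & call_state == 1L),
      fp = as.integer(cell_truth == 0L & call_state == 1L),
      fn = as.integer(cell_truth == 1L & call_state == 0L),
      tn = as.integer(cell_truth == 0L & call_state == 0L)
    )
    m %*% draws  # 4 x n_boot
  }
  k_of <- function(cells) .kappa_cells(cells[1, ], cells[2, ],
                                       cells[3, ], cells[4, ])
  kappa1 <- k_of(cells_for(cell_c1))
  kappa2 <- k_of(cells_for(cell_c2))
  ka <- if (reader_a == regs[1]) kappa1 else kappa2
  kb <- if (reader_b == regs[2]) kappa2 else kappa1

  delta <- kb - ka
  n_degen <- sum(is.na(delta))
  if (n_degen == n_boot) {
    stop("all bootstrap replicates degenerate (kappa undefined)",
         call. = FALSE)
  }
  if (n_degen / n_boot > 0.10) {
    stop("more than 10% of bootstrap replicates have undefined kappa (",
         n_degen, "/", n_boot, ")", call. = FALSE)
  }
  delta <- delta[!is.na(delta)]

  q <- stats::quantile(delta, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  p <- 2 * min(mean(delta <= 0), mean(delta >= 0))
  p <- min(1, max(1 / n_boot, p))

  # observed kappas on the analysis cohort (each reader on its available
  # subset of the retained cases)
  obs_kappa <- function(call) {
    ok <- !is.na(call)
    .kappa_cells(sum(ok & truth == 1 & call == 1),
                 sum(ok & truth == 0 & call == 1),
                 sum(ok & truth == 1 & call == 0),
                 sum(ok & truth == 0 & call == 0))
  }
  obs1 <- obs_kappa(c1)
  obs2 <- obs_kappa(c2)
  structure(
    list(delta_median = q[2], delta_lower = q[1], delta_upper = q[3],
         p_value = p, n_boot = n_boot, seed = seed,
         n_degenerate = n_degen,
         kappa_a = if (reader_a == regs[1]) obs1 else obs2,
         kappa_b = if (reader_b == regs[2]) obs2 else obs1,
         reader_a = reader_a, reader_b = reader_b, finding = finding,
         n_cases = n_cases, case_policy = case_policy),
    class = "kappa_comparison"
  )
}

#' @export
print.kappa_comparison <- function(x, ...) {
  cat(sprintf(
    "<kappa_comparison> %s: kappa(%s) - kappa(%s)\n  median %.3f (%.3f-%.3f), p = %.4g, n_boot = %d, n = %d cases\n",
    x$finding, x$reader_b, x$reader_a, x$delta_median, x$delta_lower,
    x$delta_upper, x$p_value, x$n_boot, x$n_cases))
  if (x$n_degenerate > 0) {
    cat("  degenerate replicates dropped:", x$n_degenerate, "\n")
  }
  invisible(x)
}

#' OR-rule hybrid reader
#'
#' Combines two readers into one: a finding is called present on a case if
#' either reader calls it present. When one reader's call is unavailable the
#' available reader decides; when both are unavailable the combined call is
#' unavailable and is handled by `unavailable_policy` when tabulating. This
#' models a workflow in which an algorithmic flag is added on top of the
#' human report: sensitivity can only rise and specificity can only fall
#' relative to each constituent reader.
#'
#' @inheritParams paired_bootstrap_kappa_diff
#' @param unavailable_policy passed to the confusion tabulation of the
#'   combined calls.
#' @param level confidence level for the accuracy intervals.
#' @return An object of class `hybrid_result`: list with `calls` (tibble of
#'   `case_id`, `truth`, `combined`), `confusion`, `sensitivity`,
#'   `specificity`.
#' @export
hybrid_or <- function(ds, reader_a, reader_b, finding,
                      unavailable_policy = c("drop", "count_negative"),
                      level = 0.95) {
  stopifnot(inherits(ds, "study_dataset"))
  unavailable_policy <- match.arg(unavailable_policy)
  for (r in c(reader_a, reader_b)) {
    if (!r %in% ds$readers) stop("unknown reader: ", r, call. = FALSE)
  }
  if (!finding %in% ds$findings) {
    stop("unknown finding: ", finding, call. = FALSE)
  }
  rec <- ds$records[ds$records$finding == finding, ]
  combined <- pmax(rec[[reader_a]], rec[[reader_b]], na.rm = TRUE)

  calls <- tibble::tibble(case_id = rec$case_id, truth = rec$truth,
                          combined = combined)
  hybrid_ds <- study_dataset(tibble::tibble(
    case_id = rec$case_id, finding = finding, truth = rec$truth,
    hybrid = combined
  ))
  ct <- confusion_from_calls(hybrid_ds, "hybrid", finding,
                             unavailable_policy = unavailable_policy)
  structure(
    list(calls = calls, confusion = ct,
         sensitivity = sensitivity(ct, level),
         specificity = specificity(ct, level),
         reader_a = reader_a, reader_b = reader_b, finding = finding,
         unavailable_policy = unavailable_policy),
    class = "hybrid_result"
  )
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf("<hybrid_result> %s: %s OR %s\n", x$finding, x$reader_a,
              x$reader_b))
  cat("  sensitivity: "); print(x$sensitivity)
  cat("  specificity: "); print(x$specificity)
  invisible(x)
}

#' Per-finding comparison of two readers
#'
#' Runs [paired_bootstrap_kappa_diff()] and [hybrid_or()] for every finding
#' in the dataset and returns one row per finding. Each finding uses its own
#' deterministically derived seed (`seed + finding index`), so per-finding
#' results do not depend on the order findings are processed. A finding
#' whose computation fails contributes an annotated row (message in the
#' `error` column) rather than aborting the whole table.
#'
#' @inheritParams paired_bootstrap_kappa_diff
#' @param unavailable_policy policy for the marginal and hybrid tabulations.
#' @param level confidence level for accuracy intervals.
#' @return A tibble with one row per finding: observed kappas, bootstrap
#'   difference summary, p-value, hybrid sensitivity/specificity and the
#'   per-finding seed.
#' @export
compare_all <- function(ds, reader_a, reader_b, n_boot = 10000, seed = 1,
                        case_policy = c("intersection", "per_reader"),
                        unavailable_policy = c("drop", "count_negative"),
                        level = 0.95) {
  stopifnot(inherits(ds, "study_dataset"))
  case_policy <- match.arg(case_policy)
  unavailable_policy <- match.arg(unavailable_policy)
  rows <- lapply(seq_along(ds$findings), function(i) {
    f <- ds$findings[i]
    seed_i <- seed + i
    tryCatch({
      cmp <- paired_bootstrap_kappa_diff(ds, reader_a, reader_b, f,
                                         n_boot = n_boot, seed = seed_i,
                                         case_policy = case_policy)
      hyb <- hybrid_or(ds, reader_a, reader_b, f,
                       unavailable_policy = unavailable_policy,
                       level = level)
      ka <- cohens_kappa(confusion_from_calls(ds, reader_a, f,
                                              unavailable_policy))$kappa
      kb <- cohens_kappa(confusion_from_calls(ds, reader_b, f,
                                              unavailable_policy))$kappa
      tibble::tibble(
        finding = f, n_cases = cmp$n_cases,
        kappa_a = ka, kappa_b = kb,
        delta_median = cmp$delta_median, delta_lower = cmp$delta_lower,
        delta_upper = cmp$delta_upper, p_value = cmp$p_value,
        n_degenerate = cmp$n_degenerate,
        hybrid_sens = hyb$sensitivity$point,
        hybrid_sens_lower = hyb$sensitivity$lower,
        hybrid_sens_upper = hyb$sensitivity$upper,
        hybrid_spec = hyb$specificity$point,
        hybrid_spec_lower = hyb$specificity$lower,
        hybrid_spec_upper = hyb$specificity$upper,
        seed = seed_i, error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(
        finding = f, n_cases = NA_integer_,
        kappa_a = NA_real_, kappa_b = NA_real_,
        delta_median = NA_real_, delta_lower = NA_real_,
        delta_upper = NA_real_, p_value = NA_real_,
        n_degenerate = NA_integer_,
        hybrid_sens = NA_real_, hybrid_sens_lower = NA_real_,
        hybrid_sens_upper = NA_real_,
        hybrid_spec = NA_real_, hybrid_spec_lower = NA_real_,
        hybrid_spec_upper = NA_real_,
        seed = seed_i, error = conditionMessage(e)
      )
    })
  })
  do.call(rbind, rows)
}
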