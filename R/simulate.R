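#' Configuration for a synthetic paired-reader cohort
#'
#' Describes a rectangular cohort of `n_cases` cases scored for one or more
#' findings by two readers. Per finding: truth is Bernoulli at `prevalence`;
#' each reader calls truth-positives with probability `se_*` and
#' truth-negatives negative with probability `sp_*`. Conditional on truth,
#' the two readers' calls are coupled by a common-shock mixture: with
#' probability `dep_pos` (on positives) or `dep_neg` (on negatives) both
#' readers threshold one shared latent uniform against their own operating
#' point, otherwise they call independently. This preserves each reader's
#' marginal operating point exactly for any `dep` in `[0, 1]` (so every
#' parameter combination is feasible), gives conditional independence at
#' `dep = 0`, forces agreement on every positive at `dep_pos = 1` when
#' `se_a = se_b`, and has closed-form joint cells, e.g.
#' `P(both positive | truth = 1) = (1 - dep_pos) * se_a * se_b +
#' dep_pos * min(se_a, se_b)`.
#'
#' Reader B additionally fails to produce output (an unavailable call) with
#' probability `failure_rate_b`, emulating an algorithm that cannot process
#' some images.
#'
#' @param n_cases number of cases.
#' @param findings character vector of finding names.
#' @param prevalence,se_a,sp_a,se_b,sp_b proportions in `[0, 1]`, recycled
#'   across findings.
#' @param dep_pos,dep_neg inter-reader dependence given truth-positive /
#'   truth-negative, in `[0, 1]`. Defaults (0.3 / 0.1) are working values
#'   for testing, not estimates from any study.
#' @param failure_rate_b probability a reader-B call is unavailable.
#' @param score_separation if non-`NULL`, reader-B scores are attached (see
#'   [simulate_scores()]).
#' @param seed integer seed.
#' @param reader_a,reader_b reader column names.
#' @return An object of class `sim_config`.
#' @seealso [study_sim_config()] for a configuration matching the packaged
#'   trauma chest radiograph study.
#' @export
sim_config <- function(n_cases, findings = "finding1", prevalence,
                       se_a, sp_a, se_b, sp_b,
                       dep_pos = 0.3, dep_neg = 0.1,
                       failure_rate_b = 0, score_separation = NULL,
                       seed = 1,
                       reader_a = "radiologist", reader_b = "ai") {
  k <- length(findings)
  rec <- function(x, name) {
    x <- rep_len(as.numeric(x), k)
    if (anyNA(x) || any(x < 0 | x > 1)) {
      stop("'", name, "' must lie in [0, 1]", call. = FALSE)
    }
    x
  }
  if (n_cases < 1 || n_cases != round(n_cases)) {
    stop("n_cases must be a positive integer", call. = FALSE)
  }
  cfg <- list(
    n_cases = as.integer(n_cases), findings = as.character(findings),
    prevalence = rec(prevalence, "prevalence"),
    se_a = rec(se_a, "se_a"), sp_a = rec(sp_a, "sp_a"),
    se_b = rec(se_b, "se_b"), sp_b = rec(sp_b, "sp_b"),
    dep_pos = rec(dep_pos, "dep_pos")[1], dep_neg = rec(dep_neg, "dep_neg")[1],
    failure_rate_b = rec(failure_rate_b, "failure_rate_b")[1],
    score_separation = score_separation,
    seed = as.integer(seed),
    reader_a = reader_a, reader_b = reader_b
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cases, "cases x", length(x$findings),
      "finding(s); readers:", x$reader_a, "/", x$reader_b, "\n")
  cat("  dep_pos =", x$dep_pos, " dep_neg =", x$dep_neg,
      " failure_rate_b =", signif(x$failure_rate_b, 3),
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Configuration emulating the packaged trauma radiograph study
#'
#' Builds a [sim_config()] whose per-finding prevalences and reader
#' operating points are taken from the packaged confusion counts
#' ([trauma_cxr_counts()]): 1404 cases, seven findings at the study
#' prevalences (pneumothorax 12.3%, rib fracture 24.9%, ...), radiologist
#' and algorithm sensitivities/specificities as observed, and an
#' algorithm failure rate of 4/1404.
#'
#' @param n_cases cohort size (default 1404).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()]
#'   (e.g. `dep_pos`, `score_separation`).
#' @return A `sim_config`.
#' @export
study_sim_config <- function(n_cases = 1404, seed = 1, ...) {
  counts <- trauma_cxr_counts()
  rad <- counts[counts$reader == "radiologist", ]
  ai <- counts[counts$reader == "ai", ]
  ai <- ai[match(rad$finding, ai$finding), ]
  sim_config(
    n_cases = n_cases,
    findings = rad$finding,
    prevalence = (rad$tp + rad$fn) / (rad$tp + rad$fp + rad$fn + rad$tn),
    se_a = rad$tp / (rad$tp + rad$fn),
    sp_a = rad$tn / (rad$tn + rad$fp),
    se_b = ai$tp / (ai$tp + ai$fn),
    sp_b = ai$tn / (ai$tn + ai$fp),
    failure_rate_b = 4 / 1404,
    seed = seed,
    ...
  )
}

#' Simulate a paired-reader dataset
#'
#' Draws a [study_dataset] from a [sim_config()]: per finding, Bernoulli
#' truth, coupled reader calls via the common-shock mixture, unavailable
#' reader-B calls at the configured failure rate, and (optionally) reader-B
#' scores. Deterministic given the seed.
#'
#' @param cfg a [sim_config].
#' @param seed optional override of `cfg$seed`.
#' @return A [study_dataset] with `cfg$n_cases` cases per finding.
#' @export
#' @examples
#' cfg <- sim_config(500, prevalence = 0.12, se_a = 0.33, sp_a = 0.99,
#'                   se_b = 0.39, sp_b = 0.998, seed = 7)
#' ds <- simulate_dataset(cfg)
#' confusion_from_calls(ds, "ai", "finding1")
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_cases
  case_id <- sprintf("case_%0*d", max(4L, nchar(n)), seq_len(n))
  withr::with_seed(seed, {
    parts <- lapply(seq_along(cfg$findings), function(i) {
      truth <- stats::rbinom(n, 1, cfg$prevalence[i])
      # per-case success probabilities for a positive call
      pa <- ifelse(truth == 1, cfg$se_a[i], 1 - cfg$sp_a[i])
      pb <- ifelse(truth == 1, cfg$se_b[i], 1 - cfg$sp_b[i])
      dep <- ifelse(truth == 1, cfg$dep_pos, cfg$dep_neg)
      shared <- stats::runif(n) < dep
      u_shared <- stats::runif(n)
      u_a <- stats::runif(n)
      u_b <- stats::runif(n)
      call_a <- as.integer(ifelse(shared, u_shared < pa, u_a < pa))
      call_b <- as.integer(ifelse(shared, u_shared < pb, u_b < pb))
      if (cfg$failure_rate_b > 0) {
        call_b[stats::runif(n) < cfg$failure_rate_b] <- NA_integer_
      }
      out <- tibble::tibble(case_id = case_id, finding = cfg$findings[i],
                            truth = truth)
      out[[cfg$reader_a]] <- call_a
      out[[cfg$reader_b]] <- call_b
      if (!is.null(cfg$score_separation)) {
        latent <- stats::rnorm(n, mean = truth * cfg$score_separation, sd = 1)
        out[[paste0(cfg$reader_b, "_score")]] <- stats::plogis(latent)
      }
      out
    })
    study_dataset(do.call(rbind, parts))
  })
}

#' Attach synthetic suspicion scores to a reader
#'
#' Draws a continuous score for every case of every finding from the
#' binormal model: a standard normal for truth-negatives and a unit-variance
#' normal at mean `score_separation` for truth-positives, mapped to
#' `[0, 1]` with the logistic function (so the 0.5 score corresponds to the
#' latent zero threshold). Under this model the population AUC has the
#' closed form `pnorm(score_separation / sqrt(2))`, which recovery tests
#' use as an oracle. Scores are drawn given truth only; they are not
#' conditioned on the reader's existing binary call.
#'
#' @param ds a [study_dataset].
#' @param reader reader to attach scores to.
#' @param score_separation latent mean separation (>= 0 for an informative
#'   reader).
#' @param seed integer seed.
#' @return The dataset with a `<reader>_score` column added/replaced.
#' @export
simulate_scores <- function(ds, reader, score_separation, seed = 1) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!reader %in% ds$readers) stop("unknown reader: ", reader, call. = FALSE)
  rec <- ds$records
  latent <- withr::with_seed(seed, {
    stats::rnorm(nrow(rec), mean = rec$truth * score_separation, sd = 1)
  })
  rec[[paste0(reader, "_score")]] <- stats::plogis(latent)
  study_dataset(rec, readers = ds$readers)
}

#' Simulation-based calibration and parameter recovery
#'
#' Repeatedly simulates cohorts from `cfg`, re-estimates each reader's
#' sensitivity, specificity and kappa, and runs the paired bootstrap for
#' the kappa difference. Reports, per finding: mean, bias and RMSE of the
#' estimates against the generator-implied values (kappa via
#' [implied_kappa()]), the rejection rate of the paired bootstrap at
#' p < 0.05, and the fraction of replicates whose median kappa difference
#' is positive.
#'
#' @param cfg a [sim_config].
#' @param n_reps number of simulated cohorts.
#' @param n_boot bootstrap iterations per cohort.
#' @return An object of class `recovery_report`: a tibble with one row per
#'   finding and attributes `n_reps`, `n_boot`.
#' @export
recovery_harness <- function(cfg, n_reps, n_boot = 1000) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  seeds <- withr::with_seed(cfg$seed,
                            matrix(sample.int(2^20, 2 * n_reps), nrow = 2))
  k <- length(cfg$findings)
  acc <- array(NA_real_, dim = c(n_reps, k, 9),
               dimnames = list(NULL, cfg$findings,
                               c("se_a", "sp_a", "se_b", "sp_b",
                                 "kappa_a", "kappa_b", "delta_median",
                                 "p_value", "reject")))
  for (r in seq_len(n_reps)) {
    ds <- simulate_dataset(cfg, seed = seeds[1, r])
    for (i in seq_len(k)) {
      f <- cfg$findings[i]
      est <- tryCatch({
        ca <- confusion_from_calls(ds, cfg$reader_a, f, "drop")
        cb <- confusion_from_calls(ds, cfg$reader_b, f, "drop")
        cmp <- paired_bootstrap_kappa_diff(ds, cfg$reader_a, cfg$reader_b, f,
                                           n_boot = n_boot,
                                           seed = seeds[2, r] + i)
        c(sensitivity(ca)$point, specificity(ca)$point,
          sensitivity(cb)$point, specificity(cb)$point,
          cohens_kappa(ca)$kappa, cohens_kappa(cb)$kappa,
          cmp$delta_median, cmp$p_value,
          as.numeric(cmp$p_value < 0.05))
      }, error = function(e) rep(NA_real_, 9))
      acc[r, i, ] <- est
    }
  }
  implied_a <- implied_kappa(cfg$prevalence, cfg$se_a, cfg$sp_a)
  implied_b <- implied_kappa(cfg$prevalence, cfg$se_b, cfg$sp_b)
  truth_vals <- cbind(se_a = cfg$se_a, sp_a = cfg$sp_a,
                      se_b = cfg$se_b, sp_b = cfg$sp_b,
                      kappa_a = implied_a, kappa_b = implied_b)
  rows <- lapply(seq_len(k), function(i) {
    m <- acc[, i, , drop = FALSE][, 1, ]
    if (n_reps == 1) m <- matrix(m, nrow = 1,
                                 dimnames = list(NULL, dimnames(acc)[[3]]))
    stat <- function(col) mean(m[, col], na.rm = TRUE)
    bias <- function(col) stat(col) - truth_vals[i, col]
    rmse <- function(col) sqrt(mean((m[, col] - truth_vals[i, col])^2,
                                    na.rm = TRUE))
    tibble::tibble(
      finding = cfg$findings[i],
      implied_kappa_a = implied_a[i], implied_kappa_b = implied_b[i],
      mean_se_a = stat("se_a"), bias_se_a = bias("se_a"),
      rmse_se_a = rmse("se_a"),
      mean_sp_a = stat("sp_a"), bias_sp_a = bias("sp_a"),
      mean_se_b = stat("se_b"), bias_se_b = bias("se_b"),
      mean_sp_b = stat("sp_b"), bias_sp_b = bias("sp_b"),
      mean_kappa_a = stat("kappa_a"), bias_kappa_a = bias("kappa_a"),
      rmse_kappa_a = rmse("kappa_a"),
      mean_kappa_b = stat("kappa_b"), bias_kappa_b = bias("kappa_b"),
      rmse_kappa_b = rmse("kappa_b"),
      mean_delta_median = stat("delta_median"),
      prop_delta_positive = mean(m[, "delta_median"] > 0, na.rm = TRUE),
      rejection_rate = stat("reject"),
      n_failed = sum(is.na(m[, "p_value"]))
    )
  })
  structure(do.call(rbind, rows), n_reps = n_reps, n_boot = n_boot,
            seed = cfg$seed, class = c("recovery_report", "tbl_df", "tbl",
                                       "data.frame"))
}
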