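#' Exact Clopper-Pearson binomial confidence interval
#'
#' Equal-tailed exact interval for a binomial proportion, obtained by
#' inverting the binomial tail probabilities; computed through the standard
#' beta-quantile closed form. The lower bound is 0 exactly when `k = 0` and
#' the upper bound 1 exactly when `k = n`. The interval is conservative:
#' coverage is at least the nominal level for every true proportion.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return An object of class `binom_ci`: list with `point` (`k/n`),
#'   `lower`, `upper`, `level`, `k`, `n`.
#' @export
#' @examples
#' clopper_pearson(57, 172)   # (0.262, 0.407)
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n) {
    stop("need integer 0 <= k <= n with n >= 1", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(
    list(point = k / n, lower = lower, upper = upper,
         level = level, k = as.integer(k), n = as.integer(n)),
    class = "binom_ci"
  )
}

#' @export
print.binom_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (%.1f-%.1f) [%d/%d, %g%% CI]\n",
              100 * x$point, 100 * x$lower, 100 * x$upper,
              x$k, x$n, 100 * x$level))
  invisible(x)
}

#' Sensitivity (true-positive rate) with exact interval
#'
#' @param ct a [confusion_table]; requires at least one truth-positive case.
#' @param level confidence level.
#' @return A [clopper_pearson()] interval for `tp / (tp + fn)`.
#' @export
sensitivity <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tp + ct$fn == 0) {
    stop("sensitivity undefined: no truth-positive cases", call. = FALSE)
  }
  clopper_pearson(ct$tp, ct$tp + ct$fn, level)
}

#' Specificity (true-negative rate) with exact interval
#'
#' @inheritParams sensitivity
#' @return A [clopper_pearson()] interval for `tn / (tn + fp)`.
#' @export
specificity <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tn + ct$fp == 0) {
    stop("specificity undefined: no truth-negative cases", call. = FALSE)
  }
  clopper_pearson(ct$tn, ct$tn + ct$fp, level)
}

#' Prevalence of the finding with exact interval
#'
#' @inheritParams sensitivity
#' @return A [clopper_pearson()] interval for `(tp + fn) / n`.
#' @export
prevalence <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  clopper_pearson(ct$tp + ct$fn, attr(ct, "n"), level)
}

# Vectorised kappa over parallel count vectors; NA where chance agreement
# p_e = 1 (both margins degenerate), the undefined case. Doubles throughout:
# products of large counts overflow integer arithmetic.
.kappa_cells <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  n <- tp + fp + fn + tn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  ifelse(abs(1 - p_e) < .Machine$double.eps * 4, NA_real_,
         (p_o - p_e) / (1 - p_e))
}

#' Cohen's kappa between a reader and the reference standard
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement proportion and `p_e` the agreement expected from the
#' two margins. When both margins are constant (`p_e = 1`) kappa is
#' undefined; the estimate is returned as `NA` with `degenerate = TRUE`
#' rather than silently substituting 0 or 1.
#'
#' @param ct a [confusion_table].
#' @return An object of class `kappa_estimate`: list with `kappa`, `p_o`,
#'   `p_e`, `degenerate`, and `ci`/`method` fields filled by
#'   [kappa_interval()].
#' @export
#' @examples
#' cohens_kappa(confusion_table(57, 8, 115, 1224))  # 0.44
cohens_kappa <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- as.numeric(attr(ct, "n"))
  tp <- as.numeric(ct$tp); fp <- as.numeric(ct$fp)
  fn <- as.numeric(ct$fn); tn <- as.numeric(ct$tn)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- .kappa_cells(tp, fp, fn, tn)
  structure(
    list(kappa = kappa, p_o = p_o, p_e = p_e,
         degenerate = is.na(kappa), ci = NULL, method = NULL,
         n = n),
    class = "kappa_estimate"
  )
}

#' @export
print.kappa_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("<kappa_estimate> undefined (chance agreement p_e = 1)\n")
  } else {
    cat(sprintf("<kappa_estimate> kappa = %.2f (p_o = %.3f, p_e = %.3f)\n",
                x$kappa, x$p_o, x$p_e))
    if (!is.null(x$ci)) {
      cat(sprintf("  %g%% CI (%s): %.2f-%.2f\n", 100 * x$ci$level,
                  x$method, x$ci$lower, x$ci$upper))
    }
  }
  invisible(x)
}

# Large-sample (delta-method) SE of kappa for a 2x2 agreement table,
# Fleiss-Cohen-Everitt form.
.kappa_se <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  n <- tp + fp + fn + tn
  p <- matrix(c(tp, fn, fp, tn), 2, 2) / n  # rows: reader, cols: truth
  r <- rowSums(p)
  c_ <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(r * c_)
  if (abs(1 - p_e) < .Machine$double.eps * 4) return(NA_real_)
  term1 <- sum(diag(p) * ((1 - p_e) - (r + c_) * (1 - p_o))^2)
  term2 <- 0
  for (i in 1:2) for (j in 1:2) {
    if (i != j) term2 <- term2 + p[i, j] * (c_[i] + r[j])^2
  }
  term2 <- (1 - p_o)^2 * term2
  term3 <- (p_o * p_e - 2 * p_e + p_o)^2
  v <- (term1 + term2 - term3) / ((1 - p_e)^4 * n)
  sqrt(max(v, 0))
}

#' Confidence interval for Cohen's kappa
#'
#' Either the analytic large-sample interval (delta-method standard error,
#' fast and deterministic) or a percentile bootstrap over case resamples of
#' the four confusion cells. Bootstrap replicates whose resampled table has
#' undefined kappa are dropped from the percentile computation and counted.
#'
#' @param ct a [confusion_table] with `n >= 2`.
#' @param method `"analytic"` (default) or `"bootstrap"`.
#' @param level confidence level.
#' @param n_boot bootstrap replicates (bootstrap method only).
#' @param seed integer seed (bootstrap method only); results are
#'   reproducible given the seed.
#' @return A `kappa_estimate` with `ci = list(lower, upper, level)`,
#'   `method`, and for the bootstrap `n_degenerate`.
#' @export
kappa_interval <- function(ct, method = c("analytic", "bootstrap"),
                           level = 0.95, n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  est <- cohens_kappa(ct)
  if (est$degenerate) {
    stop("kappa undefined for this table (chance agreement p_e = 1): ",
         sprintf("tp=%d fp=%d fn=%d tn=%d", ct$tp, ct$fp, ct$fn, ct$tn),
         call. = FALSE)
  }
  n <- attr(ct, "n")
  if (n < 2) stop("need at least 2 cases for an interval", call. = FALSE)
  if (method == "analytic") {
    se <- .kappa_se(ct$tp, ct$fp, ct$fn, ct$tn)
    z <- stats::qnorm(1 - (1 - level) / 2)
    est$ci <- list(lower = max(-1, est$kappa - z * se),
                   upper = min(1, est$kappa + z * se), level = level)
    est$se <- se
  } else {
    probs <- c(ct$tp, ct$fp, ct$fn, ct$tn) / n
    draws <- withr::with_seed(seed, stats::rmultinom(n_boot, n, probs))
    kb <- .kappa_cells(draws[1, ], draws[2, ], draws[3, ], draws[4, ])
    n_degen <- sum(is.na(kb))
    kb <- kb[!is.na(kb)]
    if (length(kb) == 0) {
      stop("all bootstrap replicates degenerate", call. = FALSE)
    }
    q <- stats::quantile(kb, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 7)
    est$ci <- list(lower = q[1], upper = q[2], level = level)
    est$n_degenerate <- n_degen
    est$n_boot <- n_boot
    est$seed <- seed
  }
  est$method <- method
  est
}

#' Kappa implied by a generator's operating point
#'
#' Closed-form population kappa of a reader with the given sensitivity and
#' specificity against truth at the given prevalence; used as the oracle in
#' parameter-recovery checks of the synthetic generator.
#'
#' @param prevalence,se,sp proportions in `[0, 1]`.
#' @return Population kappa (scalar; `NA` when undefined).
#' @export
implied_kappa <- function(prevalence, se, sp) {
  p11 <- prevalence * se            # truth 1, call 1
  p10 <- prevalence * (1 - se)      # truth 1, call 0
  p01 <- (1 - prevalence) * (1 - sp)
  p00 <- (1 - prevalence) * sp
  p_o <- p11 + p00
  p_e <- (p11 + p01) * prevalence + (p10 + p00) * (1 - prevalence)
  ifelse(abs(1 - p_e) < .Machine$double.eps * 4, NA_real_,
         (p_o - p_e) / (1 - p_e))
}
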