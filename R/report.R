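#' Accuracy summary from confusion counts
#'
#' One row per (finding, reader): counts, sensitivity and specificity with
#' exact Clopper-Pearson intervals, and Cohen's kappa with an analytic
#' interval. Accepts the long counts format of [trauma_cxr_counts()].
#'
#' @param counts tibble with columns `finding`, `reader`, `tp`, `fp`, `tn`,
#'   `fn`.
#' @param level confidence level.
#' @return A tibble; proportions on the 0-1 scale (reports render them as
#'   percentages).
#' @export
accuracy_from_counts <- function(counts, level = 0.95) {
  needed <- c("finding", "reader", "tp", "fp", "tn", "fn")
  if (!all(needed %in% names(counts))) {
    stop("counts must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    ct <- confusion_table(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
    # a finding with no positives (or no negatives) in the cohort leaves the
    # corresponding rate undefined; report NA rather than aborting the table
    se <- tryCatch(sensitivity(ct, level), error = function(e) NULL)
    sp <- tryCatch(specificity(ct, level), error = function(e) NULL)
    ka <- tryCatch(kappa_interval(ct, "analytic", level),
                   error = function(e) NULL)
    na_ci <- list(point = NA_real_, lower = NA_real_, upper = NA_real_)
    if (is.null(se)) se <- na_ci
    if (is.null(sp)) sp <- na_ci
    tibble::tibble(
      finding = x$finding, reader = x$reader,
      tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn, n = attr(ct, "n"),
      sensitivity = se$point, sens_lower = se$lower, sens_upper = se$upper,
      specificity = sp$point, spec_lower = sp$lower, spec_upper = sp$upper,
      kappa = if (is.null(ka)) NA_real_ else ka$kappa,
      kappa_lower = if (is.null(ka)) NA_real_ else ka$ci$lower,
      kappa_upper = if (is.null(ka)) NA_real_ else ka$ci$upper
    )
  })
  do.call(rbind, rows)
}

#' Per-finding prevalence table from a dataset
#'
#' @param ds a [study_dataset].
#' @param level confidence level.
#' @return A tibble with one row per finding: positive count, cohort size,
#'   prevalence and exact interval.
#' @export
prevalence_table <- function(ds, level = 0.95) {
  stopifnot(inherits(ds, "study_dataset"))
  rows <- lapply(ds$findings, function(f) {
    truth <- ds$records$truth[ds$records$finding == f]
    ci <- clopper_pearson(sum(truth), length(truth), level)
    tibble::tibble(finding = f, n_positive = ci$k, n = ci$n,
                   prevalence = ci$point,
                   prev_lower = ci$lower, prev_upper = ci$upper)
  })
  do.call(rbind, rows)
}

#' Full analysis bundle for a paired-reader dataset
#'
#' Ties the pipeline together: per-finding prevalence, per-reader accuracy
#' (sensitivity/specificity/kappa), the paired bootstrap comparison of the
#' two readers, the OR-rule hybrid reader, and AUC where scores exist. All
#' seeds and policies are recorded in `metadata`; regenerating a bundle
#' from the same inputs and seed reproduces it exactly (metadata carries no
#' timestamp for that reason).
#'
#' @param ds a [study_dataset] with at least two readers.
#' @param reader_a,reader_b readers to compare (defaults: the first two
#'   registered readers).
#' @param n_boot bootstrap iterations for the comparison.
#' @param seed base seed; per-finding seeds are derived from it.
#' @param case_policy,unavailable_policy see
#'   [paired_bootstrap_kappa_diff()] and [confusion_from_calls()].
#' @param level confidence level.
#' @return An object of class `report_bundle`: list with tibbles
#'   `prevalence_table`, `accuracy_table`, `comparison_table`,
#'   `hybrid_table`, optional `auc_table`, and `metadata`.
#' @export
report_bundle <- function(ds, reader_a = ds$readers[1],
                          reader_b = ds$readers[2],
                          n_boot = 10000, seed = 1,
                          case_policy = "intersection",
                          unavailable_policy = "drop",
                          level = 0.95) {
  stopifnot(inherits(ds, "study_dataset"))
  if (is.na(reader_b)) stop("need two readers to compare", call. = FALSE)

  counts <- do.call(rbind, lapply(ds$findings, function(f) {
    do.call(rbind, lapply(c(reader_a, reader_b), function(r) {
      ct <- confusion_from_calls(ds, r, f, unavailable_policy)
      tibble::tibble(finding = f, reader = r, tp = ct$tp, fp = ct$fp,
                     tn = ct$tn, fn = ct$fn)
    }))
  }))
  accuracy <- accuracy_from_counts(counts, level)
  cmp <- compare_all(ds, reader_a, reader_b, n_boot = n_boot, seed = seed,
                     case_policy = case_policy,
                     unavailable_policy = unavailable_policy, level = level)
  comparison <- cmp[, c("finding", "n_cases", "kappa_a", "kappa_b",
                        "delta_median", "delta_lower", "delta_upper",
                        "p_value", "n_degenerate", "seed", "error")]
  hybrid <- cmp[, c("finding", "hybrid_sens", "hybrid_sens_lower",
                    "hybrid_sens_upper", "hybrid_spec", "hybrid_spec_lower",
                    "hybrid_spec_upper", "error")]

  score_cols <- paste0(c(reader_a, reader_b), "_score")
  score_cols <- score_cols[score_cols %in% names(ds$records)]
  auc <- NULL
  if (length(score_cols) > 0) {
    auc <- do.call(rbind, lapply(ds$findings, function(f) {
      rec <- ds$records[ds$records$finding == f, ]
      do.call(rbind, lapply(score_cols, function(sc) {
        a <- tryCatch(roc_auc(rec[[sc]], rec$truth),
                      error = function(e) NA_real_)
        tibble::tibble(finding = f,
                       reader = sub("_score$", "", sc), auc = a)
      }))
    }))
  }

  structure(
    list(prevalence_table = prevalence_table(ds, level),
         accuracy_table = accuracy,
         comparison_table = comparison,
         hybrid_table = hybrid,
         auc_table = auc,
         metadata = list(
           package_version = as.character(utils::packageVersion("readeracc")),
           reader_a = reader_a, reader_b = reader_b,
           n_boot = n_boot, seed = seed,
           case_policy = case_policy,
           unavailable_policy = unavailable_policy,
           level = level, n_cases = nrow(ds$records) / length(ds$findings)
         )),
    class = "report_bundle"
  )
}

.fmt_pct <- function(p, lo, hi) {
  ifelse(is.na(p), "-",
         sprintf("%.1f%% (%.1f-%.1f)", 100 * p, 100 * lo, 100 * hi))
}
.fmt_kappa <- function(k, lo = NULL, hi = NULL) {
  if (is.null(lo)) {
    ifelse(is.na(k), "undefined", sprintf("%.2f", k))
  } else {
    ifelse(is.na(k), "undefined",
           sprintf("%.2f (%.2f-%.2f)", k, lo, hi))
  }
}
.md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, body), collapse = "\n")
}

#' Render a report bundle as markdown
#'
#' Display rounding follows the reporting conventions of the underlying
#' tables: kappa to 2 decimal places, percentages to 1. Internal tables
#' keep full precision.
#'
#' @param bundle a [report_bundle()].
#' @return A single markdown character string.
#' @export
format_report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  md <- bundle$metadata
  prev <- bundle$prevalence_table
  acc <- bundle$accuracy_table
  cmp <- bundle$comparison_table
  hyb <- bundle$hybrid_table

  prev_md <- tibble::tibble(
    Finding = prev$finding,
    `n positive` = prev$n_positive,
    Prevalence = .fmt_pct(prev$prevalence, prev$prev_lower, prev$prev_upper)
  )
  acc_md <- tibble::tibble(
    Finding = acc$finding, Reader = acc$reader,
    TP = acc$tp, FP = acc$fp, TN = acc$tn, FN = acc$fn,
    Sensitivity = .fmt_pct(acc$sensitivity, acc$sens_lower, acc$sens_upper),
    Specificity = .fmt_pct(acc$specificity, acc$spec_lower, acc$spec_upper),
    Kappa = .fmt_kappa(acc$kappa, acc$kappa_lower, acc$kappa_upper)
  )
  cmp_md <- tibble::tibble(
    Finding = cmp$finding,
    `Kappa A` = .fmt_kappa(cmp$kappa_a),
    `Kappa B` = .fmt_kappa(cmp$kappa_b),
    `Delta kappa (B-A)` = ifelse(
      is.na(cmp$delta_median), "-",
      sprintf("%.3f (%.3f-%.3f)", cmp$delta_median, cmp$delta_lower,
              cmp$delta_upper)),
    `p-value` = ifelse(is.na(cmp$p_value), "-",
                       sprintf("%.4g", cmp$p_value))
  )
  hyb_md <- tibble::tibble(
    Finding = hyb$finding,
    `Hybrid sensitivity` = .fmt_pct(hyb$hybrid_sens, hyb$hybrid_sens_lower,
                                    hyb$hybrid_sens_upper),
    `Hybrid specificity` = .fmt_pct(hyb$hybrid_spec, hyb$hybrid_spec_lower,
                                    hyb$hybrid_spec_upper)
  )
  sections <- c(
    "# Paired-reader accuracy report", "",
    sprintf("Readers: %s (A) vs %s (B); reference standard labels from the dataset.",
            md$reader_a, md$reader_b),
    sprintf("Bootstrap: %d iterations, base seed %d; case policy '%s'; unavailable-call policy '%s'; confidence level %g%%.",
            md$n_boot, md$seed, md$case_policy, md$unavailable_policy,
            100 * md$level),
    "",
    "## Prevalence", "", .md_table(prev_md), "",
    "## Accuracy by reader", "", .md_table(acc_md), "",
    "## Paired difference in Cohen's kappa (B - A)", "", .md_table(cmp_md), "",
    "## Hybrid OR-rule reader", "", .md_table(hyb_md), ""
  )
  if (!is.null(bundle$auc_table)) {
    auc_md <- tibble::tibble(
      Finding = bundle$auc_table$finding,
      Reader = bundle$auc_table$reader,
      AUC = sprintf("%.3f", bundle$auc_table$auc)
    )
    sections <- c(sections, "## AUC (score-bearing readers)", "",
                  .md_table(auc_md), "")
  }
  paste(sections, collapse = "\n")
}

#' Write a report bundle to disk
#'
#' Emits `prevalence_table.csv`, `accuracy_table.csv`,
#' `comparison_table.csv`, `hybrid_table.csv` (and `auc_table.csv` when
#' scores exist) plus a human-readable `report.md`, all under `outdir`.
#' Writing the same bundle twice produces byte-identical files.
#'
#' @param bundle a [report_bundle()].
#' @param outdir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tabs <- c("prevalence_table", "accuracy_table", "comparison_table",
            "hybrid_table", "auc_table")
  for (nm in tabs) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], p, na = "NA", progress = FALSE)
    paths <- c(paths, p)
  }
  rp <- file.path(outdir, "report.md")
  writeLines(format_report(bundle), rp)
  invisible(c(paths, rp))
}
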