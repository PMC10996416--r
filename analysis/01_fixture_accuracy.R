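#!/usr/bin/env Rscript

# Accuracy of each reader against the CT reference standard, recomputed from
# the packaged confusion counts of the trauma chest radiograph study:
# sensitivity/specificity with exact Clopper-Pearson intervals and Cohen's
# kappa with analytic intervals, per finding and reader.

suppressPackageStartupMessages(library(readeracc))

counts <- trauma_cxr_counts()
acc <- accuracy_from_counts(counts)

# prevalence from the radiologist margins (full 1404-case cohort)
rad <- counts[counts$reader == "radiologist", ]
prev <- do.call(rbind, lapply(seq_len(nrow(rad)), function(i) {
  ci <- prevalence(confusion_table(rad$tp[i], rad$fp[i], rad$fn[i], rad$tn[i]))
  tibble::tibble(finding = rad$finding[i], n_positive = ci$k, n = ci$n,
                 prevalence = ci$point, prev_lower = ci$lower,
                 prev_upper = ci$upper)
}))

dir.create("results", showWarnings = FALSE)
readr::write_csv(acc, "results/fixture_accuracy.csv")
readr::write_csv(prev, "results/fixture_prevalence.csv")

message("Cohort of ", prev$n[1], " cases; most common finding: ",
        prev$finding[which.max(prev$prevalence)], " (",
        sprintf("%.1f%%", 100 * max(prev$prevalence)), ").")
message("Per-reader accuracy (kappa vs CT):")
for (i in seq_len(nrow(acc))) {
  message(sprintf("  %-18s %-12s se %5.1f%%  sp %5.1f%%  kappa %.2f (%.2f-%.2f)",
                  acc$finding[i], acc$reader[i],
                  100 * acc$sensitivity[i], 100 * acc$specificity[i],
                  acc$kappa[i], acc$kappa_lower[i], acc$kappa_upper[i]))
}
message("Tables written to results/fixture_accuracy.csv and ",
        "results/fixture_prevalence.csv")
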