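#!/usr/bin/env Rscript

# Generate a synthetic paired-reader cohort that mirrors the study
# conditions: 1404 cases, seven findings at the observed prevalences, both
# readers at their observed operating points, an algorithm failure rate of
# 4/1404, and algorithm suspicion scores (binormal, separation 2.5).
# The per-case data of the real study are not published; this cohort stands
# in for them wherever per-case pairing is needed.

suppressPackageStartupMessages(library(readeracc))

cfg <- study_sim_config(seed = 20260924, score_separation = 2.5)
ds <- simulate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/synthetic_cohort.csv")

n_unavail <- sum(is.na(ds$records$ai[ds$records$finding == ds$findings[1]]))
message("Simulated ", cfg$n_cases, " cases x ", length(cfg$findings),
        " findings (", nrow(ds$records), " records); ", n_unavail,
        " case(s) with unavailable algorithm output.")
pt <- confusion_from_calls(ds, "ai", "pneumothorax")
message(sprintf("Synthetic ai pneumothorax operating point: se %.1f%%, sp %.1f%% (configured %.1f%% / %.1f%%).",
                100 * sensitivity(pt)$point, 100 * specificity(pt)$point,
                100 * cfg$se_b[match("pneumothorax", cfg$findings)],
                100 * cfg$sp_b[match("pneumothorax", cfg$findings)]))
message("Cohort written to results/synthetic_cohort.csv")
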