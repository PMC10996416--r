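# readeracc

Diagnostic-accuracy evaluation of two paired readers against a shared
reference standard.

The motivating setting is a trauma radiology reader study: every patient has
a supine chest radiograph read twice — once by the reporting radiologist and
once by an image-analysis algorithm — and a contemporaneous chest CT whose
report serves as the ground truth for seven target findings (pneumothorax,
pneumomediastinum, rib/clavicle/humerus/scapula fracture, lobar/segmental
collapse). The package answers, per finding: how accurate is each reader,
do the two readers differ, and what would a combined workflow achieve?

## Statistics at the core

For a reader with confusion counts (TP, FP, FN, TN) against truth:

* **Sensitivity** TP/(TP+FN) and **specificity** TN/(TN+FP), each with an
  exact **Clopper–Pearson** interval (equal-tailed inversion of the binomial
  tails; conservative by construction).
* **Cohen's κ** = (p₀ − pₑ)/(1 − pₑ), where p₀ = (TP+TN)/n is observed
  agreement and pₑ the agreement expected from the margins; intervals by
  the large-sample delta-method SE or a percentile bootstrap. Tables where
  both margins are constant leave κ explicitly undefined (never 0 or 1).
* **Paired bootstrap** for Δκ = κ_B − κ_A: cases are resampled with
  replacement keeping both readers' calls paired within each case; the
  replicate median, 2.5th/97.5th percentiles and the two-sided inversion
  p-value `2·min(Pr(Δ ≤ 0), Pr(Δ ≥ 0))` (clamped to `[1/n_boot, 1]`) are
  reported, so p ≤ 0.05 coincides with the 95% interval excluding zero.
* **Hybrid OR reader**: a finding is present if either reader calls it;
  sensitivity can only rise, specificity only fall.
* **ROC/AUC** (Mann–Whitney, ties counted half) for score-producing readers.
* A **synthetic cohort generator**: Bernoulli truth at configurable
  prevalence, two readers with set operating points whose calls are coupled
  given truth by a common-shock mixture (`dep = 0` conditional independence,
  `dep = 1` maximal agreement given the margins), an algorithm failure rate,
  and binormal suspicion scores with a closed-form AUC.

The confusion counts of a published 1404-case study ship as a fixture
(`trauma_cxr_counts()`), so the marginal statistics are reproducible exactly;
per-case pairing is not published, so paired comparisons run on synthetic
cohorts that emulate the study conditions.

## Worked example

```r
library(readeracc)

ct <- fixture_confusion("pneumothorax", "radiologist")
cohens_kappa(ct)
#> <kappa_estimate> kappa = 0.44 (p_o = 0.912, p_e = 0.843)
sensitivity(ct)
#> 33.1% (26.2-40.7) [57/172, 95% CI]
kappa_interval(ct)
#> <kappa_estimate> kappa = 0.44 (p_o = 0.912, p_e = 0.843)
#>   95% CI (analytic): 0.36-0.52
```

The radiologist missed two of every three CT-confirmed pneumothoraces
(sensitivity 33.1%) while almost never calling one that was absent
(specificity 99.4%); chance-corrected agreement with CT is moderate
(κ = 0.44). Paired comparison needs per-case data, so simulate a cohort at
the study's operating points and compare:

```r
cfg <- study_sim_config(seed = 20260924)
ds  <- simulate_dataset(cfg)
paired_bootstrap_kappa_diff(ds, "radiologist", "ai", "pneumothorax",
                            n_boot = 10000, seed = 42)
#> <kappa_comparison> pneumothorax: kappa(ai) - kappa(radiologist)
#>   median 0.129 (0.026-0.235), p = 0.0148, n_boot = 10000, n = 1402 cases
```

The full pipeline (`report_bundle()` / `write_report()`) emits prevalence,
accuracy, comparison and hybrid tables as CSV plus a markdown report with
every seed and policy recorded. The numbered scripts under `analysis/`
run the whole study workflow: `01_fixture_accuracy.R` (accuracy tables from
the packaged counts), `02_simulate_cohort.R` (synthetic cohort),
`03_reader_comparison.R` (paired bootstrap + hybrid report),
`04_calibration.R` (type-I error, power and parameter recovery); outputs
land under `results/`.

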