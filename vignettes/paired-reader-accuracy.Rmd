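---
title: "Evaluating paired readers against a reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating paired readers against a reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readeracc)
```

## The evaluation problem

A reader study scores two sources of binary calls — here a reporting
radiologist and an image-analysis algorithm, both reading the same trauma
chest radiographs — against a stronger reference standard, the report of a
CT acquired within hours of the radiograph. Three questions recur:

1. *How accurate is each reader?* Per finding: sensitivity, specificity and
   chance-corrected agreement (Cohen's κ) with the reference.
2. *Do the readers differ?* The readers saw the same cases, so their errors
   are correlated and the comparison must be paired.
3. *What would a combined workflow achieve?* The simplest combination calls
   a finding present when either reader does (the OR rule), modelling an
   algorithmic flag layered over the human report.

The package works from per-case long-format data (`study_dataset`): one row
per case × finding, a 0/1 reference label, one 0/1/`NA` column per reader
(`NA` marks a reader that produced no output, e.g. an algorithm that failed
to process an image), and optional `[0, 1]` suspicion scores.

## Accuracy statistics

**Binomial intervals.** All proportions carry exact Clopper–Pearson
intervals, computed through the beta-quantile closed form
(`qbeta(α/2, k, n−k+1)` and `qbeta(1−α/2, k+1, n−k)`), with the endpoints
pinned to 0 and 1 at `k = 0` and `k = n`. The exact interval is
conservative: coverage is at least nominal for every true proportion, which
the test suite verifies by simulation at n = 20 and n = 172.

**Cohen's κ.** For a 2×2 agreement table, κ = (p₀ − pₑ)/(1 − pₑ). Two
margins that are both constant give pₑ = 1 and an undefined κ; the package
returns an explicit undefined marker rather than substituting a value,
because silent substitution corrupts bootstrap distributions (degenerate
bootstrap replicates are instead dropped and counted). The analytic
interval uses the delta-method (Fleiss–Cohen–Everitt) standard error; a
percentile bootstrap is available. The published study tables that motivate
the fixture print κ intervals that match the analytic form, which is also
the default here because it is fast and deterministic.

**Display conventions.** Proportions live on the 0–1 scale in every table;
reports render percentages at 1 decimal place and κ at 2, matching standard
reporting practice. Computation is never rounded internally.

## The paired bootstrap

The difference Δκ = κ_B − κ_A is assessed by resampling *cases* with
replacement — the case is the sampling unit, and both readers' calls stay
attached to their case, which is what makes the comparison paired. Since a
case is fully described by its joint (truth, call_A, call_B) cell, the
package implements case resampling as one multinomial draw over the joint
cell counts per replicate: distributionally identical, and fast enough that
10,000 iterations take milliseconds. Cells are ordered by the dataset's
reader registry rather than by argument order, so swapping the two readers
under the same seed reuses identical draws and exactly negates Δκ.

The reported p-value inverts the bootstrap distribution:
p = 2·min(Pr(Δ ≤ 0), Pr(Δ ≥ 0)), clamped to `[1/n_boot, 1]`. This
convention makes the decision rule "p ≤ 0.05" coincide with the 95%
percentile interval excluding zero, consistent with reporting the median
and 2.5th/97.5th percentiles alongside the p-value. Simulation (the
calibration script and acceptance tests) shows the resulting type-I error
is close to, and on the conservative side of, the nominal 5% at the study's
cohort size.

Two case policies exist because readers can have different denominators:
`intersection` (default) keeps only cases where both readers produced
output — pairing is undefined on the others — while `per_reader` keeps all
cases and evaluates each reader on its own available subset within each
replicate, reproducing marginal denominators that differ between readers
(1404 vs 1400 in the fixture study). Resampling is unstratified: "paired"
refers to pairing readers within a case, not to stratifying on truth.

Per-finding analyses derive their seeds deterministically from the base
seed (`seed + finding index`), so results for one finding do not depend on
how many other findings are present or in what order.

## The synthetic generator

The study's per-case data are not published, so paired analyses are
exercised on synthetic cohorts built to the study's published margins:
1404 cases, seven findings at the observed prevalences (pneumothorax 12.3%,
rib fracture 24.9%, …), readers at the observed operating points, and an
algorithm failure rate of 4/1404 (`study_sim_config()`).

Conditional on truth, reader calls are coupled by a **common-shock
mixture**: with probability `dep` both readers threshold one shared uniform
against their own operating point; otherwise they call independently. A
single shared Bernoulli call cannot preserve two unequal marginals, so the
shared-uniform (comonotone) form is used: it preserves each marginal
exactly for any `dep` in `[0, 1]` — every parameter combination is
feasible, so validation reduces to range checks — and yields closed-form
joint cells, e.g. P(both positive | truth) =
`(1 − dep)·se_A·se_B + dep·min(se_A, se_B)`. The closed form is what makes
parameter-recovery tests possible: the generator-implied κ of a reader is
computable analytically (`implied_kappa()`), and the harness
(`recovery_harness()`) confirms the estimation pipeline recovers it.

Dependence is allowed to differ between truth-positives (`dep_pos`, default
0.3) and truth-negatives (`dep_neg`, default 0.1): readers plausibly share
misses on subtle positives more than they share false alarms. The study
publishes nothing about the joint reader distribution, so these defaults
are working values for testing, not estimates.

Suspicion scores use the binormal model — truth-negatives latent N(0, 1),
truth-positives N(s, 1), logistic-mapped to `[0, 1]` so 0.5 corresponds to
the latent zero threshold — solely because it has the closed-form AUC
Φ(s/√2) to test against; no claim is made that real algorithm scores are
binormal. Scores are drawn given truth only, not conditioned on the
simulated binary call.

What the generator does **not** emulate: correlation between findings
within a patient (findings are simulated independently, whereas over 40% of
real trauma patients carry multiple injuries), severity or size of a
finding, drift in reader behaviour over a decade of practice, and any image
content at all. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated sampling model, not performance on
real radiographs.

## Numerical and design choices

* **Unavailable calls** default to `drop` (the reader's denominator
  shrinks), matching the fixture study's exclusion of unprocessable images
  from the algorithm's denominator; `count_negative` treats a failed output
  as a negative call, the operational view for a deployed triage system.
* **Degenerate bootstrap replicates** (undefined κ) are dropped and
  counted; more than 10% degenerate is an error, since the percentile
  summary would no longer describe the intended distribution.
* **Ties in AUC** count one half (mid-ranks); a binary reader contributes a
  single ROC operating point and gets no AUC.
* **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state (`withr::with_seed`); regenerating a report from the
  same inputs and seed is byte-identical, which is why report metadata
  carries seeds and policies but no timestamp.
* **Large counts.** κ is computed in double precision throughout; products
  of counts overflow 32-bit integers already at cohort sizes of a few
  tens of thousands.

## Problem sizes in the checks

The simulation-based checks use sizes chosen to keep Monte-Carlo noise
well below the tolerances they assert while remaining desk-scale: null
calibration uses 500 simulated cohorts of n = 1400 with 1000 bootstrap
iterations (3 binomial SEs around 5% is ±2.9 points); direction under a
sensitivity gap of 0.22 uses 200 cohorts; parameter recovery uses 200
cohorts (Monte-Carlo SE of the mean κ ≈ 0.003, against a ±0.03 band);
law-of-large-numbers checks of the generator run at n = 10⁵ against ±0.01
bands.

## Known limitations

* Two readers only; no Fleiss κ or multi-reader designs, and no weighted or
  multi-category κ.
* The published confusion counts allow exact recomputation of marginal
  statistics only; the study's printed paired differences and p-values
  depend on unpublished per-case pairing and are deliberately not
  reproduction targets. Two published κ values sit exactly on a 2-decimal
  rounding boundary of the values their own printed counts imply
  (recomputed 0.525 printed as 0.53; 0.197 printed as 0.19), consistent
  with a different rounding rule or denominator convention upstream.
* The hybrid is the OR rule only; "radiologist adjudicates the algorithm's
  flags" workflows are out of scope.
* No McNemar or other paired-proportion tests; the comparison statistic is
  the κ difference.
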