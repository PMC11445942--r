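---
title: "Methods: deriving sepsis-induced ARF phenotypes from EMR event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving sepsis-induced ARF phenotypes from EMR event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Septic ICU patients who progress to acute respiratory failure (ARF) requiring
invasive mechanical ventilation (IMV) are clinically heterogeneous: some fail
primarily from hypoxemia, others from renal/cardiac or hepatic/coagulopathic
multi-organ dysfunction. `arfpheno` implements a complete, rule-transparent
pipeline that derives data-driven phenotypes of this population from
routinely collected electronic-medical-record (EMR) events — laboratory
values and vital signs in the 24 hours before intubation — and then
characterizes the phenotypes' outcomes and their association with a
high-PEEP ventilation strategy.

Because ICU EMR extracts are protected data, the package ships a synthetic
cohort generator that emulates the study conditions end-to-end, so every
stage is exercised by tests without a data download.

## Pipeline stages and their assumptions

1. **Sepsis-3 identification** (`detect_sepsis_cohort()`). Six-organ SOFA
   scores are computed on an hourly grid with last-observation-carried-forward
   inputs inside a bounded staleness horizon (24 h labs, 8 h vitals — a
   documented convention, not a claim about any particular site's charting).
   Infection suspicion is the earlier member of an antibiotics/blood-culture
   pair (culture within 24 h after antibiotics, or antibiotics within 72 h
   after a culture — the canonical EMR operationalization; both windows are
   arguments). Onset is the earliest time within [suspicion − 48 h,
   suspicion + 24 h] at which total SOFA exceeds the pre-window baseline by
   ≥ 2; with no earlier data the baseline is 0 (no pre-existing organ
   dysfunction assumed). Missing component inputs score 0.
2. **Cohort construction** (`apply_inclusion()`). The index time is the first
   ventilator-parameter record (PEEP, tidal volume, plateau pressure); for
   surgical-ICU encounters, the first such record at or after 48 h past
   surgery end. Rules are applied in a fixed order (age ≥ 18, sepsis-3, ICU
   type, index exists, ≥ 24 h IMV from index, pre-index data present, not
   intubated before ICU admission) and the first failure is recorded, so
   exclusion reasons partition the cohort. The observation window is
   half-open, (index − 24 h, index]: the index-time record is the last
   pre-ventilation observation.
3. **Feature engineering** (`preprocess_fit()`). Per-encounter medians over
   the window; implausible values (outside closed per-feature physiologic
   bounds shipped with the package) to missing; features missing in
   strictly more than 85% of encounters dropped; chained-equation imputation
   (10 deterministic regression sweeps, median initialization — the sweeps
   draw no random numbers, so the imputation is reproducible by
   construction); a greedy correlation prune at |r| > 0.75 over pairs
   ordered by (original missingness, name), dropping the higher-missingness
   member (ties: later name); z-score scaling. The imputer and scaler are
   frozen and re-applied verbatim to validation cohorts.
4. **Phenotype derivation** (`model_select()`). UMAP (uwot; n_neighbors 15,
   min_dist 0.1, Euclidean, single-threaded for determinism) or PCA
   embeddings over a (method, dimension, k) grid; k-means (best of 10
   restarts) in embedding space; silhouette, Calinski–Harabasz and
   Davies–Bouldin computed on the embedded coordinates (the space in which
   the cluster portraits are drawn — an explicit choice, since the
   derivation study does not state its own). The winner takes the most
   first places across the three indices; ties break by silhouette, then
   smaller k, then smaller dimension. The full score table is always
   emitted so any alternative rule is auditable. Reconstruction MSE is the
   least-squares linear decoder from embedding back to the scaled features
   — exactly the orthogonal back-projection for PCA, and a uniform,
   comparable definition for UMAP, which has no native inverse map in R.
   A silhouette below 0.25 flags weak cluster structure.
5. **Characterization** (`summarize_phenotypes()`, `feature_importance()`,
   `canonical_label()`). Median/IQR tables with Kruskal–Wallis (continuous)
   and Chi-squared (categorical) tests; mortality is counted per patient,
   not per encounter. Feature attributions come from exact TreeSHAP
   contributions of a gradient-boosted cluster-vs-rest surrogate
   (xgboost `predcontrib`); the additivity identity is checked to float32
   precision. The canonical A–D labels formalize the expert naming: B has
   the lowest median P/F (severe hypoxemic failure); among the rest A has
   the highest creatinine (renal/cardiac MOD); of the remaining two, D has
   the higher bilirubin (tie-checked against lower platelets) and C is the
   residual mild-hypoxia cluster. Equal anchors leave the labeling
   explicitly ambiguous rather than forcing a bijection.
6. **Transfer** (`train_transfer()`, `apply_transfer()`). A multinomial
   logistic classifier on the scaled derivation features with a stratified
   80/20 split (stratification guards against a class missing from either
   side), benchmarked against random-forest, SVM and Gaussian naive-Bayes
   baselines on the identical split, then applied frozen — same imputer,
   same scaler, same features — to external cohorts.
7. **Outcomes** (`km_estimate()`, `logrank_test()`, `vfd28()`). Kaplan–Meier
   from the intubation index with administrative censoring at 28 days;
   discharge-alive is censored at discharge by default
   (`assume_alive_post_discharge = TRUE` switches to counting it as 28-day
   survival — the derivation study does not state its convention).
   Ventilator-free days use the critical-care standard: 0 if dead by day
   28, otherwise 28 minus ventilated days, requiring 48 h of sustained
   extubation.
8. **High-PEEP effects** (`fit_propensity()`, `match_pairs()`,
   `ate_and_balance()`). Treatment is a median PEEP ≥ 10 cmH2O over the
   first 24 h of IMV (the window is an argument). Logistic propensities on
   the stated confounders (ridge refit on separation); greedy 1:1
   nearest-neighbor matching without replacement on the logit scale with a
   0.2-SD caliper, treated units processed in descending propensity order
   (deterministic); ATE as the matched risk difference (negative = benefit)
   with a 2000-replicate seeded pair bootstrap CI; standardized mean
   differences per confounder before and after matching. This analysis is
   exploratory, exactly as framed in the source study.

## The synthetic cohort generator

`generate_arf_cohort()` draws each encounter from one of four latent
phenotypes whose per-feature medians and IQRs are anchored to the published
derivation-cohort summary table (prevalences 25.2/20.7/29.7/24.4%,
patient-level 28-day mortality 40.9/51.2/21.4/49.6%, high-PEEP prevalence
16.7/49.6/24.0/16.2%, treatment risk differences +0.04/−0.04/+0.07/−0.03).
Strictly positive, skewed labs are log-normal with a three-quantile
location-shifted fit (published quartile pairs are not log-symmetric around
the median; the shift makes median, Q1 and Q3 all reproduce exactly, and
shrinks to the plain log-normal when they are); bounded measurements are
truncated normal with the location solved numerically so the truncated
median hits the target. Matching (median, Q1, Q3) is the only calibration
rule, since summary tables publish nothing else; draws are clipped at the
plausibility bounds. Draws are
coupled by a Gaussian copula with organ-system block correlation (0.15) and
a few strong physiologic pairs (hemoglobin–hematocrit 0.95, PT–INR 0.97,
P/F–S/F 0.85, blood pressures), which gives the correlation-pruning stage
real work: the redundant S/F column, for instance, is pruned just as it
would be in real data.

Each encounter follows a fixed timeline: healthy baseline values after ICU
admission, a 6-hour deterioration ramp completing 24 h before the
ventilation index (36–72 h for medical ICU; past the 48-h post-surgical mark
for surgical ICU), then a stationary phenotype-specific plateau — so window
medians equal the drawn plateau and the SOFA rise of ≥ 2 around the
antibiotic/culture pair makes virtually every encounter sepsis-3-positive,
as in the source cohort, which was selected on that criterion. Vitals are
sampled hourly, labs 6-hourly; per-feature missingness removes whole
encounter-feature series (a BNP never ordered, not a BNP half-ordered);
roughly 1% of emitted observations are multiplied by 100 or 0.01 to emulate
unit-entry mistakes. Outcomes are assigned by calibrated logistic models: a
severity score built from the same confounders drives both high-PEEP
assignment and mortality (the confounding channel that propensity matching
must undo), with intercepts solved so the marginal treated fraction and the
untreated 28-day mortality match the configured values exactly; death times
are 28-day-truncated exponentials; death implies ventilation until death;
survivors remain in-system through day 28 (administrative censoring only),
with the early-discharge convention available through
`build_survival_records()`.

The sixteen published variables carry the printed medians and IQRs
verbatim. The remaining ~34 dictionary features (no public source pins the
exact site feature list, and the dictionary is deliberately configurable)
are the package's own design: each is assigned to one contrast axis —
renal/cardiac-vs-hepatic/coagulopathic (A vs D: troponin, MCV, fibrinogen,
potassium, phosphorus, liver enzymes, RDW, heart rate) or
inflammation/oxygenation (B vs C: temperature, ferritin, respiratory rate,
SpO2, differential counts) — with the other two phenotypes near the
midpoint, and with within-phenotype IQRs on the homogeneous end of the
plausible range. This axis balancing is what makes the four phenotypes
roughly equidistant and hence recoverable as four clusters; with companions
that merely track overall severity, the cohort degenerates into two
super-clusters (severe MOD vs not) and every internal-validity index prefers
k = 2 regardless of the selection rule. That observation is itself a useful
reading of why the published population separates into four groups: the
organ-injury axes must be close to orthogonal.

**What passing tests do and do not show.** The generator produces clean,
stationary plateaus, independent encounters, a single ventilation episode,
and missingness that is completely at random given the feature. Real EMR
cohorts have temporal trends inside the window, informative missingness,
repeated encounters and care-pattern artifacts. Tests passing on this
cohort validate the pipeline's logic and statistical machinery — not the
clinical claim that four phenotypes exist in any particular hospital's
data.

## Numerical choices and degenerate inputs

- Truncated-normal location solved by `uniroot` to 1e-9; log-normal
  calibration is closed-form and exact.
- Chained imputation requires ≥ 2 observed values per feature and errors on
  all-missing features (they should have been dropped upstream); rank
  deficiency in a sweep is handled by pivoted least squares with aliased
  coefficients set to zero. Imputed values are clamped to the feature's
  observed derivation range: besides keeping imputations physiologic, this
  bounds the frozen-coefficient sweeps on validation data, which are a
  fixed linear iteration and could otherwise diverge for rows with several
  interdependent missing cells.
- Zero-variance features are dropped with a warning at scaling.
- k-means on fewer distinct points than k errors; singleton clusters score
  silhouette 0 (standard convention).
- Propensities are clipped to (1e-8, 1 − 1e-8); (quasi-)separation triggers
  a ridge (glmnet, alpha 0, lambda 0.05) refit with a warning.
- All stochastic stages take explicit seeds; UMAP runs single-threaded so
  repeated runs are bit-identical, and pipeline artifact manifests record
  MD5 hashes to make reproducibility checkable.

## Problem sizes

The packaged study conditions use 2,000-encounter derivation cohorts and
1,000-encounter external cohorts for the end-to-end checks, 5,000 encounters
for generator-fidelity checks, and 20 replicates of 3,000 encounters for the
treatment-effect recovery study. The recovery study uses a treated minority
(20%) rather than phenotype B's observed 49.6% high-PEEP prevalence: with
treated and controls near 1:1, 1:1 matching without replacement cannot
balance the confounders (there are too few controls in the high-propensity
region), which is also why the source analysis's matched-set sizes are
small relative to its treated counts. These are sizes — sizes at which the Monte-Carlo error of
every reported quantity is small relative to its acceptance margin while a
full run stays comfortably interactive on a laptop.

## Known limitations

- Median aggregation discards within-window temporal information by design
  (a stated limitation of the approach itself).
- The cardiovascular SOFA component in generated data is driven by MAP only;
  `score_sofa()` supports vasopressor dosing (µg/kg/min), but the generator
  does not emit infusion events.
- Regression-value imputation pulls imputed cells of heavily skewed labs
  toward conditional means, which inflates post-imputation medians of those
  features (visible for total bilirubin at 20% missingness). Predictive-mean
  matching would avoid this but would break the pipeline's exact,
  reproducible collinear-imputation contract; summary tables should be read
  with this in mind.
- The canonical labeling rubric assumes the four phenotypes' anchor
  orderings; cohorts without those contrasts are labeled numerically.
- The ATE analysis is a matched risk difference with a bootstrap CI — no
  doubly-robust estimator, no competing risks, mirroring the exploratory
  framing of the source analysis.
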