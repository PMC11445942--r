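# arfpheno

Phenotyping sepsis-induced acute respiratory failure (ARF) from
electronic-medical-record event streams.

Septic ICU patients who need invasive mechanical ventilation (IMV) are a
heterogeneous population: the same syndrome spans severe hypoxemic
respiratory failure, renal/cardiac multi-organ dysfunction,
hepatic/coagulopathic dysfunction, and comparatively mild hypoxia. This
package implements, as tested R functions, a complete derivation-and-
validation workflow for data-driven phenotypes of this population:

- **Sepsis-3 detection** from raw timestamped events: hourly six-organ SOFA
  scoring (respiration, coagulation, hepatic, cardiovascular, CNS, renal;
  each 0–4), suspicion-time estimation from antibiotic/blood-culture pairs,
  and onset = earliest time in [suspicion − 48 h, +24 h] with an acute total-
  SOFA rise ≥ 2 over the pre-window baseline.
- **Cohort construction** around the index of (post-surgical) IMV and
  extraction of the 24-h pre-intubation window.
- **Feature engineering**: median aggregation, implausible-value handling,
  >85% missingness filter, deterministic chained-equation imputation,
  Pearson |r| > 0.75 correlation pruning, z-scoring — all frozen and
  re-applicable to external cohorts.
- **Phenotype derivation**: UMAP/PCA embedding, k-means, and model selection
  over (method, dimension, k) by silhouette, Calinski–Harabasz and
  Davies–Bouldin rank voting, with reconstruction MSE reported per
  embedding.
- **Characterization**: per-phenotype median/IQR tables with
  Kruskal–Wallis/Chi-squared tests, patient-level mortality, TreeSHAP
  feature attributions from a gradient-boosted surrogate, age-adjusted
  Charlson comorbidity index, and a canonical A–D labeling rubric
  (B = lowest P/F; A = highest creatinine among the rest; D = higher
  bilirubin / lower platelets; C = the residual mild cluster).
- **Transfer**: a frozen multinomial logistic classifier applied to external
  cohorts, benchmarked against random forest / SVM / naive Bayes.
- **Outcomes**: 28-day Kaplan–Meier survival from intubation, k-group
  log-rank tests, ventilator-free days (VFD-28).
- **High-PEEP treatment effects**: propensity-score matching (greedy 1:1,
  logit-scale 0.2-SD caliper), SMD balance diagnostics, and the average
  treatment effect on 28-day mortality as a matched risk difference with a
  pair-bootstrap CI (negative ATE = benefit of PEEP ≥ 10).

Because ICU EMR extracts are protected, the package includes a first-class
synthetic EHR generator (`generate_arf_cohort()`) producing four latent
phenotypes whose feature distributions are anchored to published
per-phenotype medians/IQRs, with realistic missingness, unit-entry outliers,
phenotype-dependent survival and confounded high-PEEP assignment — so the
whole pipeline is testable end to end.

## Worked example

```r
library(arfpheno)

specs <- default_phenotype_specs()           # the four study phenotypes A-D
g     <- generate_arf_cohort(specs, cohort_config(2000, seed = 11))

sep <- detect_sepsis_cohort(g$stream)        # sepsis-3 onsets
coh <- apply_inclusion(g$stream, sep)        # study in/exclusion rules
pp  <- preprocess_fit(extract_windows(g$stream, coh),
                      sort(coh$encounter_id[coh$included]))

sel <- model_select(pp$data, methods = "umap", dimensions = 2:3,
                    ks = 2:6, seed = 11)
sel$best
#> $method    "umap"
#> $dimension 3
#> $k         4

asg  <- assign_phenotype_indices(sel$clustering, rownames(pp$data))
summ <- summarize_phenotypes(pp$unscaled, asg, g$stream$meta)
canonical_label(summ$table)$mapping
#>   1   2   3   4
#> "D" "B" "C" "A"

adjusted_rand_index(asg$cluster, g$latent_labels[asg$encounter_id])
#> [1] 0.981
```

The selected model has four clusters; the canonical rubric maps them to the
named phenotypes (here cluster 4 is A, the renal/cardiac multi-organ-
dysfunction group, and cluster 2 is B, severe hypoxemic respiratory
failure), and the recovered partition agrees with the generator's latent
labels at an adjusted Rand index of 0.98. `run_pipeline()` executes the same
stages plus outcomes and the matched high-PEEP analysis, persisting every
intermediate (CSV/JSON) and a hash manifest for bit-level reproducibility.

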