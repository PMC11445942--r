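# Shared fixtures. The derivation cohort is expensive (n = 2000 encounters
# through the full pipeline), so it is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

derivation_fixture <- function() {
  if (!exists("deriv", envir = .fixture_env)) {
    specs <- default_phenotype_specs()
    g <- generate_arf_cohort(specs, cohort_config(2000, seed = 101))
    sep <- detect_sepsis_cohort(g$stream)
    coh <- apply_inclusion(g$stream, sep)
    w <- extract_windows(g$stream, coh)
    pp <- preprocess_fit(w, encounter_ids = sort(coh$encounter_id[coh$included]))
    assign("deriv", list(specs = specs, cohort = g, sepsis = sep,
                         inclusion = coh, prep = pp,
                         latent = g$latent_labels[rownames(pp$data)]),
           envir = .fixture_env)
  }
  get("deriv", envir = .fixture_env)
}

# A tiny hand-built event stream for rule-level tests.
toy_stream <- function(meta_overrides = list(), events = NULL) {
  meta <- data.frame(
    encounter_id = "E1", patient_id = "P1", hospital_id = "H1",
    icu_type = "MICU", age = 60, sex = "F", race = "White",
    ethnicity = "Non-Hispanic", admission_time = 0,
    surgery_end_time = NA_real_, vent_start = 40, vent_end = 80,
    abx_times = "12", culture_times = "14", death_time = NA_real_,
    discharge_time = 700, dx_codes = "038.9", stringsAsFactors = FALSE
  )
  for (nm in names(meta_overrides)) meta[[nm]] <- meta_overrides[[nm]]
  if (is.null(events)) {
    events <- data.frame(
      encounter_id = "E1", patient_id = "P1",
      time_hours = c(seq(0, 40, by = 1), 40),
      variable = c(rep("map", 41), "peep"),
      value = c(rep(80, 41), 8), stringsAsFactors = FALSE
    )
  }
  as_event_stream(events, meta)
}

# Model selection + canonical labeling on the derivation fixture (cached).
labeled_fixture <- function() {
  if (!exists("labeled", envir = .fixture_env)) {
    fx <- derivation_fixture()
    sel <- model_select(fx$prep$data, methods = "umap", dimensions = 2:3,
                        ks = 2:6, seed = 101)
    asg <- assign_phenotype_indices(sel$clustering, rownames(fx$prep$data))
    summ <- summarize_phenotypes(fx$prep$unscaled, asg, fx$cohort$stream$meta)
    lab <- canonical_label(summ$table)
    assign("labeled", list(sel = sel, asg = asg, summ = summ, lab = lab),
           envir = .fixture_env)
  }
  get("labeled", envir = .fixture_env)
}
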