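test_that("generation is byte-identical under a fixed seed", {
  specs <- default_phenotype_specs()
  cfg <- cohort_config(50, seed = 9)
  g1 <- generate_cohort(specs, cfg)
  g2 <- generate_cohort(specs, cfg)
  expect_identical(g1$stream$events, g2$stream$events)
  expect_identical(g1$stream$meta, g2$stream$meta)
  expect_identical(g1$latent_labels, g2$latent_labels)
  o1 <- generate_outcomes(g1$stream, g1$latent_labels, specs)
  o2 <- generate_outcomes(g2$stream, g2$latent_labels, specs)
  expect_identical(o1$events, o2$events)
  expect_identical(o1$meta, o2$meta)
})

test_that("degenerate prevalence assigns every encounter to the one phenotype", {
  spec <- default_phenotype_specs()$B
  spec$prevalence <- 1
  g <- generate_cohort(list(spec), cohort_config(4, seed = 1))
  expect_equal(unname(g$latent_labels), rep("B", 4))
})

test_that("spec validation rejects bad configurations", {
  specs <- default_phenotype_specs()
  specs$A$prevalence <- 0.5
  expect_error(generate_cohort(specs, cohort_config(10)), "sum to 1")
  specs <- default_phenotype_specs()
  specs$A$feature_params <- rbind(
    specs$A$feature_params,
    data.frame(feature = "made_up_lab", median = 1, q1 = 0.5, q3 = 2))
  expect_error(generate_cohort(specs, cohort_config(10)), "unknown feature")
  expect_error(cohort_config(3), "n_encounters")
  expect_error(cohort_config(10, outlier_rate = 0.2), "outlier_rate")
})

test_that("encounters carry >= 24 h of pre-ventilation observations", {
  g <- generate_cohort(default_phenotype_specs(), cohort_config(30, seed = 3))
  ev <- g$stream$events
  for (i in seq_len(nrow(g$stream$meta))) {
    id <- g$stream$meta$encounter_id[i]
    idx <- g$stream$meta$vent_start[i]
    tt <- ev$time_hours[ev$encounter_id == id]
    expect_gte(idx - min(tt), 24)
    expect_true(all(tt >= 0))
  }
})

test_that("realized per-feature cell missingness tracks the configuration", {
  g <- generate_cohort(default_phenotype_specs(), cohort_config(1500, seed = 5))
  coh <- data.frame(encounter_id = g$stream$meta$encounter_id,
                    included = TRUE,
                    index_time = g$stream$meta$vent_start)
  w <- extract_windows(g$stream, coh)
  m <- aggregate_median(w, sort(coh$encounter_id))
  dict <- feature_dictionary()
  for (f in c("map", "creatinine", "bnp", "d_dimer", "procalcitonin")) {
    conf <- dict$missingness[dict$feature == f]
    expect_lt(abs(mean(is.na(m[, f])) - conf), 0.03)
  }
})

test_that("latent-label frequencies match prevalences within the binomial 99% CI", {
  specs <- default_phenotype_specs()
  g <- generate_cohort(specs, cohort_config(2000, seed = 17))
  tab <- table(g$latent_labels) / 2000
  for (s in specs) {
    half <- 2.576 * sqrt(s$prevalence * (1 - s$prevalence) / 2000)
    expect_lt(abs(tab[[s$label]] - s$prevalence), half + 1e-12)
  }
})

test_that("plateau medians converge to the configured values", {
  spec <- default_phenotype_specs()$B
  d <- simulate_phenotype_data(spec, 4000, seed = 21)
  expect_lt(abs(median(d$pf_ratio) - 123.3) / 123.3, 0.1)
  expect_lt(abs(median(d$creatinine) - 1.3) / 1.3, 0.1)
  expect_lt(abs(median(d$platelets) - 209) / 209, 0.1)
})

test_that("null treatment effect yields no mortality difference absent confounding", {
  spec <- default_phenotype_specs()$C
  spec$treatment_risk_difference <- 0
  spec$mortality_confounding <- 0
  d <- simulate_phenotype_data(spec, 10000, seed = 8)
  diff <- mean(d$dead28[d$treated]) - mean(d$dead28[!d$treated])
  expect_lt(abs(diff), 0.02)
})

test_that("zero mortality leaves everyone censored alive at day 28", {
  spec <- default_phenotype_specs()$C
  spec$mortality_28d <- 0
  spec$treatment_risk_difference <- 0
  d <- simulate_phenotype_data(spec, 500, seed = 2)
  expect_false(any(d$dead28))
  expect_true(all(d$time_days == 28))
})

test_that("exponential hazard reproduces closed-form 28-day survival", {
  spec <- default_phenotype_specs()$C
  lam <- 0.02
  spec$mortality_28d <- 1 - exp(-lam * 28)
  spec$hazard_rate <- lam
  spec$treatment_risk_difference <- 0
  spec$mortality_confounding <- 0
  d <- simulate_phenotype_data(spec, 10000, seed = 13)
  s28 <- mean(!d$dead28)
  se <- sqrt(0.571 * 0.429 / 10000)
  expect_lt(abs(s28 - exp(-lam * 28)), 3 * se)
  # death times are (truncated) exponential: compare mean to closed form
  dt <- d$time_days[d$dead28]
  m_theory <- 1 / lam - 28 * exp(-28 * lam) / (1 - exp(-28 * lam))
  expect_lt(abs(mean(dt) - m_theory), 0.6)
})

test_that("treated fraction is calibrated to the configured prevalence", {
  spec <- default_phenotype_specs()$B   # treatment_prevalence 0.496
  d <- simulate_phenotype_data(spec, 5000, seed = 4)
  expect_lt(abs(mean(d$treated) - 0.496), 0.025)
})

test_that("death implies ventilation until death, no extubation-alive record", {
  g <- generate_arf_cohort(default_phenotype_specs(), cohort_config(200, seed = 6))
  meta <- g$stream$meta
  dead <- !is.na(meta$death_time)
  expect_true(any(dead))
  expect_equal(meta$vent_end[dead], meta$death_time[dead])
  expect_true(all(meta$death_time[dead] > meta$vent_start[dead]))
  # no event is recorded after death
  last_obs <- tapply(g$stream$events$time_hours,
                     g$stream$events$encounter_id, max)
  expect_true(all(meta$death_time[dead] >=
                    last_obs[meta$encounter_id[dead]] - 1e-9))
})

test_that("cohort round-trips through the CSV writer and readers", {
  g <- generate_arf_cohort(default_phenotype_specs(), cohort_config(20, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(g, dir, specs = default_phenotype_specs())
  ev <- read_events(file.path(dir, "events.csv"))
  me <- read_encounter_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(ev), nrow(g$stream$events))
  expect_equal(me$encounter_id, g$stream$meta$encounter_id)
  side <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(side$latent_labels), g$latent_labels)
})
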