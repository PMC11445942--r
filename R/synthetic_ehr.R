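# Synthetic multi-phenotype EHR cohort generator. Encounters are drawn from
# one of four latent phenotypes; each phenotype's per-feature marginals are
# calibrated to published medians/IQRs via a Gaussian copula with
# organ-system block correlation. Every encounter follows the same timeline:
# healthy baseline values after ICU admission, a 6-h deterioration ramp that
# completes 24 h before the ventilation index, then a stationary
# phenotype-specific plateau, so that window medians equal the drawn plateau.

.rand_labels <- function(specs, n) {
  labs <- vapply(specs, `[[`, character(1), "label")
  prev <- vapply(specs, `[[`, numeric(1), "prevalence")
  sample(labs, n, replace = TRUE, prob = prev)
}

# Draw the per-encounter plateau feature matrix for one set of specs.
# Assumes the RNG is already seeded by the caller.
.draw_plateau <- function(specs, labels) {
  dict <- feature_dictionary()
  feats <- dict$feature
  n <- length(labels)
  R <- copula_correlation(feats)
  L <- chol(R)
  X <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (s in specs) {
    idx <- which(labels == s$label)
    if (!length(idx)) next
    W <- matrix(stats::rnorm(length(idx) * length(feats)), nrow = length(idx))
    U <- stats::pnorm(W %*% L)
    fp <- s$feature_params[match(feats, s$feature_params$feature), ]
    for (j in seq_along(feats)) {
      marg <- .calibrate_marginal(dict$family[j], fp$median[j], fp$q1[j],
                                  fp$q3[j], dict$lower[j], dict$upper[j])
      # live-patient values are physiologically bounded; clip log-normal tails
      X[idx, j] <- pmin(pmax(.q_marginal(U[, j], marg), dict$lower[j]),
                        dict$upper[j])
    }
  }
  X[, "gcs_total"] <- pmin(15, pmax(3, round(X[, "gcs_total"])))
  X
}

# Phenotype-weighted admission diagnosis codes (always includes septicemia).
.sample_dx <- function(labels) {
  cm <- charlson_map()
  cats <- unique(cm$category)
  base <- stats::setNames(rep(0.04, length(cats)), cats)
  w <- list(
    A = c(renal_disease = 0.50, congestive_heart_failure = 0.45,
          myocardial_infarction = 0.12, diabetes_complicated = 0.15),
    B = c(chronic_pulmonary_disease = 0.30, diabetes_uncomplicated = 0.12),
    C = c(diabetes_uncomplicated = 0.15, chronic_pulmonary_disease = 0.12),
    D = c(mild_liver_disease = 0.30, moderate_severe_liver_disease = 0.22,
          malignancy = 0.15)
  )
  n <- length(labels)
  out <- rep("038.9", n)
  for (cat in cats) {
    p <- rep(base[[cat]], n)
    for (l in names(w)) {
      if (cat %in% names(w[[l]])) p[labels == l] <- w[[l]][[cat]]
    }
    hit <- stats::runif(n) < p
    if (any(hit)) {
      pref <- cm$icd9_prefix[cm$category == cat]
      code <- sample(pref, sum(hit), replace = TRUE)
      out[hit] <- paste(out[hit], code, sep = ";")
    }
  }
  out
}

#' Generate a synthetic ARF cohort event stream
#'
#' Draws `config$n_encounters` encounters, each from exactly one latent
#' phenotype, and expands them into a long-format timestamped event stream
#' (hourly vitals, 6-hourly labs) with per-feature missingness, injected
#' implausible outliers, antibiotic/blood-culture times that trigger sepsis-3
#' suspicion, and a ventilation index at 36-72 h (MICU) or beyond the 48-h
#' post-surgical mark (SICU). Deterministic given `config$seed`.
#'
#' @param specs list of [phenotype_spec()]; prevalences must sum to 1.
#' @param config a [cohort_config()].
#' @return list with `stream` (class `arf_event_stream`: `$events`,
#'   `$meta`) and `latent_labels` (named character, encounter -> label).
#'   The drawn per-encounter plateau feature matrix is attached to the
#'   stream as attribute `"plateau"` for calibration checks and for the
#'   outcome-assignment stage.
#' @seealso [generate_outcomes()] to add survival, ventilation stop times and
#'   PEEP exposure.
#' @export
generate_cohort <- function(specs, config) {
  validate_specs(specs)
  dict <- feature_dictionary()
  feats <- dict$feature
  miss <- stats::setNames(dict$missingness, feats)
  if (!is.null(config$missingness)) {
    unknown <- setdiff(names(config$missingness), feats)
    if (length(unknown)) stop("unknown feature in missingness config: ",
                              paste(unknown, collapse = ", "))
    miss[names(config$missingness)] <- config$missingness
  }
  n <- config$n_encounters
  set.seed(config$seed)
  labels <- .rand_labels(specs, n)
  X <- .draw_plateau(specs, labels)

  if (config$icu_type == "MICU") {
    surgery_end <- rep(NA_real_, n)
    index <- round(stats::runif(n, 36, 72))
  } else {
    surgery_end <- round(stats::runif(n, 5, 15))
    index <- surgery_end + 48 + round(stats::runif(n, 4, 26))
  }

  measured <- matrix(stats::runif(n * length(feats)), n) >=
    matrix(miss, n, length(feats), byrow = TRUE)
  scale_f <- .iqr_sd(dict$ill_q1, dict$ill_q3)

  enc_l <- list(); t_l <- list(); var_l <- list(); val_l <- list()
  for (j in seq_along(feats)) {
    step <- if (dict$kind[j] == "vital") config$sampling_resolution_hours else 6
    ids <- which(measured[, j])
    if (!length(ids)) next
    counts <- floor(index[ids] / step) + 1L
    enc <- rep(ids, counts)
    tt <- (sequence(counts) - 1L) * step
    if (feats[j] == "weight_kg") {
      v <- X[enc, j]
    } else {
      ramp <- pmin(1, pmax(0, (tt - (index[enc] - 30)) / 6))
      v <- dict$healthy[j] + ramp * (X[enc, j] - dict$healthy[j])
      v <- v + stats::rnorm(length(v), 0, 0.08 * scale_f[j])
      v <- pmin(pmax(v, dict$lower[j]), dict$upper[j])
    }
    if (feats[j] == "gcs_total") v <- round(v)
    if (config$outlier_rate > 0) {
      o <- stats::runif(length(v)) < config$outlier_rate
      if (any(o)) {
        fac <- ifelse(stats::runif(sum(o)) < 0.5, 100, 0.01)
        v[o] <- v[o] * fac
      }
    }
    enc_l[[j]] <- enc; t_l[[j]] <- tt
    var_l[[j]] <- rep(feats[j], length(v)); val_l[[j]] <- v
  }

  eid <- sprintf("%s-E%05d", config$hospital_id, seq_len(n))
  pid <- sprintf("%s-P%05d", config$hospital_id, seq_len(n))
  if (n >= 40) {  # a few patients contribute two encounters
    ndup <- max(1L, round(0.03 * n))
    dup <- sample(seq_len(n), ndup)
    donor <- sample(seq_len(n), ndup)
    ok <- dup != donor
    pid[dup[ok]] <- pid[donor[ok]]
  }

  events <- data.frame(
    encounter_id = eid[unlist(enc_l)],
    patient_id = pid[unlist(enc_l)],
    time_hours = unlist(t_l),
    variable = unlist(var_l),
    value = unlist(val_l),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$encounter_id, events$time_hours, events$variable), ]
  rownames(events) <- NULL

  abx <- index - 26 + stats::runif(n, 0, 4)
  cult <- abx + stats::runif(n, 0.5, 12)
  age <- round(.qtruncnorm(stats::runif(n), 62.3, 15.5, 16, 100))
  meta <- data.frame(
    encounter_id = eid, patient_id = pid, hospital_id = config$hospital_id,
    icu_type = config$icu_type, age = age,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.542, 0.458)),
    race = sample(c("Black", "White", "Other"), n, replace = TRUE,
                  prob = c(0.485, 0.431, 0.084)),
    ethnicity = sample(c("Non-Hispanic", "Hispanic", "Unknown"), n,
                       replace = TRUE, prob = c(0.888, 0.039, 0.073)),
    admission_time = 0, surgery_end_time = surgery_end,
    vent_start = index, vent_end = NA_real_,
    abx_times = sprintf("%.3f", abx), culture_times = sprintf("%.3f", cult),
    death_time = NA_real_, discharge_time = NA_real_,
    dx_codes = .sample_dx(labels),
    stringsAsFactors = FALSE
  )
  stream <- structure(list(events = events, meta = meta),
                      class = "arf_event_stream")
  attr(stream, "plateau") <- X
  attr(stream, "config") <- config
  list(stream = stream, latent_labels = stats::setNames(labels, eid))
}

# Confounder z-scores within a phenotype, using the spec's own configured
# location/scale (deterministic, no data-dependent standardization).
.spec_zscores <- function(X, spec, conf) {
  fp <- spec$feature_params
  z <- sapply(conf, function(f) {
    i <- match(f, fp$feature)
    if (is.na(i)) stop("confounder '", f, "' not in spec feature_params")
    (X[, f] - fp$median[i]) / .iqr_sd(fp$q1[i], fp$q3[i])
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, conf))
  z
}

.calibrate_intercept <- function(lp, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

# Severity score shared between the treatment and mortality models: this is
# the confounding channel.
.severity_coefs <- c(pf_ratio = -0.6, lactate = 0.6, creatinine = 0.3, map = -0.3)

# Assign treatment and 28-day survival for encounters with plateau features
# X (rows) and latent labels. RNG must be seeded by the caller.
.assign_outcomes <- function(X, labels, specs) {
  n <- length(labels)
  treated <- logical(n); dead <- logical(n); death_day <- rep(NA_real_, n)
  p_treat <- numeric(n); p_death <- numeric(n)
  for (s in specs) {
    idx <- which(labels == s$label)
    if (!length(idx)) next
    coefs <- s$high_peep_propensity_coefs
    zt <- .spec_zscores(X[idx, , drop = FALSE], s, names(coefs))
    lp_t <- drop(zt %*% coefs)
    a <- .calibrate_intercept(lp_t, s$treatment_prevalence)
    pt <- stats::plogis(a + lp_t)
    tr <- stats::runif(length(idx)) < pt

    zs <- .spec_zscores(X[idx, , drop = FALSE], s, names(.severity_coefs))
    sev <- drop(zs %*% .severity_coefs) / sqrt(sum(.severity_coefs^2))
    lp_m <- s$mortality_confounding * sev
    if (s$mortality_28d <= 0) {
      pd <- rep(0, length(idx))
    } else if (s$mortality_28d >= 1) {
      pd <- rep(1, length(idx))
    } else {
      b <- .calibrate_intercept(lp_m, s$mortality_28d)
      pd <- stats::plogis(b + lp_m)
    }
    pd <- pmin(1, pmax(0, pd + tr * s$treatment_risk_difference))
    dd <- stats::runif(length(idx)) < pd
    lam <- s$hazard_rate
    u <- stats::runif(length(idx))
    dtime <- -log(1 - u * (1 - exp(-28 * lam))) / lam
    treated[idx] <- tr; dead[idx] <- dd
    death_day[idx][dd] <- dtime[dd]
    p_treat[idx] <- pt; p_death[idx] <- pd
  }
  data.frame(treated = treated, dead28 = dead, death_day = death_day,
             p_treat = p_treat, p_death = p_death)
}

#' Assign outcomes, PEEP exposure and ventilation stop times
#'
#' Augments a generated event stream with: high-PEEP assignment from a
#' logistic model of configured confounders (intercept calibrated so the
#' marginal treated fraction matches each spec's `treatment_prevalence`);
#' 28-day death indicators whose untreated marginal equals `mortality_28d`
#' and whose treated marginal is shifted by `treatment_risk_difference`;
#' death times from a 28-day-truncated exponential with the spec's
#' `hazard_rate`; ventilation stop, death and discharge times consistent
#' with survival (death implies ventilation until death); and hourly PEEP /
#' ventilator-parameter events over the first 24 h of ventilation.
#'
#' @param stream an `arf_event_stream` from [generate_cohort()].
#' @param latent_labels named character vector, encounter -> phenotype label.
#' @param specs the phenotype specs used to generate the stream.
#' @param seed RNG seed; default derives from the generating config.
#' @return the augmented stream; `attr(, "truth")` holds per-encounter latent
#'   label, treatment flag, death indicator and assignment probabilities for
#'   test harnesses.
#' @export
generate_outcomes <- function(stream, latent_labels, specs, seed = NULL) {
  meta <- stream$meta
  if (anyNA(latent_labels[meta$encounter_id]))
    stop("missing latent label for some encounters")
  labels <- unname(latent_labels[meta$encounter_id])
  if (is.null(seed)) {
    cfg <- attr(stream, "config")
    seed <- if (!is.null(cfg)) cfg$seed + 1000003L else 1000003L
  }
  set.seed(seed)
  X <- attr(stream, "plateau")
  if (is.null(X)) X <- .window_medians_matrix(stream, meta$vent_start)
  out <- .assign_outcomes(X, labels, specs)

  cfg <- attr(stream, "config")
  vmed <- if (!is.null(cfg)) cfg$vent_days_median else
    c(A = 10.4, B = 10.4, C = 8.4, D = 11.1)
  vm <- ifelse(labels %in% names(vmed), vmed[labels], 10)
  vent_days <- pmax(stats::qlnorm(stats::runif(nrow(meta)), log(vm), 0.5), 1.05)

  index <- meta$vent_start
  death_time <- ifelse(out$dead28, index + out$death_day * 24, NA_real_)
  vent_end <- ifelse(out$dead28, death_time, index + vent_days * 24)
  discharge <- ifelse(out$dead28, death_time,
                      index + 28 * 24 + stats::runif(nrow(meta), 0, 240))
  meta$vent_end <- vent_end
  meta$death_time <- death_time
  meta$discharge_time <- discharge

  # ventilator-parameter events: hourly PEEP for the first 24 h of IMV
  n_peep <- pmax(1L, pmin(24L, floor((vent_end - index)) + 1L))
  enc <- rep(seq_len(nrow(meta)), n_peep)
  tt <- index[enc] + (sequence(n_peep) - 1L)
  peep <- ifelse(out$treated[enc],
                 pmax(10, round(stats::rnorm(length(enc), 12, 1.5))),
                 pmin(9, pmax(4, round(stats::rnorm(length(enc), 6, 1.5)))))
  vent_ev <- data.frame(
    encounter_id = meta$encounter_id[enc],
    patient_id = meta$patient_id[enc],
    time_hours = tt, variable = "peep", value = peep,
    stringsAsFactors = FALSE
  )
  tv <- data.frame(
    encounter_id = meta$encounter_id, patient_id = meta$patient_id,
    time_hours = index, variable = "tidal_volume",
    value = round(stats::rnorm(nrow(meta), 450, 40)),
    stringsAsFactors = FALSE
  )
  events <- rbind(stream$events, vent_ev, tv)
  events <- events[order(events$encounter_id, events$time_hours, events$variable), ]
  rownames(events) <- NULL
  stream$events <- events
  stream$meta <- meta
  attr(stream, "truth") <- data.frame(
    encounter_id = meta$encounter_id, label = labels,
    treated = out$treated, dead28 = out$dead28, death_day = out$death_day,
    p_treat = out$p_treat, p_death = out$p_death,
    stringsAsFactors = FALSE
  )
  stream
}

# Fallback confounder matrix when the generator's plateau is unavailable:
# per-encounter medians over the 24 h preceding the ventilation index.
.window_medians_matrix <- function(stream, index) {
  feats <- feature_dictionary()$feature
  ev <- stream$events
  idx <- stats::setNames(index, stream$meta$encounter_id)
  keep <- ev$variable %in% feats &
    ev$time_hours > idx[ev$encounter_id] - 24 &
    ev$time_hours <= idx[ev$encounter_id]
  ev <- ev[keep, ]
  X <- matrix(NA_real_, nrow(stream$meta), length(feats),
              dimnames = list(NULL, feats))
  agg <- stats::aggregate(value ~ encounter_id + variable, ev, stats::median)
  i <- match(agg$encounter_id, stream$meta$encounter_id)
  j <- match(agg$variable, feats)
  X[cbind(i, j)] <- agg$value
  X
}

#' Generate a complete synthetic cohort (events + outcomes)
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [generate_outcomes()].
#'
#' @inheritParams generate_cohort
#' @return list with `stream`, `latent_labels`, and `truth` (the sidecar
#'   data.frame of latent labels, treatment flags and death indicators).
#' @export
generate_arf_cohort <- function(specs = default_phenotype_specs(), config) {
  g <- generate_cohort(specs, config)
  stream <- generate_outcomes(g$stream, g$latent_labels, specs)
  list(stream = stream, latent_labels = g$latent_labels,
       truth = attr(stream, "truth"))
}

#' Simulate one phenotype at the encounter-feature level
#'
#' Lightweight path through the generator's core (no event-stream
#' expansion): draws the plateau feature matrix for a single phenotype spec
#' and assigns confounded treatment and 28-day outcomes. Used for
#' treatment-effect recovery studies where event-level detail is
#' irrelevant.
#'
#' @param spec a [phenotype_spec()].
#' @param n number of encounters.
#' @param seed RNG seed.
#' @return data.frame of plateau features plus `age`, `treated`, `dead28`,
#'   `time_days` (death day, or 28 if censored alive) and `event`.
#' @export
simulate_phenotype_data <- function(spec, n, seed = 1L) {
  set.seed(seed)
  labels <- rep(spec$label, n)
  X <- .draw_plateau(list(spec), labels)
  out <- .assign_outcomes(X, labels, list(spec))
  df <- as.data.frame(X)
  df$age <- round(.qtruncnorm(stats::runif(n), 62.3, 15.5, 16, 100))
  df$treated <- out$treated
  df$dead28 <- out$dead28
  df$time_days <- ifelse(out$dead28, out$death_day, 28)
  df$event <- out$dead28
  df
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `events.csv` (long format), `metadata.csv`, and a JSON sidecar
#' `truth.json` with latent labels and configured true treatment effects.
#'
#' @param cohort result of [generate_arf_cohort()].
#' @param dir output directory (created if needed).
#' @param specs specs used (for the sidecar's true effects); optional.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, specs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_ev <- file.path(dir, "events.csv")
  p_me <- file.path(dir, "metadata.csv")
  p_tr <- file.path(dir, "truth.json")
  utils::write.csv(cohort$stream$events, p_ev, row.names = FALSE)
  utils::write.csv(cohort$stream$meta, p_me, row.names = FALSE)
  side <- list(latent_labels = as.list(cohort$latent_labels))
  if (!is.null(specs)) {
    side$true_effects <- lapply(specs, function(s) list(
      label = s$label, mortality_28d = s$mortality_28d,
      treatment_prevalence = s$treatment_prevalence,
      treatment_risk_difference = s$treatment_risk_difference
    ))
  }
  jsonlite::write_json(side, p_tr, auto_unbox = TRUE, digits = NA)
  invisible(c(p_ev, p_me, p_tr))
}
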