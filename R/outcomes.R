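# 28-day outcome machinery: survival records from intubation, Kaplan-Meier
# estimation, log-rank testing, and ventilator-free days.

#' Build 28-day survival records from encounter metadata
#'
#' Time zero is the ventilation index. Deaths within 28 days are events;
#' everyone else is censored at day 28 (administrative) or, by default, at
#' hospital discharge when that comes first. `assume_alive_post_discharge`
#' switches to treating discharge-alive as survival to day 28.
#'
#' @param meta encounter metadata (vent_start/vent_end, death_time,
#'   discharge_time in hours).
#' @param index_times named vector, encounter -> index time (hours);
#'   defaults to `vent_start`.
#' @param phenotypes optional named label vector.
#' @param treated optional named logical vector (high-PEEP exposure).
#' @param assume_alive_post_discharge censoring convention switch.
#' @return data.frame(encounter_id, phenotype, time (days), event, treated,
#'   index_time, vent_start, vent_end, dead28).
#' @export
build_survival_records <- function(meta, index_times = NULL, phenotypes = NULL,
                                   treated = NULL,
                                   assume_alive_post_discharge = FALSE) {
  idx <- if (is.null(index_times)) stats::setNames(meta$vent_start, meta$encounter_id)
  else index_times
  it <- unname(idx[meta$encounter_id])
  death_d <- (meta$death_time - it) / 24
  disc_d <- (meta$discharge_time - it) / 24
  if (any(!is.na(death_d) & death_d < 0)) stop("negative time-to-death")
  event <- !is.na(death_d) & death_d <= 28
  cens <- if (assume_alive_post_discharge) rep(28, nrow(meta)) else
    pmin(28, ifelse(is.na(disc_d), 28, disc_d))
  time <- ifelse(event, pmin(death_d, 28), cens)
  data.frame(
    encounter_id = meta$encounter_id,
    phenotype = if (is.null(phenotypes)) NA_character_ else
      unname(phenotypes[meta$encounter_id]),
    time = time, event = as.integer(event),
    treated = if (is.null(treated)) NA else unname(treated[meta$encounter_id]),
    index_time = it, vent_start = meta$vent_start, vent_end = meta$vent_end,
    dead28 = event, stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood-variance confidence bands
#' (survival::survfit).
#'
#' @param time event/censoring times in days (>= 0).
#' @param event 1 = death, 0 = censored.
#' @param conf_level confidence level for the bands.
#' @return list with `curve` (data.frame time, n_risk, n_event, surv, lower,
#'   upper) and `fit` (the survfit object).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (!length(time)) stop("no records")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  list(curve = curve, fit = fit)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km a [km_estimate()] result.
#' @param t times (days).
#' @return survival probabilities (right-continuous step function).
#' @export
km_survival_at <- function(km, t) {
  cv <- km$curve[km$curve$n_event > 0 | km$curve$n_risk > 0, ]
  vapply(t, function(tt) {
    s <- cv$surv[cv$time <= tt]
    if (!length(s)) 1 else s[length(s)]
  }, numeric(1))
}

#' K-group log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 distinct groups required).
#' @return list(statistic, df, p).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Ventilator-free days at 28 days
#'
#' The critical-care convention: 0 for patients dead by day 28; otherwise
#' 28 minus days ventilated within the 28-day window, provided the final
#' extubation is sustained for at least `sustain_hours` before day 28
#' (otherwise 0).
#'
#' @param index_time index of ventilation, hours.
#' @param vent_intervals list (one element per encounter) of two-column
#'   matrices of `[start, stop)` ventilation intervals in hours.
#' @param dead28 logical, dead by day 28.
#' @param sustain_hours sustained-extubation requirement (default 48).
#' @return numeric vector of VFDs in `[0, 28]`.
#' @export
vfd28 <- function(index_time, vent_intervals, dead28, sustain_hours = 48) {
  n <- length(index_time)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (isTRUE(dead28[i])) { out[i] <- 0; next }
    iv <- vent_intervals[[i]]
    if (is.null(iv) || !nrow(iv)) { out[i] <- 28; next }
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("overlapping ventilation intervals")
    rel <- cbind(pmax(iv[, 1] - index_time[i], 0) / 24,
                 pmin(pmax(iv[, 2] - index_time[i], 0) / 24, 28))
    days_vent <- sum(pmax(rel[, 2] - rel[, 1], 0))
    last_stop <- max(rel[, 2])
    sustained <- (28 - last_stop) * 24 >= sustain_hours
    out[i] <- if (sustained) max(0, 28 - days_vent) else 0
  }
  out
}

#' Per-encounter and per-phenotype VFD summary from survival records
#'
#' @param records output of [build_survival_records()].
#' @return list(per_encounter, per_phenotype mean VFD).
#' @export
vfd28_summary <- function(records) {
  iv <- lapply(seq_len(nrow(records)), function(i) {
    if (is.na(records$vent_start[i])) return(matrix(numeric(0), 0, 2))
    end <- if (is.na(records$vent_end[i])) records$vent_start[i] + 28 * 24
    else records$vent_end[i]
    matrix(c(records$vent_start[i], end), 1, 2)
  })
  v <- vfd28(records$index_time, iv, records$dead28)
  per <- data.frame(encounter_id = records$encounter_id,
                    phenotype = records$phenotype, vfd = v,
                    stringsAsFactors = FALSE)
  byph <- tapply(v, records$phenotype, mean)
  list(per_encounter = per,
       per_phenotype = data.frame(phenotype = names(byph),
                                  mean_vfd = as.numeric(byph),
                                  stringsAsFactors = FALSE))
}
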