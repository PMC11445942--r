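# Rule-based sepsis-3 identification from EMR events, in four steps:
# (a) six-organ SOFA scoring on an hourly grid, (b) suspicion-time estimation
# from antibiotic and blood-culture timing, (c) detection of an acute SOFA
# increase >= 2, (d) onset-time assignment within a window around suspicion.

.sofa_components <- c("respiration", "coagulation", "hepatic",
                      "cardiovascular", "cns", "renal")
.sofa_inputs <- c(respiration = "pf_ratio", coagulation = "platelets",
                  hepatic = "bilirubin_total", cardiovascular = "map",
                  cns = "gcs_total", renal = "creatinine")
.vasopressors <- c("dopamine", "norepinephrine", "epinephrine", "dobutamine")

# Vectorized one-component score for a vector of input values (NA allowed).
.component_score <- function(component, values, ventilated,
                             doses = NULL) {
  rub <- sofa_rubric()
  rows <- rub[rub$component == component, ]
  n <- length(values)
  if (length(ventilated) == 1L) ventilated <- rep(ventilated, n)
  score <- integer(n)
  for (r in seq_len(nrow(rows))) {
    var <- rows$variable[r]
    v <- if (var %in% .vasopressors) {
      if (is.null(doses) || is.null(doses[[var]])) rep(NA_real_, n) else doses[[var]]
    } else values
    sat <- !is.na(v) & v >= rows$min[r] & v < rows$max[r]
    if (rows$support[r] == "vent") sat <- sat & ventilated
    score[sat] <- pmax(score[sat], rows$score[r])
  }
  score
}

#' Score the six SOFA components at one time point
#'
#' Components whose inputs are absent score 0 (the canonical no-data-no-
#' dysfunction convention; a carry-forward alternative is available through
#' the staleness horizon of [sofa_track()]). Vasopressor doses are in
#' ug/kg/min.
#'
#' @param observations named numeric vector/list; recognized names are
#'   `pf_ratio`, `platelets` (1e3/uL), `bilirubin_total` (mg/dL), `map`
#'   (mmHg), `gcs_total`, `creatinine` (mg/dL).
#' @param vasopressors named numeric vector of doses among `dopamine`,
#'   `norepinephrine`, `epinephrine`, `dobutamine`.
#' @param ventilated logical; mechanical ventilatory support (gates the
#'   respiratory 3-4 bands).
#' @return list with the six component scores and `total`.
#' @examples
#' score_sofa(c(platelets = 90))$coagulation  # 2
#' @export
score_sofa <- function(observations = c(), vasopressors = c(), ventilated = FALSE) {
  obs <- unlist(observations)
  vp <- unlist(vasopressors)
  if (length(obs) && any(!is.na(obs) & obs < 0))
    stop("negative lab/vital values: ",
         paste(names(obs)[!is.na(obs) & obs < 0], collapse = ", "))
  if (length(vp) && any(!is.na(vp) & vp < 0)) stop("negative vasopressor doses")
  doses <- as.list(vp)
  out <- lapply(.sofa_components, function(cmp) {
    v <- if (.sofa_inputs[[cmp]] %in% names(obs)) obs[[.sofa_inputs[[cmp]]]] else NA_real_
    .component_score(cmp, v, ventilated, doses)
  })
  names(out) <- .sofa_components
  out <- lapply(out, as.integer)
  out$total <- sum(unlist(out))
  out
}

.parse_times <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Hourly SOFA track for one encounter
#'
#' Builds a regular-grid SOFA series from an event stream using
#' last-observation-carried-forward inputs within a bounded staleness
#' horizon (default 24 h for labs, 8 h for vitals and vasopressor doses).
#' Ventilation status is taken from the encounter's ventilation episode.
#'
#' @param stream an `arf_event_stream`.
#' @param encounter_id encounter to score.
#' @param resolution grid step in hours.
#' @param staleness named vector `c(lab=, vital=)` of carry-forward horizons.
#' @return data.frame with columns time, the six components, and total;
#'   zero rows if the encounter has no scoreable observations.
#' @export
sofa_track <- function(stream, encounter_id, resolution = 1,
                       staleness = c(lab = 24, vital = 8)) {
  meta <- stream$meta[stream$meta$encounter_id == encounter_id, ]
  if (!nrow(meta)) stop("encounter not found: ", encounter_id)
  ev <- stream$events[stream$events$encounter_id == encounter_id, ]
  .sofa_track_events(ev, meta, resolution, staleness)
}

.sofa_track_events <- function(ev, meta, resolution = 1,
                               staleness = c(lab = 24, vital = 8)) {
  vars <- c(unname(.sofa_inputs), .vasopressors)
  ev <- ev[ev$variable %in% vars & !is.na(ev$value), ]
  if (!nrow(ev)) {
    return(data.frame(time = numeric(0), respiration = integer(0),
                      coagulation = integer(0), hepatic = integer(0),
                      cardiovascular = integer(0), cns = integer(0),
                      renal = integer(0), total = integer(0)))
  }
  dict <- feature_dictionary()
  grid <- seq(0, max(ev$time_hours), by = resolution)
  locf <- function(var) {
    e <- ev[ev$variable == var, ]
    if (!nrow(e)) return(rep(NA_real_, length(grid)))
    e <- e[order(e$time_hours), ]
    kind <- dict$kind[match(var, dict$feature)]
    hor <- if (!is.na(kind) && kind == "lab") staleness[["lab"]] else staleness[["vital"]]
    i <- findInterval(grid, e$time_hours)
    v <- ifelse(i > 0, e$value[pmax(i, 1)], NA_real_)
    age <- grid - ifelse(i > 0, e$time_hours[pmax(i, 1)], Inf)
    v[age > hor] <- NA_real_
    v
  }
  vals <- lapply(stats::setNames(unname(.sofa_inputs), names(.sofa_inputs)), locf)
  doses <- lapply(stats::setNames(.vasopressors, .vasopressors), locf)
  ventilated <- !is.na(meta$vent_start) & grid >= meta$vent_start &
    (is.na(meta$vent_end) | grid < meta$vent_end)
  comp <- lapply(.sofa_components, function(cmp)
    .component_score(cmp, vals[[cmp]], ventilated, doses))
  names(comp) <- .sofa_components
  out <- data.frame(time = grid, comp)
  out$total <- rowSums(out[, .sofa_components])
  out
}

#' Per-component maximum SOFA over a time window
#'
#' The windowed aggregate used for SOFA score-maps: each organ component is
#' the maximum over the window; the aggregate total is the sum of the
#' component maxima.
#'
#' @param track output of [sofa_track()].
#' @param t_start,t_end window bounds in hours (half-open on the left).
#' @return one-row data.frame of component maxima and their sum.
#' @export
sofa_window_max <- function(track, t_start = -Inf, t_end = Inf) {
  w <- track[track$time > t_start & track$time <= t_end, , drop = FALSE]
  if (!nrow(w)) return(NULL)
  mx <- vapply(.sofa_components, function(c) max(w[[c]]), numeric(1))
  out <- as.data.frame(as.list(mx))
  out$total <- sum(mx)
  out
}

#' Estimate the infection-suspicion time
#'
#' A suspicion event exists when a blood culture follows antibiotics within
#' `abx_to_culture` hours, or antibiotics follow a culture within
#' `culture_to_abx` hours; the suspicion time is the earlier member of the
#' qualifying pair, and the earliest qualifying pair wins.
#'
#' @param abx_times,culture_times numeric vectors of event times (hours).
#' @param abx_to_culture,culture_to_abx window bounds in hours (canonical
#'   EMR operationalization: 24 and 72).
#' @return list(time, trigger) or NULL when no pair qualifies.
#' @export
find_suspicion <- function(abx_times, culture_times,
                           abx_to_culture = 24, culture_to_abx = 72) {
  if (!length(abx_times) || !length(culture_times)) return(NULL)
  best <- NULL
  for (a in abx_times) for (cc in culture_times) {
    cand <- NULL
    if (cc >= a && cc - a <= abx_to_culture) {
      cand <- list(time = a, trigger = "abx_then_culture")
    } else if (a > cc && a - cc <= culture_to_abx) {
      cand <- list(time = cc, trigger = "culture_then_abx")
    }
    if (!is.null(cand) && (is.null(best) || cand$time < best$time)) best <- cand
  }
  best
}

#' Detect sepsis-3 onset around a suspicion time
#'
#' Onset is the earliest grid time within `[suspicion - window_before,
#' suspicion + window_after]` at which total SOFA exceeds the pre-window
#' baseline by >= 2. The baseline is the minimum total over the
#' `baseline_hours` preceding the search window, or 0 when no earlier data
#' exist (no pre-existing organ dysfunction assumed).
#'
#' @param track time-ordered output of [sofa_track()].
#' @param suspicion list(time, trigger) from [find_suspicion()], or NULL.
#' @param window_before,window_after search-window bounds in hours.
#' @param baseline_hours lookback for the baseline minimum.
#' @return list(onset_time (or NA), suspicion, delta_sofa, baseline).
#' @export
detect_sepsis3 <- function(track, suspicion, window_before = 48,
                           window_after = 24, baseline_hours = 24) {
  if (nrow(track) > 1 && is.unsorted(track$time))
    stop("SOFA track must be time-ordered")
  none <- list(onset_time = NA_real_, suspicion = suspicion,
               delta_sofa = 0L, baseline = 0L)
  if (is.null(suspicion) || !nrow(track)) return(none)
  wstart <- suspicion$time - window_before
  wend <- suspicion$time + window_after
  pre <- track$total[track$time >= wstart - baseline_hours & track$time < wstart]
  baseline <- if (length(pre)) min(pre) else 0
  w <- track[track$time >= wstart & track$time <= wend, , drop = FALSE]
  if (!nrow(w)) return(none)
  delta <- max(w$total) - baseline
  hit <- which(w$total - baseline >= 2)
  onset <- if (length(hit)) w$time[hit[1]] else NA_real_
  list(onset_time = onset, suspicion = suspicion,
       delta_sofa = as.integer(delta), baseline = as.integer(baseline))
}

#' Run sepsis-3 detection over a whole cohort
#'
#' @param stream an `arf_event_stream` with antibiotic and culture times in
#'   its metadata.
#' @param resolution SOFA grid step in hours.
#' @return data.frame with one row per encounter: suspicion time/trigger,
#'   onset time, delta SOFA and the sepsis-3 flag.
#' @export
detect_sepsis_cohort <- function(stream, resolution = 1) {
  meta <- stream$meta
  vars <- c(unname(.sofa_inputs), .vasopressors)
  ev <- stream$events[stream$events$variable %in% vars, ]
  ev_split <- split(ev, ev$encounter_id)
  res <- lapply(seq_len(nrow(meta)), function(i) {
    susp <- find_suspicion(.parse_times(meta$abx_times[i]),
                           .parse_times(meta$culture_times[i]))
    ei <- ev_split[[meta$encounter_id[i]]]
    if (is.null(ei)) ei <- ev[0, ]
    trk <- .sofa_track_events(ei, meta[i, ], resolution = resolution)
    det <- detect_sepsis3(trk, susp)
    data.frame(
      encounter_id = meta$encounter_id[i],
      suspicion_time = if (is.null(susp)) NA_real_ else susp$time,
      trigger = if (is.null(susp)) NA_character_ else susp$trigger,
      onset_time = det$onset_time, delta_sofa = det$delta_sofa,
      sepsis3 = !is.na(det$onset_time), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
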