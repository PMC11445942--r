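# Cohort construction: index time of (post-surgical) invasive mechanical
# ventilation, ordered inclusion/exclusion rules, and extraction of the 24-h
# pre-intubation observation window.

.vent_param_vars <- c("peep", "tidal_volume", "plateau_pressure")

#' Find the index time of invasive mechanical ventilation
#'
#' MICU encounters: the earliest ventilator-parameter record (PEEP, tidal
#' volume or plateau pressure). SICU encounters: the earliest such record at
#' or after 48 h past the end of surgery.
#'
#' @param events event data.frame for one encounter.
#' @param icu_type "MICU" or "SICU".
#' @param surgery_end_time hours; required for SICU.
#' @return index time in hours, or NA when no qualifying record exists.
#' @export
find_index_time <- function(events, icu_type, surgery_end_time = NA) {
  vt <- events$time_hours[events$variable %in% .vent_param_vars]
  if (icu_type == "SICU") {
    if (is.na(surgery_end_time)) stop("SICU encounter without surgery end time")
    vt <- vt[vt >= surgery_end_time + 48]
  }
  if (!length(vt)) return(NA_real_)
  min(vt)
}

#' Apply the study inclusion/exclusion rules
#'
#' Tags every encounter included/excluded with the first failing rule as the
#' reason, in this fixed order: age >= 18; sepsis-3 met; admitted to a
#' medical or surgical ICU; a ventilation index time exists; >= `min_imv_hours`
#' of invasive ventilation from the index; at least one observation in the
#' 24-h pre-index window; ventilation not initiated before ICU admission
#' (field/ED intubation).
#'
#' @param stream an `arf_event_stream`.
#' @param sepsis data.frame from [detect_sepsis_cohort()].
#' @param min_imv_hours minimum IMV duration measured from the index time.
#' @return data.frame, one row per encounter: `included`,
#'   `exclusion_reason` (NA when included), `index_time`, `icu_type`.
#' @export
apply_inclusion <- function(stream, sepsis, min_imv_hours = 24) {
  meta <- stream$meta
  ev_split <- split(stream$events[stream$events$variable %in% .vent_param_vars, ],
                    stream$events$encounter_id[stream$events$variable %in% .vent_param_vars])
  obs <- stream$events[!(stream$events$variable %in% .vent_param_vars), ]
  obs_split <- split(obs$time_hours, obs$encounter_id)
  sep <- stats::setNames(sepsis$sepsis3, sepsis$encounter_id)

  out <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$encounter_id[i]
    reason <- NA_character_
    idx <- NA_real_
    repeat {
      if (meta$age[i] < 18) { reason <- "age"; break }
      if (!isTRUE(sep[[id]])) { reason <- "no sepsis-3"; break }
      if (!meta$icu_type[i] %in% c("MICU", "SICU")) { reason <- "ICU type"; break }
      ei <- ev_split[[id]]
      idx <- if (is.null(ei)) NA_real_ else
        find_index_time(ei, meta$icu_type[i], meta$surgery_end_time[i])
      if (is.na(idx)) { reason <- "no index time"; break }
      vent_end <- meta$vent_end[i]
      dur <- if (is.na(vent_end)) Inf else vent_end - idx
      if (dur < min_imv_hours) { reason <- "IMV duration"; break }
      ot <- obs_split[[id]]
      if (is.null(ot) || !any(ot > idx - 24 & ot <= idx)) {
        reason <- "no pre-index data"; break
      }
      if (!is.na(meta$vent_start[i]) &&
          meta$vent_start[i] < meta$admission_time[i]) {
        reason <- "field/ED intubation"; break
      }
      break
    }
    data.frame(encounter_id = id, included = is.na(reason),
               exclusion_reason = reason, index_time = idx,
               icu_type = meta$icu_type[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the 24-h pre-intubation observation window
#'
#' Returns all observation records with `index_time - 24 < t <= index_time`
#' (half-open on the left: the index-time record is the window's last
#' observation). Ventilator-parameter records are not observations and are
#' excluded.
#'
#' @param stream an `arf_event_stream`.
#' @param indexed one row of the [apply_inclusion()] output (or a list with
#'   `encounter_id`, `included`, `index_time`).
#' @return data.frame of in-window event records.
#' @export
extract_window <- function(stream, indexed) {
  if (!isTRUE(indexed$included))
    stop("extract_window called on an excluded encounter: ",
         indexed$encounter_id)
  ev <- stream$events
  ev[ev$encounter_id == indexed$encounter_id &
       !(ev$variable %in% .vent_param_vars) &
       ev$time_hours > indexed$index_time - 24 &
       ev$time_hours <= indexed$index_time, , drop = FALSE]
}

#' Extract windows for all included encounters
#'
#' @param stream an `arf_event_stream`.
#' @param cohort output of [apply_inclusion()].
#' @return data.frame of in-window records across included encounters.
#' @export
extract_windows <- function(stream, cohort) {
  inc <- cohort[cohort$included, ]
  ev <- stream$events[!(stream$events$variable %in% .vent_param_vars), ]
  ev <- ev[ev$encounter_id %in% inc$encounter_id, ]
  idx <- stats::setNames(inc$index_time, inc$encounter_id)
  it <- idx[ev$encounter_id]
  ev[ev$time_hours > it - 24 & ev$time_hours <= it, , drop = FALSE]
}
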