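# Shared plumbing: schema-validated readers, the treatment-exposure helper,
# end-to-end pipeline orchestration with flat CSV/JSON artifacts and a
# reproducibility manifest.

.events_schema <- c("encounter_id", "patient_id", "time_hours", "variable", "value")

#' Read a long-format clinical event table
#'
#' @param path CSV with columns encounter_id, patient_id, time_hours,
#'   variable, value. Rows with non-numeric values or times are collected
#'   into a `rejects` attribute rather than failing the read.
#' @return events data.frame (attribute `rejects` holds malformed rows).
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_c <- setdiff(.events_schema, names(raw))
  if (length(missing_c))
    stop("events file missing mandatory columns: ",
         paste(missing_c, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  tt <- suppressWarnings(as.numeric(raw$time_hours))
  bad <- is.na(val) | is.na(tt)
  ev <- data.frame(encounter_id = raw$encounter_id[!bad],
                   patient_id = raw$patient_id[!bad],
                   time_hours = tt[!bad], variable = raw$variable[!bad],
                   value = val[!bad], stringsAsFactors = FALSE)
  attr(ev, "rejects") <- raw[bad, , drop = FALSE]
  ev
}

#' Read encounter metadata
#' @param path metadata CSV written by [write_cohort()].
#' @return data.frame.
#' @export
read_encounter_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble an event stream from events and metadata tables
#' @param events,meta data.frames as produced by the readers.
#' @return an `arf_event_stream`.
#' @export
as_event_stream <- function(events, meta) {
  structure(list(events = events, meta = meta), class = "arf_event_stream")
}

#' High-PEEP exposure flags
#'
#' An encounter is treated when its median PEEP over the first
#' `window` hours of ventilation is at or above `threshold` cmH2O.
#'
#' @param stream an `arf_event_stream`.
#' @param index_times named vector encounter -> index time (hours).
#' @param threshold PEEP cut (default 10). @param window exposure window in
#'   hours (default 24).
#' @return named logical vector (NA when no PEEP was recorded).
#' @export
peep_treated <- function(stream, index_times, threshold = 10, window = 24) {
  ev <- stream$events[stream$events$variable == "peep", ]
  it <- index_times[ev$encounter_id]
  ev <- ev[!is.na(it) & ev$time_hours >= it & ev$time_hours < it + window, ]
  med <- tapply(ev$value, ev$encounter_id, stats::median)
  out <- stats::setNames(rep(NA, length(index_times)), names(index_times))
  out[names(med)] <- med >= threshold
  out
}

#' Pipeline configuration with documented defaults
#'
#' @param seed master seed for every stochastic stage.
#' @param resolution SOFA grid step (hours).
#' @param missing_threshold,r_threshold,n_iterations preprocessing settings.
#' @param methods,dimensions,ks,n_init model-selection grids.
#' @param confounders propensity-model confounder features (must survive
#'   preprocessing).
#' @param peep_threshold,exposure_window high-PEEP definition.
#' @param n_boot bootstrap replicates for the ATE CI.
#' @param min_arm minimum per-arm size to attempt matching in a phenotype.
#' @return list of class `arf_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, resolution = 1,
                            missing_threshold = 0.85, r_threshold = 0.75,
                            n_iterations = 10,
                            methods = "umap", dimensions = 2:3, ks = 2:6,
                            n_init = 10,
                            confounders = c("pf_ratio", "lactate",
                                            "creatinine", "map"),
                            peep_threshold = 10, exposure_window = 24,
                            n_boot = 2000, min_arm = 5) {
  structure(list(seed = as.integer(seed), resolution = resolution,
                 missing_threshold = missing_threshold,
                 r_threshold = r_threshold, n_iterations = n_iterations,
                 methods = methods, dimensions = dimensions, ks = ks,
                 n_init = n_init, confounders = confounders,
                 peep_threshold = peep_threshold,
                 exposure_window = exposure_window, n_boot = n_boot,
                 min_arm = min_arm),
            class = "arf_pipeline_config")
}

.write_artifact_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

.write_artifact_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in order — sepsis-3 detection, cohort construction,
#' preprocessing, embedding/cluster model selection, characterization and
#' canonical labeling, 28-day outcomes, and per-phenotype propensity-matched
#' high-PEEP effect estimation — persisting every intermediate as flat
#' CSV/JSON under `out_dir` together with a manifest of file hashes, seeds
#' and parameters.
#'
#' @param stream an `arf_event_stream` (see [generate_arf_cohort()],
#'   [read_events()] / [as_event_stream()]).
#' @param config an [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return invisible list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(stream, config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sepsis <- step("sepsis3", detect_sepsis_cohort(stream, config$resolution))
  art <- c(art, .write_artifact_csv(sepsis, file.path(out_dir, "sepsis_onsets.csv")))

  cohort <- step("cohort", apply_inclusion(stream, sepsis))
  art <- c(art, .write_artifact_csv(cohort, file.path(out_dir, "cohort.csv")))
  inc <- cohort[cohort$included, ]
  if (nrow(inc) < 8) stop("pipeline stage 'cohort' failed: fewer than 8 included encounters")

  windows <- step("windows", extract_windows(stream, cohort))
  prep <- step("preprocess",
               preprocess_fit(windows, encounter_ids = sort(inc$encounter_id),
                              missing_threshold = config$missing_threshold,
                              r_threshold = config$r_threshold,
                              n_iterations = config$n_iterations))
  art <- c(art, .write_artifact_csv(
    data.frame(encounter_id = rownames(prep$data), prep$data,
               check.names = FALSE),
    file.path(out_dir, "features_scaled.csv")))
  art <- c(art, .write_artifact_json(prep$prep$report,
                                     file.path(out_dir, "preprocess_report.json")))

  sel <- step("phenotype",
              model_select(prep$data, methods = config$methods,
                           dimensions = config$dimensions, ks = config$ks,
                           seed = config$seed, n_init = config$n_init))
  art <- c(art, .write_artifact_csv(sel$table, file.path(out_dir, "model_selection.csv")))
  art <- c(art, .write_artifact_csv(
    data.frame(encounter_id = rownames(prep$data), sel$embedding$coords,
               check.names = FALSE),
    file.path(out_dir, "embedding.csv")))

  assignments <- assign_phenotype_indices(sel$clustering, rownames(prep$data))

  summar <- step("characterize",
                 summarize_phenotypes(prep$unscaled, assignments, stream$meta))
  labeling <- canonical_label(summar$table)
  if (!is.null(labeling$mapping)) {
    assignments$phenotype <- unname(labeling$mapping[as.character(assignments$cluster)])
  } else {
    assignments$phenotype <- as.character(assignments$cluster)
  }
  art <- c(art, .write_artifact_csv(assignments, file.path(out_dir, "assignments.csv")))
  art <- c(art, .write_artifact_csv(summar$table, file.path(out_dir, "phenotype_profiles.csv")))
  if (!is.null(summar$tests))
    art <- c(art, .write_artifact_csv(summar$tests, file.path(out_dir, "phenotype_tests.csv")))
  art <- c(art, .write_artifact_json(
    list(mapping = as.list(labeling$mapping), ambiguous = labeling$ambiguous),
    file.path(out_dir, "labeling.json")))

  imp <- step("importance", feature_importance(prep$data, assignments))
  imp_tab <- do.call(rbind, lapply(names(imp), function(k) {
    r <- imp[[k]]$ranking
    r$cluster <- k
    r
  }))
  art <- c(art, .write_artifact_csv(imp_tab, file.path(out_dir, "feature_importance.csv")))

  meta_inc <- stream$meta[stream$meta$encounter_id %in% assignments$encounter_id, ]
  charl <- vapply(seq_len(nrow(meta_inc)), function(i)
    charlson_age_adjusted(.parse_codes(meta_inc$dx_codes[i]), meta_inc$age[i]),
    integer(1))
  ph <- stats::setNames(assignments$phenotype, assignments$encounter_id)
  charl_by <- do.call(rbind, lapply(sort(unique(assignments$phenotype)), function(l) {
    v <- charl[ph[meta_inc$encounter_id] == l]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(phenotype = l, mean = mean(v),
               ci_lower = mean(v) - 1.96 * se, ci_upper = mean(v) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  art <- c(art, .write_artifact_csv(charl_by, file.path(out_dir, "charlson.csv")))

  idx <- stats::setNames(inc$index_time, inc$encounter_id)
  treated <- peep_treated(stream, idx, config$peep_threshold,
                          config$exposure_window)
  records <- step("outcomes",
                  build_survival_records(meta_inc, idx, ph, treated))
  art <- c(art, .write_artifact_csv(records, file.path(out_dir, "survival_records.csv")))

  km_tabs <- do.call(rbind, lapply(sort(unique(records$phenotype)), function(l) {
    r <- records[records$phenotype == l, ]
    cv <- km_estimate(r$time, r$event)$curve
    cv$phenotype <- l
    cv
  }))
  art <- c(art, .write_artifact_csv(km_tabs, file.path(out_dir, "km_curves.csv")))
  lr <- logrank_test(records$time, records$event, records$phenotype)
  vfd <- vfd28_summary(records)
  art <- c(art, .write_artifact_csv(vfd$per_phenotype, file.path(out_dir, "vfd.csv")))
  art <- c(art, .write_artifact_json(lr, file.path(out_dir, "logrank.json")))

  ate <- list()
  for (l in sort(unique(records$phenotype))) {
    sub <- assignments$encounter_id[assignments$phenotype == l]
    tr <- treated[sub]
    sub <- sub[!is.na(tr)]
    tr <- as.logical(tr[sub])
    if (sum(tr) < config$min_arm || sum(!tr) < config$min_arm) {
      ate[[l]] <- list(phenotype = l, skipped = "insufficient arm sizes")
      next
    }
    conf_feats <- intersect(config$confounders, colnames(prep$unscaled))
    X <- prep$unscaled[sub, conf_feats, drop = FALSE]
    p <- fit_propensity(X, tr)
    mt <- match_pairs(p, tr, ids = sub)
    if (!mt$n_matched) {
      ate[[l]] <- list(phenotype = l, skipped = "no matches within caliper")
      next
    }
    y <- stats::setNames(as.numeric(records$dead28), records$encounter_id)[sub]
    ab <- ate_and_balance(mt, y, X, stats::setNames(tr, sub),
                          n_boot = config$n_boot, seed = config$seed)
    ate[[l]] <- list(phenotype = l, n_matched = mt$n_matched,
                     ate = ab$ate, ci = ab$ci, naive = ab$naive,
                     smd = ab$smd)
  }
  art <- c(art, .write_artifact_json(ate, file.path(out_dir, "ate.json")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("arfpheno")),
    seed = config$seed,
    parameters = unclass(config),
    n_encounters = nrow(stream$meta),
    n_included = nrow(inc),
    artifacts = lapply(stats::setNames(sort(art), basename(sort(art))),
                       function(p) unname(tools::md5sum(p)))
  )
  mpath <- .write_artifact_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(sepsis = sepsis, cohort = cohort, prep = prep,
                 selection = sel, assignments = assignments,
                 summary = summar, labeling = labeling,
                 importance = imp, records = records, logrank = lr,
                 vfd = vfd, ate = ate, manifest = mpath))
}

.parse_codes <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}
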