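#' @keywords internal
.res_cache <- new.env(parent = emptyenv())

.read_resource <- function(name, colClasses = NA) {
  if (!exists(name, envir = .res_cache)) {
    path <- system.file("extdata", name, package = "arfpheno")
    if (!nzchar(path)) stop("bundled resource not found: ", name)
    assign(name, utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = colClasses),
           envir = .res_cache)
  }
  get(name, envir = .res_cache)
}

#' Packaged clinical feature dictionary
#'
#' The dictionary drives both the synthetic cohort generator and the
#' preprocessing stages. Each row is one routinely collected clinical feature
#' with its sampling kind (`vital` = hourly, `lab` = 6-hourly), the marginal
#' distribution family used by the generator (`lognormal` for strictly
#' positive, skewed labs; `truncnorm` for bounded measurements), a healthy
#' reference value, physiologic plausibility bounds (used to flag implausible
#' outliers), a default per-feature missingness fraction, and the
#' organ-system block used for the within-phenotype copula correlation.
#'
#' The set of features is a configurable stand-in for a site's own chart
#' dictionary: it covers the variables reported in the phenotype summary
#' tables plus the standard SOFA inputs and routine chemistries.
#'
#' @return A data.frame, one row per feature.
#' @export
feature_dictionary <- function() .read_resource("feature_dictionary.csv")

#' Bundled SOFA scoring rubric
#'
#' The standard six-organ SOFA rubric encoded as value bands: a component's
#' score is the maximum score over all satisfied rows, where a row is
#' satisfied when `min <= value < max` and its support requirement (currently
#' only `vent` for the respiratory 3-4 bands) is met. Vasopressor doses are
#' in ug/kg/min.
#'
#' @return A data.frame with columns component, variable, min, max, support,
#'   score.
#' @export
sofa_rubric <- function() .read_resource("sofa_rubric.csv")

#' Bundled Charlson comorbidity ICD-9 mapping
#'
#' Seventeen comorbidity categories with ICD-9 code prefixes and Charlson
#' weights. `hierarchy_group` marks mutually exclusive severity pairs
#' (e.g. mild vs. moderate/severe liver disease) of which only the heavier
#' is counted.
#'
#' @return A data.frame with columns category, icd9_prefix, weight,
#'   hierarchy_group.
#' @export
charlson_map <- function()
  .read_resource("charlson_icd9.csv",
                 colClasses = c(icd9_prefix = "character"))
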