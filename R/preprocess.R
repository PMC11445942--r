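# Feature engineering from windowed event streams to the model-ready matrix.
# All stages are fit on derivation data and can be re-applied, frozen, to
# validation cohorts.

#' Median-aggregate windowed observations into a feature matrix
#'
#' Each cell is the median of that feature's in-window values for that
#' encounter; cells with no values are missing. Rows are encounters (sorted),
#' columns follow the feature dictionary order with any extra observed
#' variables appended alphabetically.
#'
#' @param windows data.frame of in-window records (see [extract_windows()]).
#' @param encounter_ids optional row universe (encounters with no records get
#'   all-missing rows).
#' @return numeric matrix with NA for missing cells.
#' @export
aggregate_median <- function(windows, encounter_ids = NULL) {
  if (!is.numeric(windows$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(windows$value))))[1]
    stop("non-numeric value in record ", bad, ": variable=",
         windows$variable[bad], " value=", windows$value[bad])
  }
  if (is.null(encounter_ids)) encounter_ids <- sort(unique(windows$encounter_id))
  dict_feats <- feature_dictionary()$feature
  feats <- unique(windows$variable)
  feats <- c(intersect(dict_feats, feats), sort(setdiff(feats, dict_feats)))
  m <- matrix(NA_real_, length(encounter_ids), length(feats),
              dimnames = list(encounter_ids, feats))
  if (nrow(windows)) {
    agg <- stats::aggregate(value ~ encounter_id + variable, windows, stats::median)
    i <- match(agg$encounter_id, encounter_ids)
    j <- match(agg$variable, feats)
    keep <- !is.na(i) & !is.na(j)
    m[cbind(i[keep], j[keep])] <- agg$value[keep]
  }
  m
}

#' Convert physiologically implausible values to missing
#'
#' Values outside the closed per-feature plausibility interval become NA.
#' Per-feature conversion counts are attached as attribute
#' `outlier_counts`.
#'
#' @param m feature matrix from [aggregate_median()].
#' @param bounds data.frame with columns feature, lower, upper; defaults to
#'   the packaged dictionary's bounds. Every matrix feature must be covered.
#' @return the matrix with outliers set to NA.
#' @export
outliers_to_missing <- function(m, bounds = NULL) {
  if (is.null(bounds)) {
    d <- feature_dictionary()
    bounds <- data.frame(feature = d$feature, lower = d$lower, upper = d$upper)
  }
  i <- match(colnames(m), bounds$feature)
  if (anyNA(i))
    stop("features absent from plausibility table: ",
         paste(colnames(m)[is.na(i)], collapse = ", "))
  lo <- matrix(bounds$lower[i], nrow(m), ncol(m), byrow = TRUE)
  hi <- matrix(bounds$upper[i], nrow(m), ncol(m), byrow = TRUE)
  out <- !is.na(m) & (m < lo | m > hi)
  counts <- colSums(out)
  m[out] <- NA_real_
  attr(m, "outlier_counts") <- counts
  m
}

#' Drop features missing in more than a threshold fraction of encounters
#'
#' @param m feature matrix.
#' @param threshold strict upper bound on the missing fraction (default
#'   0.85: a feature missing in exactly 85% of rows is retained).
#' @return the reduced matrix; attribute `dropped_missingness` lists removed
#'   features, `missing_fraction` the pre-drop per-feature fractions.
#' @export
drop_high_missingness <- function(m, threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- colMeans(is.na(m))
  drop <- frac > threshold
  out <- m[, !drop, drop = FALSE]
  attr(out, "dropped_missingness") <- colnames(m)[drop]
  attr(out, "missing_fraction") <- frac[!drop]
  out
}

.lm_beta <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

#' Chained-equation imputation
#'
#' Iterated conditional regression sweeps: missing cells are initialized at
#' the observed column median, then each incomplete feature is repeatedly
#' regressed on all other features (observed rows only) and its missing
#' cells replaced by the regression prediction. Sweeps are deterministic;
#' observed cells are never modified. The fitted imputer (initial medians
#' plus final-sweep coefficients) is attached as attribute `imputer` and can
#' be applied, frozen, to validation data with [apply_imputer()].
#'
#' @param m feature matrix with missing cells.
#' @param n_iterations number of full sweeps (default 10).
#' @param seed kept for interface stability; the sweeps draw no random
#'   numbers.
#' @return complete matrix with attribute `imputer`.
#' @export
impute_chained <- function(m, n_iterations = 10, seed = 1L) {
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop("all-missing feature reached imputation: ",
         paste(colnames(m)[nobs == 0], collapse = ", "))
  if (any(nobs < 2))
    stop("features with < 2 observed values: ",
         paste(colnames(m)[nobs < 2], collapse = ", "))
  obs <- !is.na(m)
  medians <- apply(m, 2, stats::median, na.rm = TRUE)
  filled <- m
  for (j in seq_len(ncol(m))) filled[!obs[, j], j] <- medians[j]
  rng_lo <- apply(m, 2, min, na.rm = TRUE)
  rng_hi <- apply(m, 2, max, na.rm = TRUE)
  targets <- which(colSums(!obs) > 0)
  ord <- targets[order(colSums(!obs)[targets], colnames(m)[targets])]
  if (length(ord)) {
    for (it in seq_len(n_iterations)) {
      for (j in ord) {
        b <- .lm_beta(filled[obs[, j], -j, drop = FALSE], filled[obs[, j], j])
        pred <- drop(cbind(1, filled[!obs[, j], -j, drop = FALSE]) %*% b)
        # imputations stay inside the observed range (keeps the sweep map
        # bounded and the values physiologic)
        filled[!obs[, j], j] <- pmin(pmax(pred, rng_lo[j]), rng_hi[j])
      }
    }
  }
  coefs <- lapply(seq_len(ncol(m)), function(j)
    .lm_beta(filled[obs[, j], -j, drop = FALSE], filled[obs[, j], j]))
  names(coefs) <- colnames(m)
  attr(filled, "imputer") <- list(
    features = colnames(m), medians = medians, coefs = coefs,
    order = colnames(m)[ord], n_iterations = n_iterations,
    range_low = rng_lo, range_high = rng_hi
  )
  filled
}

#' Apply a frozen imputer to new data
#'
#' @param imputer the `imputer` attribute of an [impute_chained()] result.
#' @param m feature matrix with the imputer's feature set (order enforced).
#' @return complete matrix.
#' @export
apply_imputer <- function(imputer, m) {
  missing_f <- setdiff(imputer$features, colnames(m))
  if (length(missing_f)) {
    add <- matrix(NA_real_, nrow(m), length(missing_f),
                  dimnames = list(rownames(m), missing_f))
    m <- cbind(m, add)
  }
  m <- m[, imputer$features, drop = FALSE]
  obs <- !is.na(m)
  filled <- m
  for (j in seq_len(ncol(m))) filled[!obs[, j], j] <- imputer$medians[j]
  # every incomplete feature is swept (external missingness patterns need
  # not match the derivation's); imputations are clamped to the derivation
  # observed range, which keeps the frozen linear sweeps bounded
  ord <- which(colSums(!obs) > 0)
  for (it in seq_len(imputer$n_iterations)) {
    for (j in ord) {
      miss <- !obs[, j]
      pred <- drop(cbind(1, filled[miss, -j, drop = FALSE]) %*%
                     imputer$coefs[[j]])
      filled[miss, j] <- pmin(pmax(pred, imputer$range_low[j]),
                              imputer$range_high[j])
    }
  }
  filled
}

#' Prune highly correlated features
#'
#' Greedy single pass over feature pairs ordered by (original missingness,
#' name): when a pair's absolute Pearson correlation exceeds the threshold
#' and both members are still retained, the member with the higher original
#' missingness is dropped (ties: the lexicographically later name).
#'
#' @param m complete feature matrix.
#' @param r_threshold absolute correlation above which a pair offends
#'   (default 0.75).
#' @param missingness named per-feature original missing fractions used for
#'   ordering and tie-breaking; defaults to the matrix's
#'   `missing_fraction` attribute or zero.
#' @return the pruned matrix; attribute `dropped_correlated` lists removals.
#' @export
correlation_prune <- function(m, r_threshold = 0.75, missingness = NULL) {
  if (is.null(missingness)) {
    missingness <- attr(m, "missing_fraction")
    if (is.null(missingness))
      missingness <- stats::setNames(rep(0, ncol(m)), colnames(m))
  }
  miss <- missingness[colnames(m)]
  miss[is.na(miss)] <- 0
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  ord <- order(miss, colnames(m))
  kept <- rep(TRUE, ncol(m))
  dropped <- character(0)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!kept[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!kept[j]) next
      if (abs(r[i, j]) > r_threshold) {
        pick <- if (miss[i] > miss[j]) i
        else if (miss[j] > miss[i]) j
        else if (colnames(m)[i] > colnames(m)[j]) i else j
        kept[pick] <- FALSE
        dropped <- c(dropped, colnames(m)[pick])
        if (!kept[i]) break
      }
    }
  }
  out <- m[, kept, drop = FALSE]
  attr(out, "dropped_correlated") <- dropped
  attr(out, "missing_fraction") <- miss[kept]
  out
}

#' Standardize features to zero mean, unit variance
#'
#' @param m complete feature matrix (derivation data).
#' @return list with `data` (scaled matrix) and `scaler` (center/scale per
#'   feature) for frozen reuse on validation cohorts. Zero-variance features
#'   are dropped with a warning.
#' @export
scale_features <- function(m) {
  ctr <- colMeans(m)
  sc <- apply(m, 2, stats::sd)
  zero <- sc == 0 | is.na(sc)
  if (any(zero)) {
    warning("dropping zero-variance features: ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    ctr <- ctr[!zero]; sc <- sc[!zero]
  }
  data <- sweep(sweep(m, 2, ctr), 2, sc, "/")
  list(data = data,
       scaler = list(features = colnames(m), center = ctr, scale = sc))
}

#' Apply a frozen scaler
#'
#' @param scaler from [scale_features()].
#' @param m matrix containing (at least) the scaler's features.
#' @return scaled matrix restricted to the scaler's features, in its order.
#' @export
apply_scaler <- function(scaler, m) {
  missing_f <- setdiff(scaler$features, colnames(m))
  extra_f <- setdiff(colnames(m), scaler$features)
  if (length(missing_f))
    stop("feature-set mismatch; missing: ", paste(missing_f, collapse = ", "),
         if (length(extra_f)) paste0("; extra: ", paste(extra_f, collapse = ", ")))
  m <- m[, scaler$features, drop = FALSE]
  sweep(sweep(m, 2, scaler$center), 2, scaler$scale, "/")
}

#' Fit the full preprocessing pipeline on derivation windows
#'
#' Median aggregation, outlier-to-missing, >85% missingness filter,
#' chained-equation imputation, correlation pruning at |r| > 0.75, and
#' z-score scaling. Returns both the scaled matrix (clustering input) and
#' the unscaled imputed matrix (characterization input), plus the frozen
#' transformers and a preprocessing report.
#'
#' @param windows windowed records from [extract_windows()].
#' @param encounter_ids optional row universe.
#' @param missing_threshold,r_threshold,n_iterations stage parameters.
#' @return list(data, unscaled, prep) where `prep` carries the imputer,
#'   scaler, retained features, and report.
#' @export
preprocess_fit <- function(windows, encounter_ids = NULL,
                           missing_threshold = 0.85, r_threshold = 0.75,
                           n_iterations = 10) {
  m <- aggregate_median(windows, encounter_ids)
  m <- outliers_to_missing(m)
  outlier_counts <- attr(m, "outlier_counts")
  m <- drop_high_missingness(m, missing_threshold)
  dropped_miss <- attr(m, "dropped_missingness")
  missing_fraction <- attr(m, "missing_fraction")
  imp <- impute_chained(m, n_iterations = n_iterations)
  imputer <- attr(imp, "imputer")
  pruned <- correlation_prune(imp, r_threshold, missing_fraction)
  dropped_corr <- attr(pruned, "dropped_correlated")
  sc <- scale_features(pruned)
  prep <- list(
    imputer = imputer, scaler = sc$scaler,
    features = sc$scaler$features,
    report = list(
      n_encounters = nrow(m),
      outlier_conversions = as.list(outlier_counts[outlier_counts > 0]),
      dropped_missingness = dropped_miss,
      dropped_correlated = dropped_corr,
      missing_fraction = as.list(missing_fraction)
    )
  )
  list(data = sc$data, unscaled = pruned[, prep$features, drop = FALSE],
       prep = prep)
}

#' Apply a frozen preprocessing pipeline to validation windows
#'
#' @param prep the `prep` element of [preprocess_fit()].
#' @param windows windowed records of the validation cohort.
#' @param encounter_ids optional row universe.
#' @return list(data, unscaled) on the derivation feature set.
#' @export
preprocess_apply <- function(prep, windows, encounter_ids = NULL) {
  m <- aggregate_median(windows, encounter_ids)
  keep <- intersect(colnames(m), feature_dictionary()$feature)
  m <- outliers_to_missing(m[, keep, drop = FALSE])
  imp <- apply_imputer(prep$imputer, m)
  un <- imp[, prep$features, drop = FALSE]
  list(data = apply_scaler(prep$scaler, un), unscaled = un)
}
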