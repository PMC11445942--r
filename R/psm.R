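# Exploratory high-PEEP treatment-effect analysis: propensity modeling on
# stated confounders, greedy 1:1 caliper matching on the logit scale,
# standardized-mean-difference balance diagnostics, risk-difference ATE with
# a pair-resampling bootstrap CI, and matched Kaplan-Meier curves.

#' Fit a propensity model for high-PEEP exposure
#'
#' Logistic regression of treatment on the confounders. When the fit is
#' (quasi-)separated, a warning is raised and a ridge-regularized fit
#' (glmnet, alpha = 0) replaces it.
#'
#' @param confounders numeric matrix/data.frame of confounding variables.
#' @param treated logical/0-1 treatment flags.
#' @return numeric vector of propensities strictly inside (0, 1).
#' @export
fit_propensity <- function(confounders, treated) {
  treated <- as.integer(as.logical(treated))
  if (sum(treated) == 0 || sum(treated) == length(treated))
    stop("need at least one treated and one control unit")
  X <- as.matrix(confounders)
  df <- data.frame(X)
  df$.tr <- treated
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.tr ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  p <- stats::fitted(fit)
  if (sep || any(p > 1 - 1e-10) || any(p < 1e-10)) {
    warning("propensity model separation detected; refitting with ridge penalty")
    Xr <- if (ncol(X) < 2) cbind(X, `.pad` = 0) else X  # glmnet needs >= 2 cols
    g <- glmnet::glmnet(Xr, treated, family = "binomial", alpha = 0,
                        lambda = 0.05)
    p <- drop(stats::predict(g, Xr, type = "response"))
  }
  pmin(pmax(p, 1e-8), 1 - 1e-8)
}

#' Greedy 1:1 propensity matching without replacement
#'
#' Treated units, sorted by descending propensity, each take the nearest
#' unused control on the logit-propensity scale within the caliper
#' (default 0.2 standard deviations of the logit scores).
#'
#' @param propensity propensities in (0, 1).
#' @param treated logical treatment flags.
#' @param ids unit identifiers (default integer indices).
#' @param caliper absolute caliper on the logit scale; default
#'   `caliper_sd * sd(logit(propensity))`.
#' @param caliper_sd caliper width in logit SD units.
#' @return list(pairs = data.frame(treated_id, control_id, distance),
#'   n_matched, caliper).
#' @export
match_pairs <- function(propensity, treated, ids = seq_along(propensity),
                        caliper = NULL, caliper_sd = 0.2) {
  treated <- as.logical(treated)
  lg <- stats::qlogis(propensity)
  if (is.null(caliper)) caliper <- caliper_sd * stats::sd(lg)
  t_idx <- which(treated)
  c_idx <- which(!treated)
  t_idx <- t_idx[order(-propensity[t_idx])]
  used <- rep(FALSE, length(c_idx))
  pairs <- list()
  for (ti in t_idx) {
    d <- abs(lg[c_idx] - lg[ti])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= caliper) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        treated_id = ids[ti], control_id = ids[c_idx[j]],
        distance = d[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) {
    warning("no matches within caliper")
    pairs_df <- data.frame(treated_id = character(0), control_id = character(0),
                           distance = numeric(0))
  } else pairs_df <- do.call(rbind, pairs)
  list(pairs = pairs_df, n_matched = nrow(pairs_df), caliper = caliper)
}

#' Standardized mean difference
#'
#' `(mean_t - mean_c) / sqrt((var_t + var_c) / 2)` per covariate.
#'
#' @param X covariate matrix. @param treated logical flags.
#' @return named numeric vector of SMDs.
#' @export
standardized_mean_diff <- function(X, treated) {
  X <- as.matrix(X)
  treated <- as.logical(treated)
  mt <- colMeans(X[treated, , drop = FALSE])
  mc <- colMeans(X[!treated, , drop = FALSE])
  vt <- apply(X[treated, , drop = FALSE], 2, stats::var)
  vc <- apply(X[!treated, , drop = FALSE], 2, stats::var)
  (mt - mc) / sqrt(pmax((vt + vc) / 2, 1e-12))
}

#' ATE (risk difference) with bootstrap CI and balance diagnostics
#'
#' Within the matched sample: ATE = mean(treated outcome) - mean(control
#' outcome); negative values indicate reduced mortality under treatment.
#' The CI is a seeded pair-resampling percentile bootstrap. SMDs per
#' confounder are reported before (full sample) and after matching.
#'
#' @param match a [match_pairs()] result.
#' @param outcome named 0/1 outcome vector (28-day mortality) by unit id.
#' @param confounders matrix with rownames = unit ids.
#' @param treated named logical treatment flags by unit id.
#' @param n_boot bootstrap replicates (default 2000). @param seed RNG seed.
#' @param conf_level CI level.
#' @return list(ate, ci, n_pairs, smd = data.frame(feature, before, after),
#'   naive = unmatched risk difference).
#' @export
ate_and_balance <- function(match, outcome, confounders, treated,
                            n_boot = 2000, seed = 1L, conf_level = 0.95) {
  pairs <- match$pairs
  if (!nrow(pairs)) stop("no matched pairs")
  yt <- outcome[as.character(pairs$treated_id)]
  yc <- outcome[as.character(pairs$control_id)]
  diffs <- as.numeric(yt) - as.numeric(yc)
  ate <- mean(diffs)
  set.seed(seed)
  n <- length(diffs)
  boots <- vapply(seq_len(n_boot), function(b)
    mean(diffs[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))

  ids <- rownames(confounders)
  tr <- as.logical(treated[ids])
  smd_before <- standardized_mean_diff(confounders, tr)
  m_ids <- c(as.character(pairs$treated_id), as.character(pairs$control_id))
  m_tr <- c(rep(TRUE, nrow(pairs)), rep(FALSE, nrow(pairs)))
  smd_after <- standardized_mean_diff(confounders[m_ids, , drop = FALSE], m_tr)
  naive <- mean(as.numeric(outcome[ids][tr])) - mean(as.numeric(outcome[ids][!tr]))
  list(ate = ate, ci = ci, n_pairs = n,
       smd = data.frame(feature = colnames(confounders),
                        before = unname(smd_before),
                        after = unname(smd_after), stringsAsFactors = FALSE),
       naive = naive)
}

#' Matched Kaplan-Meier curves by treatment arm
#'
#' @param match a [match_pairs()] result.
#' @param records survival records with rownames or `encounter_id` matching
#'   the matched ids.
#' @return list(treated, control) of [km_estimate()] results.
#' @export
km_by_treatment <- function(match, records) {
  pairs <- match$pairs
  if (!nrow(pairs)) stop("no matched pairs")
  rec <- records
  rownames(rec) <- rec$encounter_id
  t_rec <- rec[as.character(pairs$treated_id), ]
  c_rec <- rec[as.character(pairs$control_id), ]
  if (!nrow(t_rec) || !nrow(c_rec)) stop("empty treatment arm")
  list(treated = km_estimate(t_rec$time, t_rec$event),
       control = km_estimate(c_rec$time, c_rec$event))
}
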