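# Marginal distributions calibrated from a median and IQR, plus the Gaussian
# copula used to induce within-phenotype correlation. Only medians and IQRs
# are published per phenotype, so moment matching from (median, Q1, Q3) is
# the calibration rule throughout.

.Z75 <- stats::qnorm(0.75)

# Quantile function of a normal truncated to [a, b].
.qtruncnorm <- function(p, mean, sd, a, b) {
  if (sd <= 0) return(rep(mean, length(p)))
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(pa + p * (pb - pa), mean, sd)
}

# Calibrate a marginal so that its median and IQR approximate the target.
# For the log-normal the match is exact; for the truncated normal the
# location is solved numerically so the truncated median equals the target.
.calibrate_marginal <- function(family, m, q1, q3, lower, upper) {
  stopifnot(q3 >= q1)
  if (family == "lognormal") {
    if (m <= 0 || q1 <= 0) stop("lognormal marginal requires positive median/quantiles")
    if (q3 <= q1)
      return(list(family = "lognormal", p1 = log(m), p2 = 1e-8, shift = 0,
                  lower = lower, upper = upper))
    # three-quantile fit: a location shift makes the configured quartiles
    # exactly log-symmetric around the median, so median, Q1 and Q3 are all
    # reproduced. delta = 0 recovers the plain log-normal; only upward-skew
    # shifts (0 <= delta < Q1) are applied.
    den <- 2 * m - q1 - q3
    delta <- if (abs(den) < 1e-12) 0 else (m^2 - q1 * q3) / den
    if (!is.finite(delta) || delta < 0 || delta > 0.95 * q1) delta <- 0
    sdlog <- log((q3 - delta) / (q1 - delta)) / (2 * .Z75)
    list(family = "lognormal", p1 = log(m - delta), p2 = sdlog,
         shift = delta, lower = lower, upper = upper)
  } else if (family == "truncnorm") {
    sd <- (q3 - q1) / (2 * .Z75)
    if (sd <= 0) {
      return(list(family = "truncnorm", p1 = m, p2 = 0, lower = lower, upper = upper))
    }
    f <- function(mu) .qtruncnorm(0.5, mu, sd, lower, upper) - m
    mu <- tryCatch(
      stats::uniroot(f, lower = m - 8 * sd, upper = m + 8 * sd, tol = 1e-9)$root,
      error = function(e) m
    )
    list(family = "truncnorm", p1 = mu, p2 = sd, lower = lower, upper = upper)
  } else stop("unknown distribution family: ", family)
}

# Quantile transform for a calibrated marginal (copula inverse step).
.q_marginal <- function(p, marg) {
  if (marg$family == "lognormal") {
    marg$shift + stats::qlnorm(p, marg$p1, marg$p2)
  } else {
    .qtruncnorm(p, marg$p1, marg$p2, marg$lower, marg$upper)
  }
}

# Robust scale (IQR-derived SD) implied by a (q1, q3) pair.
.iqr_sd <- function(q1, q3) pmax((q3 - q1) / (2 * .Z75), 1e-8)

#' Build the within-phenotype copula correlation matrix
#'
#' Features in the same organ-system block of the feature dictionary share a
#' modest correlation (default 0.15); a small set of strong physiologic pairs
#' (hemoglobin-hematocrit, PT-INR, blood pressures, oxygenation indices) is
#' set explicitly so the downstream correlation-pruning stage has realistic
#' work to do. The matrix is projected to the nearest positive-definite
#' correlation matrix by eigenvalue clipping.
#'
#' @param features character vector of feature names (dictionary subset).
#' @param block_r within-block correlation, default 0.4.
#' @return correlation matrix with dimnames = features.
#' @export
copula_correlation <- function(features = feature_dictionary()$feature, block_r = 0.15) {
  dict <- feature_dictionary()
  dict <- dict[match(features, dict$feature), ]
  p <- length(features)
  R <- diag(p)
  dimnames(R) <- list(features, features)
  blk <- dict$block
  for (b in setdiff(unique(blk), "none")) {
    idx <- which(blk == b)
    R[idx, idx] <- block_r
  }
  overrides <- list(
    c("hemoglobin", "hematocrit", 0.95), c("pt", "inr", 0.97),
    c("sbp", "map", 0.80), c("dbp", "map", 0.75), c("sbp", "dbp", 0.60),
    c("pao2", "pf_ratio", 0.65), c("spo2", "sf_ratio", 0.60),
    c("pf_ratio", "sf_ratio", 0.85), c("fio2", "pf_ratio", -0.55),
    c("fio2", "sf_ratio", -0.55), c("bun", "creatinine", 0.65),
    c("ast", "alt", 0.70)
  )
  for (o in overrides) {
    i <- match(o[1], features); j <- match(o[2], features)
    if (!is.na(i) && !is.na(j)) R[i, j] <- R[j, i] <- as.numeric(o[3])
  }
  diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    R <- e$vectors %*% (v * t(e$vectors))
    R <- stats::cov2cor(R)
    dimnames(R) <- list(features, features)
  }
  R
}
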