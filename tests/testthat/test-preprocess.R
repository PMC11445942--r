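mk_windows <- function(df) {
  df$patient_id <- df$encounter_id
  df
}

test_that("median aggregation matches per-cell brute force", {
  w <- mk_windows(data.frame(
    encounter_id = c("E1", "E1", "E1", "E2", "E2", "E3"),
    time_hours = c(1, 2, 3, 1, 2, 1),
    variable = c("map", "map", "map", "map", "map", "creatinine"),
    value = c(1, 3, 5, 2, 4, 1.1), stringsAsFactors = FALSE
  ))
  m <- aggregate_median(w)
  expect_equal(m["E1", "map"], 3)      # odd count
  expect_equal(m["E2", "map"], 3)      # even count: mean of middle pair
  expect_true(is.na(m["E3", "map"]))   # no values -> missing
  expect_equal(m["E3", "creatinine"], 1.1)

  set.seed(7)
  w2 <- mk_windows(data.frame(
    encounter_id = sample(paste0("E", 1:6), 200, TRUE),
    time_hours = runif(200, 0, 24),
    variable = sample(c("map", "creatinine", "lactate"), 200, TRUE),
    value = rnorm(200), stringsAsFactors = FALSE
  ))
  m2 <- aggregate_median(w2)
  for (e in rownames(m2)) for (f in colnames(m2)) {
    v <- w2$value[w2$encounter_id == e & w2$variable == f]
    expect_equal(m2[e, f], if (length(v)) median(v) else NA_real_)
  }
})

test_that("implausible values become missing; bound values survive", {
  m <- matrix(c(140, 0.1, 40, 1.5), 2, 2,
              dimnames = list(c("E1", "E2"), c("creatinine", "creatinine2")))
  colnames(m) <- c("creatinine", "lactate")
  out <- outliers_to_missing(m)
  expect_true(is.na(out["E1", "creatinine"]))  # 140 outside [0.1, 40]
  expect_equal(out["E2", "creatinine"], 0.1)   # exactly at bound retained
  expect_equal(attr(out, "outlier_counts")[["creatinine"]], 1)
  expect_true(is.na(out["E1", "lactate"]))     # 40 above lactate bound 30
  m2 <- m; m2[] <- c(1.0, 1.2, 2, 3)
  expect_equal(unname(outliers_to_missing(m2)[, ]), unname(m2[, ]))
  m3 <- m; colnames(m3) <- c("creatinine", "unknown_thing")
  expect_error(outliers_to_missing(m3), "plausibility")
})

test_that("missingness filter is strict at the threshold", {
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("E", 1:20), paste0("f", 1:10)))
  m[1:18, 1] <- NA  # 90% missing -> dropped
  m[1:17, 2] <- NA  # exactly 85% -> retained
  out <- drop_high_missingness(m, 0.85)
  expect_false("f1" %in% colnames(out))
  expect_true("f2" %in% colnames(out))
  expect_equal(attr(out, "dropped_missingness"), "f1")
  full <- m[, 3:10]
  expect_equal(colnames(drop_high_missingness(full)), colnames(full))
})

test_that("chained imputation is deterministic, exact for collinear features", {
  set.seed(3)
  m <- matrix(rnorm(300), 100, 3,
              dimnames = list(paste0("E", 1:100), c("a", "b", "c")))
  m <- cbind(m, d = 2 * m[, "a"] + 1)
  m_miss <- m
  m_miss[5, "d"] <- NA
  out <- impute_chained(m_miss)
  expect_lt(abs(out[5, "d"] - (2 * m[5, "a"] + 1)), 1e-6)
  expect_equal(out[-5, ], m[-5, ])               # observed cells untouched
  expect_identical(impute_chained(m_miss), out)  # rerun identical
  expect_identical(impute_chained(m), m, ignore_attr = TRUE)  # complete input
  m_bad <- m_miss; m_bad[, "b"] <- NA
  expect_error(impute_chained(m_bad), "all-missing")
})

test_that("frozen imputer applies to validation data", {
  set.seed(4)
  m <- matrix(rnorm(400), 100, 4,
              dimnames = list(paste0("E", 1:100), c("a", "b", "c", "d")))
  m[sample(400, 40)] <- NA
  fit <- impute_chained(m)
  imputer <- attr(fit, "imputer")
  m_new <- matrix(rnorm(40), 10, 4,
                  dimnames = list(paste0("V", 1:10), c("a", "b", "c", "d")))
  m_new[2, "a"] <- NA
  out <- apply_imputer(imputer, m_new)
  expect_false(anyNA(out))
  expect_equal(out[-2, ], m_new[-2, ])
})

test_that("correlation pruning follows the documented greedy order", {
  set.seed(5)
  a <- rnorm(200)
  m <- cbind(f1 = a, f2 = a + rnorm(200, 0, 0.01), f3 = rnorm(200))
  rownames(m) <- paste0("E", 1:200)
  out <- correlation_prune(m, 0.75,
                           missingness = c(f1 = 0, f2 = 0, f3 = 0))
  expect_equal(attr(out, "dropped_correlated"), "f2")  # tie -> later name
  expect_true(all(c("f1", "f3") %in% colnames(out)))
  # higher-missingness member of the pair is dropped
  out2 <- correlation_prune(m, 0.75,
                            missingness = c(f1 = 0.5, f2 = 0.1, f3 = 0))
  expect_equal(attr(out2, "dropped_correlated"), "f1")
  # three mutually correlated features: the two later-ranked members go
  z <- rnorm(500)
  m3 <- sapply(1:3, function(i) z + rnorm(500, 0, 0.22))
  colnames(m3) <- c("g1", "g2", "g3"); rownames(m3) <- paste0("E", 1:500)
  stopifnot(all(abs(cor(m3)[upper.tri(diag(3))]) > 0.9))
  out3 <- correlation_prune(m3, 0.75,
                            missingness = c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(colnames(out3), "g1")
  expect_equal(sort(attr(out3, "dropped_correlated")), c("g2", "g3"))
  # independent features both retained
  m4 <- cbind(h1 = rnorm(300), h2 = rnorm(300))
  rownames(m4) <- paste0("E", 1:300)
  expect_equal(ncol(correlation_prune(m4, 0.75,
                                      missingness = c(h1 = 0, h2 = 0))), 2)
})

test_that("scaling standardizes and freezes", {
  set.seed(6)
  m <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(paste0("E", 1:50), paste0("f", 1:4)))
  sc <- scale_features(m)
  expect_true(all(abs(colMeans(sc$data)) < 1e-9))
  expect_true(all(abs(apply(sc$data, 2, var) - 1) < 1e-9))
  # location invariance: a constant-shifted copy scales identically
  m2 <- m; m2[, 1] <- m[, 1] + 100
  expect_equal(scale_features(m2)$data[, 1], sc$data[, 1])
  # validation row equal to the derivation mean vector -> all zeros
  row0 <- matrix(colMeans(m), 1, dimnames = list("V1", colnames(m)))
  expect_true(all(abs(apply_scaler(sc$scaler, row0)) < 1e-12))
  # zero-variance feature dropped with warning
  m3 <- cbind(m, cst = 1)
  expect_warning(scale_features(m3), "zero-variance")
  # schema error lists the missing feature
  expect_error(apply_scaler(sc$scaler, m[, 1:3]), "f4")
})

test_that("the full preprocess is row-exchangeable and complete", {
  g <- generate_arf_cohort(default_phenotype_specs(), cohort_config(80, seed = 14))
  coh <- data.frame(encounter_id = g$stream$meta$encounter_id,
                    included = TRUE, index_time = g$stream$meta$vent_start)
  w <- extract_windows(g$stream, coh)
  ids <- sort(coh$encounter_id)
  p1 <- preprocess_fit(w, ids)
  w_shuf <- w[sample(nrow(w)), ]
  p2 <- preprocess_fit(w_shuf, ids)
  expect_equal(p1$data, p2$data)
  expect_false(anyNA(p1$data))
  expect_lte(ncol(p1$data), 50)
})
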