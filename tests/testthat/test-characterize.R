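mk_assign <- function(ids, cl) data.frame(encounter_id = ids, cluster = cl,
                                          stringsAsFactors = FALSE)

test_that("group summaries match brute-force medians and quartiles", {
  set.seed(1)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("E%02d", 1:50), paste0("f", 1:4)))
  cl <- sample(1:3, 50, TRUE)
  s <- summarize_phenotypes(m, mk_assign(rownames(m), cl))
  for (g in 1:3) for (f in colnames(m)) {
    row <- s$table[s$table$cluster == g & s$table$feature == f, ]
    v <- m[cl == g, f]
    expect_equal(row$median, median(v))
    expect_equal(row$q1, unname(quantile(v, 0.25)))
    expect_equal(row$q3, unname(quantile(v, 0.75)))
  }
})

test_that("identical groups give a null Kruskal-Wallis statistic", {
  m <- matrix(rep(rep(1:10, 4), 2), 40, 2,
              dimnames = list(sprintf("E%02d", 1:40), c("f1", "f2")))
  cl <- rep(1:4, each = 10)
  s <- summarize_phenotypes(m, mk_assign(rownames(m), cl))
  expect_true(all(s$tests$statistic < 1e-9))
  expect_true(all(s$tests$p > 0.999))
})

test_that("a fully separated 2x2 contingency is significant", {
  # closed form: chi-squared statistic 20 before correction on (10,0; 0,10)
  tb <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(unname(suppressWarnings(
    chisq.test(tb, correct = FALSE))$statistic), 20)
  m <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("E%02d", 1:20), c("f1", "f2")))
  meta <- data.frame(encounter_id = rownames(m),
                     patient_id = rownames(m),
                     sex = rep(c("M", "F"), each = 10),
                     death_time = NA_real_, vent_start = 0,
                     stringsAsFactors = FALSE)
  s <- summarize_phenotypes(m, mk_assign(rownames(m), rep(1:2, each = 10)), meta)
  expect_lt(s$tests$p[s$tests$feature == "sex"], 0.01)
})

test_that("mortality is counted at the patient level", {
  m <- matrix(rnorm(8), 4, 2,
              dimnames = list(c("E1", "E2", "E3", "E4"), c("f1", "f2")))
  meta <- data.frame(
    encounter_id = c("E1", "E2", "E3", "E4"),
    patient_id = c("P1", "P1", "P2", "P3"),   # P1 has two encounters
    vent_start = 0,
    death_time = c(NA, 24 * 10, NA, NA),      # P1 dies on the second one
    stringsAsFactors = FALSE
  )
  s <- summarize_phenotypes(m, mk_assign(rownames(m), rep(1, 4)), meta)
  expect_equal(s$mortality$n_encounters, 4)
  expect_equal(s$mortality$n_patients, 3)
  expect_equal(s$mortality$deaths, 1)
  expect_equal(s$mortality$mortality, 1 / 3)
})

test_that("single-feature separation puts that feature first for every phenotype", {
  set.seed(2)
  n <- 240
  cl <- rep(1:3, each = n / 3)
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("E%03d", 1:n), paste0("f", 1:6)))
  x[, "f1"] <- cl * 4 + rnorm(n, 0, 0.3)
  x <- scale(x)
  imp <- feature_importance(x, mk_assign(rownames(x), cl), nrounds = 30)
  for (k in names(imp)) {
    expect_equal(imp[[k]]$ranking$feature[1], "f1")
    expect_lt(imp[[k]]$additivity_residual, 1e-4)
  }
  expect_error(feature_importance(x, mk_assign(rownames(x), rep(1, n))),
               ">= 2")
})

test_that("permuting feature columns permutes the attribution ranking", {
  set.seed(3)
  n <- 150
  cl <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("E%03d", 1:n), c("a", "b", "c", "d")))
  x[, "b"] <- cl * 3 + rnorm(n, 0, 0.3)
  imp1 <- feature_importance(x, mk_assign(rownames(x), cl), nrounds = 20)
  perm <- c("d", "b", "a", "c")
  imp2 <- feature_importance(x[, perm], mk_assign(rownames(x), cl), nrounds = 20)
  r1 <- imp1[["1"]]$ranking
  r2 <- imp2[["1"]]$ranking
  expect_equal(r2$mean_abs_attribution[match(r1$feature, r2$feature)],
               r1$mean_abs_attribution, tolerance = 1e-6)
})

test_that("age-adjusted Charlson follows the category and age rubric", {
  expect_equal(charlson_age_adjusted(character(0), 45), 0L)
  expect_equal(charlson_age_adjusted(character(0), 65), 2L)
  # diabetes listed twice counts once: weight 1 + age 2
  expect_equal(charlson_age_adjusted(c("250.0", "250.02"), 65), 3L)
  # hierarchy: mild + severe liver disease -> only the heavier (3)
  expect_equal(charlson_age_adjusted(c("571.2", "572.2"), 40), 3L)
  # metastatic (6) supersedes localized malignancy (2)
  expect_equal(charlson_age_adjusted(c("153", "197.0"), 40), 6L)
  expect_equal(charlson_age_adjusted(c("428.0", "585"), 85), 1L + 2L + 4L)
  expect_warning(z <- charlson_age_adjusted(c("x99", "428.0"), 40), "malformed")
  expect_equal(z, 1L)
})

.profiles <- function(pf, cr, bil, plt) {
  do.call(rbind, lapply(1:4, function(i)
    data.frame(cluster = as.character(i),
               feature = c("pf_ratio", "creatinine", "bilirubin_total", "platelets"),
               median = c(pf[i], cr[i], bil[i], plt[i]),
               stringsAsFactors = FALSE)))
}

test_that("canonical labeling recovers A-D from the published medians", {
  # derivation-cohort anchors
  lab1 <- canonical_label(.profiles(
    pf = c(302.3, 123.3, 240.0, 266.5), cr = c(3.5, 1.3, 1.1, 1.4),
    bil = c(0.8, 0.6, 0.6, 1.2), plt = c(175, 209, 213, 118)))
  expect_equal(unname(lab1$mapping), c("A", "B", "C", "D"))
  # validation-cohort anchors
  lab2 <- canonical_label(.profiles(
    pf = c(300.6, 104.0, 256.7, 272.0), cr = c(4.1, 1.6, 1.1, 1.4),
    bil = c(0.6, 0.9, 0.7, 1.2), plt = c(178.5, 147, 213.5, 154)))
  expect_equal(unname(lab2$mapping), c("A", "B", "C", "D"))
  # invariant to cluster-index permutation
  p <- .profiles(pf = c(123.3, 302.3, 266.5, 240.0), cr = c(1.3, 3.5, 1.4, 1.1),
                 bil = c(0.6, 0.8, 1.2, 0.6), plt = c(209, 175, 118, 213))
  lab3 <- canonical_label(p)
  expect_equal(unname(lab3$mapping), c("B", "A", "D", "C"))
  expect_equal(sort(unname(lab3$mapping)), c("A", "B", "C", "D"))
})

test_that("degenerate or incomplete profiles refuse to label", {
  same <- .profiles(pf = rep(240, 4), cr = rep(1, 4), bil = rep(1, 4),
                    plt = rep(200, 4))
  lab <- canonical_label(same)
  expect_true(lab$ambiguous)
  expect_null(lab$mapping)
  p3 <- .profiles(pf = c(300, 120, 240, 260), cr = c(3, 1, 1, 1.4),
                  bil = c(1, 1, 1, 2), plt = c(150, 200, 210, 100))
  p3 <- p3[p3$cluster != "4", ]
  expect_message(lab3 <- canonical_label(p3), "4 clusters")
  expect_true(lab3$ambiguous)
  noanchor <- data.frame(cluster = rep(as.character(1:4), 2),
                         feature = "map", median = 80)
  expect_message(lab4 <- canonical_label(noanchor), "anchors")
  expect_true(lab4$ambiguous)
})
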