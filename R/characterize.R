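# Turning clusters into named phenotypes: per-cluster summaries with
# significance tests, attribution-based feature importance via a
# gradient-boosted cluster-vs-rest surrogate, the age-adjusted Charlson
# comorbidity index, and the canonical A-D labeling rubric.

#' Per-phenotype summary table with significance tests
#'
#' Medians and IQRs per feature and cluster, Kruskal-Wallis p-values across
#' clusters for continuous features, Chi-squared tests for categorical
#' metadata (sex, race, ethnicity), and patient-level 28-day mortality (a
#' patient counts as dead when any of their encounters ends in death within
#' 28 days of the ventilation index).
#'
#' @param m unscaled feature matrix (rows = encounters).
#' @param assignments data.frame(encounter_id, cluster) covering all rows.
#' @param meta optional encounter metadata (for mortality and categorical
#'   tests).
#' @return list(table, tests, mortality).
#' @export
summarize_phenotypes <- function(m, assignments, meta = NULL) {
  cl <- stats::setNames(assignments$cluster, assignments$encounter_id)
  if (anyNA(cl[rownames(m)])) stop("assignments do not cover all encounters")
  g <- factor(cl[rownames(m)])
  sizes <- table(g)
  small <- any(sizes < 2) || nlevels(g) < 2
  if (small) warning("fewer than 2 groups of >= 2 members: significance tests skipped")

  rows <- list(); tests <- list()
  for (f in colnames(m)) {
    v <- m[, f]
    q <- tapply(v, g, function(z)
      stats::quantile(z, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE))
    rows[[f]] <- data.frame(
      feature = f, cluster = names(q),
      median = vapply(q, `[`, numeric(1), 1),
      q1 = vapply(q, `[`, numeric(1), 2),
      q3 = vapply(q, `[`, numeric(1), 3),
      stringsAsFactors = FALSE
    )
    if (!small) {
      kw <- stats::kruskal.test(v, g)
      tests[[f]] <- data.frame(feature = f, test = "kruskal-wallis",
                               statistic = unname(kw$statistic),
                               p = kw$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(meta) && !small) {
    md <- meta[match(rownames(m), meta$encounter_id), ]
    for (f in intersect(c("sex", "race", "ethnicity"), names(md))) {
      tb <- table(md[[f]], g)
      if (all(dim(tb) >= 2)) {
        cs <- suppressWarnings(stats::chisq.test(tb))
        tests[[f]] <- data.frame(feature = f, test = "chi-squared",
                                 statistic = unname(cs$statistic),
                                 p = cs$p.value, stringsAsFactors = FALSE)
      }
    }
  }

  mortality <- NULL
  if (!is.null(meta)) {
    md <- meta[match(rownames(m), meta$encounter_id), ]
    dead28 <- !is.na(md$death_time) &
      (md$death_time - md$vent_start) / 24 <= 28
    mortality <- do.call(rbind, lapply(levels(g), function(lev) {
      sel <- g == lev
      pats <- split(dead28[sel], md$patient_id[sel])
      pdead <- vapply(pats, any, logical(1))
      data.frame(cluster = lev, n_encounters = sum(sel),
                 n_patients = length(pats), deaths = sum(pdead),
                 mortality = mean(pdead), stringsAsFactors = FALSE)
    }))
  }
  list(table = do.call(rbind, rows),
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       mortality = mortality)
}

#' Attribution-based feature importance per phenotype
#'
#' Fits a gradient-boosted cluster-vs-rest surrogate classifier on the
#' scaled features for each cluster and computes exact additive (TreeSHAP)
#' attributions; a cluster's feature ranking is the mean absolute
#' attribution among its own members. The additivity residual (max deviation
#' of attributions + base value from the model margin) is reported.
#'
#' @param x scaled feature matrix.
#' @param assignments data.frame(encounter_id, cluster).
#' @param nrounds,max_depth,eta surrogate booster settings.
#' @return list per cluster: `ranking` (data.frame feature,
#'   mean_abs_attribution, sorted), `additivity_residual`.
#' @export
feature_importance <- function(x, assignments, nrounds = 50, max_depth = 4,
                               eta = 0.3) {
  cl <- stats::setNames(assignments$cluster, assignments$encounter_id)
  g <- cl[rownames(x)]
  ks <- sort(unique(g))
  if (length(ks) < 2) stop("feature importance requires >= 2 phenotypes")
  out <- lapply(ks, function(k) {
    y <- as.numeric(g == k)
    dtr <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0)
    contrib <- stats::predict(bst, dtr, predcontrib = TRUE)
    margin <- stats::predict(bst, dtr, outputmargin = TRUE)
    resid <- max(abs(rowSums(contrib) - margin))
    mem <- g == k
    imp <- colMeans(abs(contrib[mem, seq_len(ncol(x)), drop = FALSE]))
    ranking <- data.frame(feature = colnames(x),
                          mean_abs_attribution = unname(imp),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$mean_abs_attribution), ]
    rownames(ranking) <- NULL
    list(ranking = ranking, additivity_residual = resid)
  })
  names(out) <- as.character(ks)
  out
}

#' Age-adjusted Charlson comorbidity index from ICD-9 codes
#'
#' Sum of comorbidity-category weights (each category counted once; within a
#' severity hierarchy such as mild vs. moderate/severe liver disease only
#' the heavier member counts) plus age points: one per decade from 50-59,
#' capped at 4.
#'
#' @param codes character vector of ICD-9 codes (prefix-matched against the
#'   bundled 17-category mapping). Malformed codes are skipped with a
#'   warning.
#' @param age years.
#' @return integer score.
#' @export
charlson_age_adjusted <- function(codes, age) {
  cm <- charlson_map()
  codes <- codes[!is.na(codes) & nzchar(codes)]
  bad <- !grepl("^[0-9EV]", codes)
  if (any(bad)) {
    warning("skipping malformed ICD-9 codes: ", paste(codes[bad], collapse = ", "))
    codes <- codes[!bad]
  }
  hit <- unique(unlist(lapply(codes, function(cd) {
    sel <- startsWith(cd, cm$icd9_prefix)
    cm$category[sel]
  })))
  if (length(hit)) {
    rows <- unique(cm[cm$category %in% hit, c("category", "weight", "hierarchy_group")])
    for (grp in setdiff(unique(rows$hierarchy_group), "none")) {
      sub <- rows[rows$hierarchy_group == grp, ]
      if (nrow(sub) > 1) {
        keep <- sub$category[which.max(sub$weight)]
        rows <- rows[rows$hierarchy_group != grp | rows$category == keep, ]
      }
    }
    w <- sum(rows$weight)
  } else w <- 0
  age_pts <- min(4, max(0, floor(age / 10) - 4))
  as.integer(w + age_pts)
}

#' Canonical A-D phenotype labeling rubric
#'
#' Formalizes the expert naming of the four phenotypes from their anchor
#' features: B is the cluster with the lowest median P/F ratio (severe
#' hypoxemic respiratory failure); among the rest, A has the highest median
#' creatinine (renal/cardiac multi-organ dysfunction); of the remaining two,
#' D has the higher median total bilirubin (hepatic/coagulopathic
#' dysfunction; ties checked against the lower platelet count) and C is the
#' residual mild-hypoxia cluster.
#'
#' @param profiles data.frame with columns cluster, feature, median (e.g.
#'   the `table` element of [summarize_phenotypes()]).
#' @return list(mapping = named character cluster -> label (or NULL when
#'   ambiguous), anchors = the anchor medians used, ambiguous flag).
#' @export
canonical_label <- function(profiles) {
  need <- c("pf_ratio", "creatinine", "bilirubin_total", "platelets")
  have <- unique(profiles$feature)
  if (!all(need %in% have)) {
    message("labeling skipped: anchors missing (",
            paste(setdiff(need, have), collapse = ", "), ")")
    return(list(mapping = NULL, anchors = NULL, ambiguous = TRUE))
  }
  clusters <- unique(profiles$cluster)
  if (length(clusters) != 4) {
    message("labeling skipped: rubric requires exactly 4 clusters")
    return(list(mapping = NULL, anchors = NULL, ambiguous = TRUE))
  }
  med <- function(f) {
    v <- profiles$median[profiles$feature == f][match(clusters,
      profiles$cluster[profiles$feature == f])]
    stats::setNames(v, clusters)
  }
  pf <- med("pf_ratio"); cr <- med("creatinine")
  bil <- med("bilirubin_total"); plt <- med("platelets")
  anchors <- data.frame(cluster = clusters, pf_ratio = pf[clusters],
                        creatinine = cr[clusters],
                        bilirubin_total = bil[clusters],
                        platelets = plt[clusters], row.names = NULL)
  uniq_min <- function(v) sum(v == min(v)) == 1
  uniq_max <- function(v) sum(v == max(v)) == 1
  if (!uniq_min(pf)) return(list(mapping = NULL, anchors = anchors, ambiguous = TRUE))
  b <- names(which.min(pf))
  rest <- setdiff(clusters, b)
  if (!uniq_max(cr[rest])) return(list(mapping = NULL, anchors = anchors, ambiguous = TRUE))
  a <- rest[which.max(cr[rest])]
  rest2 <- setdiff(rest, a)
  d <- if (bil[rest2[1]] != bil[rest2[2]]) {
    rest2[which.max(bil[rest2])]
  } else if (plt[rest2[1]] != plt[rest2[2]]) {
    rest2[which.min(plt[rest2])]
  } else {
    return(list(mapping = NULL, anchors = anchors, ambiguous = TRUE))
  }
  cc <- setdiff(rest2, d)
  mapping <- stats::setNames(c("A", "B", "C", "D"), c(a, b, cc, d))
  mapping <- mapping[as.character(clusters)]
  names(mapping) <- as.character(clusters)
  list(mapping = mapping, anchors = anchors, ambiguous = FALSE)
}
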