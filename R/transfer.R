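# Frozen-transfer phenotype classifier: multinomial logistic regression
# trained on the scaled derivation features, benchmarked against random
# forest, SVM and Gaussian naive Bayes, then applied unchanged to external
# cohorts scaled with the derivation scaler.

.class_metrics <- function(truth, pred, classes) {
  tb <- table(factor(truth, classes), factor(pred, classes))
  prec <- diag(tb) / pmax(colSums(tb), 1)
  rec <- diag(tb) / pmax(rowSums(tb), 1)
  list(accuracy = mean(truth == pred),
       per_class = data.frame(class = classes, precision = unname(prec),
                              recall = unname(rec), stringsAsFactors = FALSE))
}

#' Train the multiclass phenotype transfer classifier
#'
#' Stratified random 80/20 split, multinomial logistic regression on the
#' training portion, accuracy and per-class precision/recall on the test
#' portion, with random-forest, SVM and Gaussian naive-Bayes baselines
#' fitted on the identical split.
#'
#' @param x scaled derivation feature matrix.
#' @param labels phenotype label per row.
#' @param split_fraction training fraction in (0, 1).
#' @param seed RNG seed for the split and the stochastic baselines.
#' @param baselines fit the comparator models too?
#' @return object of class `arf_transfer_model` with the fitted model, the
#'   feature set, test metrics, and baseline accuracies.
#' @export
train_transfer <- function(x, labels, split_fraction = 0.8, seed = 1L,
                           baselines = TRUE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1): an empty train or test set is not allowed")
  set.seed(seed)
  train_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    n_tr <- floor(split_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("stratification error: class '", cl,
           "' cannot populate both train and test splits")
    sample(idx, n_tr)
  }))
  test_idx <- setdiff(seq_along(labels), train_idx)
  df_tr <- data.frame(x[train_idx, , drop = FALSE])
  df_te <- data.frame(x[test_idx, , drop = FALSE])
  y_tr <- factor(labels[train_idx], classes)
  y_te <- factor(labels[test_idx], classes)
  df_tr$.y <- y_tr
  fit <- nnet::multinom(.y ~ ., data = df_tr, trace = FALSE, maxit = 300,
                        MaxNWts = 10000)
  pred <- as.character(stats::predict(fit, newdata = df_te))
  metrics <- .class_metrics(as.character(y_te), pred, classes)

  baseline_metrics <- NULL
  if (baselines) {
    set.seed(seed)
    rf <- randomForest::randomForest(x[train_idx, , drop = FALSE], y_tr,
                                     ntree = 200)
    sv <- e1071::svm(x[train_idx, , drop = FALSE], y_tr)
    nb <- e1071::naiveBayes(x[train_idx, , drop = FALSE], y_tr)
    acc <- function(p) mean(as.character(p) == as.character(y_te))
    baseline_metrics <- c(
      random_forest = acc(stats::predict(rf, x[test_idx, , drop = FALSE])),
      svm = acc(stats::predict(sv, x[test_idx, , drop = FALSE])),
      naive_bayes = acc(stats::predict(nb, x[test_idx, , drop = FALSE]))
    )
  }
  structure(list(model = fit, classes = classes, features = colnames(x),
                 split_seed = seed, metrics = metrics,
                 baseline_metrics = baseline_metrics),
            class = "arf_transfer_model")
}

#' Apply the frozen transfer classifier to an external cohort
#'
#' @param model an `arf_transfer_model`.
#' @param x external feature matrix, scaled with the frozen derivation
#'   scaler, same feature set and order.
#' @return list(labels, probabilities, prevalence) — prevalence is the
#'   recovered class-frequency table.
#' @export
apply_transfer <- function(model, x) {
  missing_f <- setdiff(model$features, colnames(x))
  extra_f <- setdiff(colnames(x), model$features)
  if (length(missing_f) || length(extra_f))
    stop("feature-set mismatch; missing: ",
         paste(missing_f, collapse = ", "), "; extra: ",
         paste(extra_f, collapse = ", "))
  x <- x[, model$features, drop = FALSE]
  if (nrow(x) == 0) {
    return(list(labels = character(0),
                probabilities = matrix(numeric(0), 0, length(model$classes),
                                       dimnames = list(NULL, model$classes)),
                prevalence = stats::setNames(rep(0, length(model$classes)),
                                             model$classes)))
  }
  probs <- stats::predict(model$model, newdata = data.frame(x), type = "probs")
  if (is.null(dim(probs))) {  # two-class or single-row edge
    if (length(model$classes) == 2) {
      probs <- cbind(1 - probs, probs)
      colnames(probs) <- model$classes
    } else probs <- matrix(probs, nrow = 1, dimnames = list(NULL, model$classes))
  }
  labels <- model$classes[max.col(probs, ties.method = "first")]
  prev <- table(factor(labels, model$classes)) / length(labels)
  list(labels = labels, probabilities = probs,
       prevalence = stats::setNames(as.numeric(prev), model$classes))
}
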