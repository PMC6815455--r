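## Evaluation: AUC, confusion-based metrics, paired t-test, Pearson
## correlation, and the repeated-experiment runner.

#' Area under the ROC curve
#'
#' Computed as the pairwise concordance probability: the probability that a
#' random active compound receives a higher score than a random inactive
#' one, with ties credited 1/2. Equivalent to the rank-sum (Mann-Whitney)
#' statistic normalized by the number of active/inactive pairs.
#'
#' @param y 0/1 labels (both classes present).
#' @param p Numeric score/probability vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, p) {
  y <- as.integer(y)
  if (length(y) != length(p))
    stop_qsar("labels and scores differ in length", class = "qsar_format_error")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_qsar("AUC undefined: single-class labels",
              class = "qsar_single_class_error")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' @param y 0/1 labels.
#' @param p Probabilities.
#' @param threshold Classification cut (default 0.5; predictions `>=`
#'   threshold are called active).
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(y, p, threshold = 0.5) {
  yhat <- as.integer(p >= threshold)
  out <- list(TP = sum(y == 1 & yhat == 1), FP = sum(y == 0 & yhat == 1),
              FN = sum(y == 1 & yhat == 0), TN = sum(y == 0 & yhat == 0),
              threshold = threshold)
  class(out) <- "confusion_counts"
  out
}

#' Accuracy, Matthews correlation and F1 from confusion counts
#'
#' Implements the standard closed forms:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`;
#' MCC `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when the denominator vanishes; F1 `2TP / (2TP+FP+FN)`, defined as 0 when
#' its denominator vanishes.
#'
#' @param counts A [confusion_counts()] object, or `TP` as a number with
#'   `FP`, `FN`, `TN` supplied.
#' @param FP,FN,TN Counts when `counts` is given as the `TP` number.
#' @return A `metrics_report` list: `accuracy`, `mcc`, `f1`, `threshold`.
#' @export
confusion_metrics <- function(counts, FP = NULL, FN = NULL, TN = NULL) {
  if (is.numeric(counts) && !is.null(FP))
    counts <- structure(list(TP = counts, FP = FP, FN = FN, TN = TN,
                             threshold = NA_real_),
                        class = "confusion_counts")
  with(counts, {
    total <- TP + FP + FN + TN
    if (total <= 0) stop_qsar("empty confusion table",
                              class = "qsar_format_error")
    acc <- (TP + TN) / total
    den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
    f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
    structure(list(accuracy = acc, mcc = mcc, f1 = f1,
                   threshold = counts$threshold),
              class = "metrics_report")
  })
}

#' Full metric panel for probabilistic predictions
#' @inheritParams confusion_counts
#' @return A `metrics_report` that also carries `auc`.
#' @export
metrics_report <- function(y, p, threshold = 0.5) {
  rep_ <- confusion_metrics(confusion_counts(y, p, threshold))
  rep_$auc <- roc_auc(y, p)
  rep_
}

#' Paired t-test on a vector of differences
#'
#' For paired outcome scores `y1`, `y2`, the differences `d = y1 - y2` are
#' tested against a mean of zero: `t = dbar / (s_d / sqrt(n))` with the
#' sample standard deviation (`n - 1` denominator) and `n - 1` degrees of
#' freedom. Two-sided by default.
#'
#' @param differences Numeric vector of paired differences, `n >= 2`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `paired_t_result`: `mean_diff`, `sd_diff`, `n`, `t_statistic`,
#'   `df`, `p_value`, and `infinite_t` (`TRUE` when `s_d = 0` but the mean
#'   difference is non-zero).
#' @export
paired_t_test <- function(differences,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 2) stop_qsar("paired t-test needs n >= 2", class = "qsar_format_error")
  dbar <- mean(d); sd_d <- stats::sd(d); df <- n - 1
  infinite_t <- FALSE
  if (sd_d == 0) {
    if (dbar == 0) { t <- 0 } else { t <- sign(dbar) * Inf; infinite_t <- TRUE }
  } else t <- dbar / (sd_d / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df))
  structure(list(mean_diff = dbar, sd_diff = sd_d, n = n, t_statistic = t,
                 df = df, p_value = p, infinite_t = infinite_t,
                 alternative = alternative),
            class = "paired_t_result")
}

#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation; the p-value comes from the
#' t-transform `t = r sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return List with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_qsar("need equal-length vectors with n >= 3",
              class = "qsar_format_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_qsar("correlation undefined for constant input",
              class = "qsar_format_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Repeated ensemble experiments on one assay
#'
#' Runs the full protocol `repeats` times: each repeat draws a fresh random
#' train/test split and fold plan from the master seed stream, trains every
#' first-level learner and the meta-ensemble, and records the test-set AUC
#' of each. Features are computed once per dataset (they do not depend on
#' the split).
#'
#' @param ds A `bioassay_dataset`.
#' @param specs List of `learner_spec`s.
#' @param combiner Meta-learner (see [train_meta()]).
#' @param repeats Number of repeated experiments (default 20).
#' @param master_seed Integer master seed.
#' @param train_fraction,k Split parameters (defaults 0.75 and 5).
#' @param features Optional precomputed named feature list; computed from
#'   `ds` when `NULL`.
#' @param fingerprint_backend Backend for ECFP/MACCS when featurizing here.
#' @param n_bags Optional first-level bagging (see [train_bagged()]).
#' @return An `experiment_table`: list with `auc` (matrix `repeats x
#'   (n_models + 1)`, last column `ensemble`), `mean`, `sd`.
#' @export
run_experiment <- function(ds, specs, combiner = "SVM", repeats = 20,
                           master_seed = 1, train_fraction = 0.75, k = 5,
                           features = NULL,
                           fingerprint_backend = "chemmineob",
                           n_bags = NULL) {
  if (repeats < 1) stop_qsar("repeats must be >= 1", class = "qsar_format_error")
  if (length(specs) < 1) stop_qsar("need at least one learner",
                                   class = "qsar_spec_error")
  reps_needed <- unique(vapply(specs, function(s) s$representation,
                               character(1)))
  if (is.null(features)) {
    features <- stats::setNames(lapply(reps_needed, function(r)
      featurize_dataset(ds, r, backend = fingerprint_backend)), reps_needed)
  }
  labels <- vapply(specs, spec_label, character(1))
  auc <- matrix(NA_real_, repeats, length(specs) + 1,
                dimnames = list(NULL, c(labels, "ensemble")))
  for (r in seq_len(repeats)) {
    plan <- split_train_test(ds, train_fraction = train_fraction, k = k,
                             seed = derive_seed(master_seed, "repeat", r))
    ens <- train_ensemble(specs, features, ds$label, plan,
                          combiner = combiner,
                          seed = derive_seed(master_seed, "meta", r),
                          n_bags = n_bags)
    pr <- predict(ens, features)
    ytest <- ds$label[plan$test_indices]
    for (j in seq_along(specs)) auc[r, j] <- roc_auc(ytest, pr$base[, j])
    auc[r, length(specs) + 1] <- roc_auc(ytest, pr$probability)
  }
  structure(list(auc = auc, mean = colMeans(auc),
                 sd = apply(auc, 2, stats::sd)),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("Mean test AUC over", nrow(x$auc), "repeats:\n")
  print(round(x$mean, 3))
  invisible(x)
}
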