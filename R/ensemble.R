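## Second-level combining: out-of-fold first-level probabilities, the
## meta-learner, and weight-based model-importance interpretation.

#' Generate the out-of-fold prediction matrix
#'
#' For every learner spec and every fold `f`, a model is trained on the
#' training folds other than `f` and predicts the held-out fold; the
#' predictions are assembled in original training order and concatenated
#' column-wise across learners. Row `i` of the result was therefore produced
#' by a model whose training data excluded compound `i` — the structural
#' no-leakage property of stacked generalization, recorded per row in
#' `fold_provenance` and auditable with [audit_oof()].
#'
#' @param specs List of `learner_spec`s (column order of the result).
#' @param features Named list of feature objects keyed by representation
#'   (e.g. `list(ECFP = <matrix>, SMILES = <smiles_tensor>)`), each covering
#'   the full dataset the plan indexes into.
#' @param y Full-dataset 0/1 labels.
#' @param plan A [split_train_test()] plan with `k >= 2` folds.
#' @param n_bags If non-`NULL`, every first-level fit is a
#'   [train_bagged()] model with this many bootstrap members.
#' @return An `oof_matrix`: list with `P` (`n_train x n_models` probability
#'   matrix), `model_order` (labels), `fold_provenance`, `train_rows` (rows
#'   each fold's models trained on), `fold_models`, and `train_indices`.
#' @export
generate_oof <- function(specs, features, y, plan, n_bags = NULL) {
  if (plan$k < 2) stop_qsar("plan must have k >= 2 folds",
                            class = "qsar_spec_error")
  tr <- plan$train_indices
  fold <- fold_of(plan, tr)
  P <- matrix(NA_real_, length(tr), length(specs))
  fold_models <- vector("list", plan$k)
  train_rows <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    in_rows <- tr[fold != f]; out_rows <- tr[fold == f]
    train_rows[[f]] <- in_rows
    fold_models[[f]] <- vector("list", length(specs))
    for (j in seq_along(specs)) {
      spec <- specs[[j]]
      Xall <- features[[spec$representation]]
      if (is.null(Xall))
        stop_qsar("no features supplied for representation %s",
                  spec$representation, class = "qsar_spec_error")
      m <- tryCatch(
        fit_first_level(spec, subset_features(Xall, in_rows), y[in_rows],
                        n_bags),
        error = function(e)
          stop_qsar("training failed for %s on fold %d: %s",
                    spec_label(spec), f, conditionMessage(e),
                    class = "qsar_training_error"))
      P[fold == f, j] <- predict(m, subset_features(Xall, out_rows))
      fold_models[[f]][[j]] <- m
    }
  }
  colnames(P) <- vapply(specs, spec_label, character(1))
  structure(list(P = P, model_order = colnames(P), specs = specs,
                 fold_provenance = fold, train_rows = train_rows,
                 fold_models = fold_models, train_indices = tr),
            class = "oof_matrix")
}

#' @noRd
fit_first_level <- function(spec, X, y, n_bags = NULL) {
  if (is.null(n_bags)) train_base(spec, X, y)
  else train_bagged(spec, X, y, n_bags = n_bags, seed = spec$seed)
}

#' @noRd
subset_features <- function(X, rows) {
  idx <- rows
  if (length(dim(X)) == 3) return(X[idx, , ])
  out <- X[idx, , drop = FALSE]
  attr(out, "representation") <- attr(X, "representation")
  out
}

#' Structural no-leakage audit of an OOF matrix
#'
#' Verifies, row by row, that the model which produced each out-of-fold
#' entry was trained on rows excluding that row, and that every entry is a
#' probability. Errors on the first violation; returns `TRUE` invisibly.
#'
#' @param oof An `oof_matrix`.
#' @return `TRUE` (invisibly) if the audit passes.
#' @export
audit_oof <- function(oof) {
  if (any(!is.finite(oof$P)) || any(oof$P < 0 | oof$P > 1))
    stop_qsar("OOF matrix contains non-probability entries",
              class = "qsar_leakage_error")
  for (i in seq_along(oof$train_indices)) {
    f <- oof$fold_provenance[i]
    if (oof$train_indices[i] %in% oof$train_rows[[f]])
      stop_qsar("leakage: row %d was in the training rows of its fold %d",
                oof$train_indices[i], f, class = "qsar_leakage_error")
  }
  invisible(TRUE)
}

#' Uniform average of per-model probabilities
#'
#' The non-learning combiner: equal weight `1/n` per model.
#' @param probabilities Numeric vector (or matrix with models in columns).
#' @return The arithmetic mean (row means for a matrix).
#' @export
uniform_average <- function(probabilities) {
  if (length(probabilities) == 0)
    stop_qsar("uniform_average of empty input", class = "qsar_spec_error")
  if (is.matrix(probabilities)) rowMeans(probabilities)
  else mean(probabilities)
}

#' Train the second-level (meta) learner
#'
#' Combines the first-level out-of-fold probabilities into a final decision.
#' `SVM` (linear, Platt-calibrated — the best-performing combiner in the
#' reference experiments), `LOGISTIC` and `OLS` are linear combiners whose
#' weight vector is recoverable for importance interpretation; `RF`, `GBM`
#' and `NN` are nonlinear alternatives; `UNIFORM` fixes every weight to
#' `1/n`.
#'
#' @param P An `oof_matrix` or a plain probability matrix.
#' @param y 0/1 labels aligned with the rows of `P`.
#' @param combiner One of `"SVM"`, `"LOGISTIC"`, `"OLS"`, `"RF"`, `"GBM"`,
#'   `"NN"`, `"UNIFORM"`.
#' @param seed Integer seed.
#' @return A `meta_model` with fields `combiner`, `weights` (linear
#'   combiners only) and the fitted state.
#' @export
train_meta <- function(P, y, combiner = c("SVM", "LOGISTIC", "OLS", "RF",
                                          "GBM", "NN", "UNIFORM"),
                       seed = 1) {
  combiner <- match.arg(combiner)
  model_order <- if (inherits(P, "oof_matrix")) P$model_order else colnames(P)
  M <- if (inherits(P, "oof_matrix")) P$P else as.matrix(P)
  if (is.null(model_order)) model_order <- paste0("model", seq_len(ncol(M)))
  if (combiner != "UNIFORM" && length(unique(y)) < 2)
    stop_qsar("meta-learning requires both classes",
              class = "qsar_single_class_error")
  if (nrow(M) != length(y))
    stop_qsar("P rows (%d) do not align with y (%d)", nrow(M), length(y),
              class = "qsar_spec_error")
  fit <- NULL; weights <- NULL
  if (combiner == "UNIFORM") {
    weights <- rep(1 / ncol(M), ncol(M))
  } else if (combiner == "LOGISTIC") {
    df <- as.data.frame(M); names(df) <- paste0("m", seq_len(ncol(M)))
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    weights <- unname(stats::coef(fit)[-1])
    weights[!is.finite(weights)] <- 0
  } else if (combiner == "OLS") {
    df <- as.data.frame(M); names(df) <- paste0("m", seq_len(ncol(M)))
    fit <- stats::lm(y ~ ., data = df)
    weights <- unname(stats::coef(fit)[-1])
    weights[!is.finite(weights)] <- 0
  } else {
    spec <- default_spec(switch(combiner, SVM = "SVM", RF = "RF",
                                GBM = "GBM", NN = "NN"),
                         "ECFP", seed = seed)
    if (combiner == "NN")
      spec$hyperparams <- utils::modifyList(spec$hyperparams,
                                            list(hidden = c(32L),
                                                 activations = "relu",
                                                 epochs = 60L))
    Xmeta <- M; attr(Xmeta, "representation") <- NULL
    fit <- train_base(spec, Xmeta, y)
    if (combiner == "SVM") {
      # linear SVM weight vector: w = t(coefs) %*% SV, oriented to active
      w <- as.numeric(crossprod(fit$fit$coefs, fit$fit$SV))
      if (!isTRUE(fit$positive_first)) w <- -w
      weights <- w
    }
  }
  structure(list(combiner = combiner, weights = weights, fit = fit,
                 model_order = model_order, n_models = ncol(M)),
            class = "meta_model")
}

#' Predict final probabilities from a meta-model
#' @param object A `meta_model`.
#' @param P Matrix of first-level probabilities (columns in
#'   `object$model_order`).
#' @param ... Unused.
#' @return Final ensemble probabilities in `[0, 1]`.
#' @export
predict.meta_model <- function(object, P, ...) {
  M <- if (inherits(P, "oof_matrix")) P$P else as.matrix(P)
  if (ncol(M) != object$n_models)
    stop_qsar("model count mismatch: meta has %d, input has %d",
              object$n_models, ncol(M), class = "qsar_spec_error")
  if (!is.null(colnames(M)) &&
      !identical(colnames(M), object$model_order))
    stop_qsar("model order mismatch between meta-model and inputs",
              class = "qsar_spec_error")
  switch(object$combiner,
    UNIFORM = rowMeans(M),
    LOGISTIC = as.numeric(stats::predict(
      object$fit, stats::setNames(as.data.frame(M),
                                  paste0("m", seq_len(ncol(M)))),
      type = "response")),
    OLS = pmin(pmax(as.numeric(stats::predict(
      object$fit, stats::setNames(as.data.frame(M),
                                  paste0("m", seq_len(ncol(M)))))), 0), 1),
    { Xm <- M; attr(Xm, "representation") <- NULL
      predict(object$fit, Xm) })
}

#' Model importance from a linear meta-learner
#'
#' Normalized absolute weights, `|w_i| / sum_j |w_j|`: the learned weight a
#' linear combiner places on each first-level model, interpretable as that
#' model's importance to the final decision. Invariant to positive rescaling
#' of the weight vector; defined only for linear combiners (`SVM`,
#' `LOGISTIC`, `OLS`, `UNIFORM`).
#'
#' @param meta A `meta_model`.
#' @return Named numeric vector summing to 1.
#' @export
model_importance <- function(meta) {
  if (is.null(meta$weights))
    stop_qsar("model importance is defined only for linear combiners (got %s)",
              meta$combiner, class = "qsar_interpretation_error")
  w <- abs(meta$weights)
  if (sum(w) == 0) w <- rep(1, length(w))
  stats::setNames(w / sum(w), meta$model_order)
}

#' Train a full comprehensive ensemble
#'
#' Runs the two-level procedure on one training split: out-of-fold
#' first-level probabilities, the meta-learner on those probabilities, and a
#' refit of every first-level learner on the full training set for test-time
#' prediction (standard stacked generalization; fold-model averaging is
#' available via `refit = FALSE`).
#'
#' @inheritParams generate_oof
#' @param combiner Meta-learner, see [train_meta()].
#' @param refit If `TRUE` (default), base learners are refit on the full
#'   training set for test-time prediction; otherwise the five fold models
#'   are averaged.
#' @param n_bags Optional bootstrap-bagging of every first-level learner
#'   (see [train_bagged()]).
#' @param seed Integer seed for the meta-learner.
#' @return A `qsar_ensemble` with `oof`, `meta`, `base_models` and the plan.
#' @export
train_ensemble <- function(specs, features, y, plan,
                           combiner = "SVM", refit = TRUE, seed = 1,
                           n_bags = NULL) {
  oof <- generate_oof(specs, features, y, plan, n_bags = n_bags)
  meta <- train_meta(oof, y[plan$train_indices], combiner = combiner,
                     seed = seed)
  base_models <- NULL
  if (refit) {
    base_models <- lapply(specs, function(spec) {
      Xall <- features[[spec$representation]]
      fit_first_level(spec, subset_features(Xall, plan$train_indices),
                      y[plan$train_indices], n_bags)
    })
  }
  structure(list(specs = specs, oof = oof, meta = meta,
                 base_models = base_models, plan = plan, refit = refit),
            class = "qsar_ensemble")
}

#' Predict with a comprehensive ensemble
#' @param object A `qsar_ensemble`.
#' @param features Named feature list as in [generate_oof()], covering the
#'   rows in `indices`.
#' @param indices Dataset indices to predict (default: the plan's test set).
#' @param ... Unused.
#' @return List with `probability` (final ensemble) and `base` (matrix of
#'   first-level probabilities).
#' @export
predict.qsar_ensemble <- function(object, features,
                                  indices = object$plan$test_indices, ...) {
  specs <- object$specs
  base <- matrix(NA_real_, length(indices), length(specs),
                 dimnames = list(NULL, object$oof$model_order))
  for (j in seq_along(specs)) {
    Xall <- features[[specs[[j]]$representation]]
    Xt <- subset_features(Xall, indices)
    if (object$refit) {
      base[, j] <- predict(object$base_models[[j]], Xt)
    } else {
      fold_preds <- vapply(object$oof$fold_models,
                           function(fm) predict(fm[[j]], Xt),
                           numeric(length(indices)))
      if (is.null(dim(fold_preds)))
        fold_preds <- matrix(fold_preds, nrow = 1)
      base[, j] <- rowMeans(fold_preds)
    }
  }
  list(probability = predict(object$meta, base), base = base)
}
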