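## First-level learners: the thirteen (method x representation) base models.
## RF and GBM go through randomForest and xgboost; the linear SVM (e1071) is
## Platt-calibrated on internal cross-validated decision scores; NN and the
## SMILES CNN->GRU use the package's own backend.

.methods <- c("RF", "SVM", "GBM", "NN", "CNN_GRU")
.representations <- c("PUBCHEM", "ECFP", "MACCS", "SMILES")

#' Specify a first-level learner
#'
#' Valid combinations: `RF`, `SVM`, `GBM`, `NN` with any fingerprint family
#' (`PUBCHEM`, `ECFP`, `MACCS`), and `CNN_GRU` with `SMILES` — thirteen
#' combinations in total.
#'
#' @param method One of `"RF"`, `"SVM"`, `"GBM"`, `"NN"`, `"CNN_GRU"`.
#' @param representation One of `"PUBCHEM"`, `"ECFP"`, `"MACCS"`, `"SMILES"`.
#' @param hyperparams Named list overriding the method defaults.
#' @param seed Integer seed.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(method, representation, hyperparams = list(),
                         seed = 1) {
  method <- match.arg(method, .methods)
  representation <- match.arg(representation, .representations)
  if ((method == "CNN_GRU") != (representation == "SMILES"))
    stop_qsar("invalid combination %s x %s: CNN_GRU pairs only with SMILES and fingerprint methods only with fingerprints",
              method, representation, class = "qsar_spec_error")
  structure(list(method = method, representation = representation,
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Human-readable label of a learner spec
#' @param spec A `learner_spec`.
#' @return E.g. `"ECFP-RF"` or `"SMILES-CNN_GRU"`.
#' @export
spec_label <- function(spec) {
  rep_lab <- c(PUBCHEM = "PubChem", ECFP = "ECFP", MACCS = "MACCS",
               SMILES = "SMILES")[[spec$representation]]
  paste0(rep_lab, "-", spec$method)
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec %s (seed %d)>\n", spec_label(x), x$seed))
  invisible(x)
}

#' Default learner specification for a method/representation pair
#'
#' Defaults follow the reference protocol: 100 estimators for RF and GBM
#' (GBM additionally depth 3, learning rate 0.1); linear-kernel SVM with
#' penalty parameter 0.05 and Platt calibration; the feed-forward network
#' uses 512/64/1 units with ReLU/tanh/sigmoid, Adam at learning rate 0.001,
#' 30 epochs, minibatch 256; the SMILES model uses [cnn_gru_default_hp()].
#'
#' @inheritParams learner_spec
#' @return A `learner_spec` with filled `hyperparams`.
#' @export
default_spec <- function(method, representation, seed = 1) {
  method <- match.arg(method, .methods)
  hp <- switch(method,
    RF = list(ntree = 100L),
    SVM = list(kernel = "linear", cost = 0.05, calibrate = TRUE,
               calibration_folds = 3L),
    GBM = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    NN = list(hidden = c(512L, 64L), activations = c("relu", "tanh"),
              lr = 0.001, epochs = 30L, batch_size = 256L),
    CNN_GRU = cnn_gru_default_hp())
  learner_spec(method, representation, hyperparams = hp, seed = seed)
}

#' All thirteen default first-level learners
#'
#' Ordered as the reference model list: PubChem-RF/SVM/GBM/NN, then
#' ECFP-..., MACCS-..., then SMILES-CNN_GRU, so importance grids are
#' comparable across runs.
#'
#' @param seed Integer master seed; each learner derives its own stream.
#' @return List of thirteen `learner_spec`s.
#' @export
all_default_specs <- function(seed = 1) {
  specs <- list()
  for (rep_ in c("PUBCHEM", "ECFP", "MACCS"))
    for (m in c("RF", "SVM", "GBM", "NN"))
      specs[[length(specs) + 1]] <-
        default_spec(m, rep_, seed = derive_seed(seed, m, rep_))
  specs[[length(specs) + 1]] <-
    default_spec("CNN_GRU", "SMILES", seed = derive_seed(seed, "CNN_GRU"))
  specs
}

## Platt calibration ---------------------------------------------------------

#' Fit a Platt-style sigmoid calibrator
#'
#' Maps raw classifier scores to probabilities via
#' `p = 1 / (1 + exp(a * s + b))`, with `(a, b)` minimizing binomial
#' cross-entropy (logistic regression on the score). The calibrator is
#' constrained monotone non-decreasing in the score; if the fitted slope
#' points the wrong way, or all scores are equal, the calibrator degenerates
#' to the constant class prevalence.
#'
#' @param scores Numeric score vector.
#' @param y 0/1 labels (both classes present).
#' @return A `platt_calibrator`.
#' @export
fit_platt_calibration <- function(scores, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop_qsar("calibration requires both classes",
              class = "qsar_single_class_error")
  prevalence <- mean(y)
  if (stats::sd(scores) == 0 || !is.finite(stats::sd(scores))) {
    cal <- list(flat = TRUE, prevalence = prevalence)
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ scores, family = stats::binomial()))
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope < 0) {
      cal <- list(flat = TRUE, prevalence = prevalence)
    } else {
      # glm parameterization: p = 1/(1+exp(-(b0 + b1 s))) -> a = -b1, b = -b0
      cal <- list(flat = FALSE, a = -slope,
                  b = -unname(stats::coef(fit)[1]))
    }
  }
  class(cal) <- "platt_calibrator"
  cal
}

#' Apply a Platt calibrator to scores
#' @param cal A `platt_calibrator`.
#' @param scores Numeric scores.
#' @return Probabilities in `(0, 1)`.
#' @export
apply_calibration <- function(cal, scores) {
  if (cal$flat) return(rep(cal$prevalence, length(scores)))
  1 / (1 + exp(cal$a * scores + cal$b))
}

## Training ------------------------------------------------------------------

#' @noRd
check_training_inputs <- function(spec, X, y) {
  if (length(unique(y)) < 2)
    stop_qsar("cannot train %s on single-class labels", spec_label(spec),
              class = "qsar_single_class_error")
  xrep <- attr(X, "representation")
  if (!is.null(xrep) && xrep != spec$representation)
    stop_qsar("features are %s but spec wants %s", xrep, spec$representation,
              class = "qsar_spec_error")
  if (spec$method == "CNN_GRU" && length(dim(X)) != 3)
    stop_qsar("CNN_GRU requires a smiles_tensor", class = "qsar_spec_error")
}

#' @noRd
svm_oriented_scores <- function(fit, X, positive_first) {
  d <- attr(stats::predict(fit, X, decision.values = TRUE),
            "decision.values")[, 1]
  if (positive_first) d else -d
}

#' Train a first-level model
#'
#' Fits the learner described by `spec` on the given representation and
#' returns a model whose `predict` method emits probabilities of the active
#' class. RF, SVM and GBM are deterministic given `spec$seed`; the neural
#' methods are deterministic too (the backend seeds initialization, batch
#' order and dropout). The SVM is calibrated with a Platt sigmoid fitted on
#' internal cross-validated decision scores (leakage-safe), then refit on
#' the full data.
#'
#' @param spec A `learner_spec` (see [default_spec()]).
#' @param X Features matching `spec$representation` (fingerprint matrix or
#'   `smiles_tensor`).
#' @param y 0/1 labels, both classes present.
#' @return A `trained_model`.
#' @export
train_base <- function(spec, X, y) {
  check_training_inputs(spec, X, y)
  y <- as.integer(y)
  hp <- utils::modifyList(default_spec(spec$method, spec$representation)$hyperparams,
                          spec$hyperparams)
  fit <- calibrator <- NULL
  positive_first <- NA
  if (spec$method == "RF") {
    fit <- with_seed(spec$seed,
      randomForest::randomForest(x = as.matrix(X), y = factor(y, levels = 0:1),
                                 ntree = hp$ntree))
  } else if (spec$method == "GBM") {
    d <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = spec$seed),
      data = d, nrounds = hp$nrounds, verbose = 0)
  } else if (spec$method == "SVM") {
    Xm <- as.matrix(X); yf <- factor(y, levels = 0:1)
    fit <- e1071::svm(Xm, yf, kernel = hp$kernel, cost = hp$cost,
                      scale = FALSE)
    # orient decision scores so that higher means active
    d0 <- attr(stats::predict(fit, Xm, decision.values = TRUE),
               "decision.values")
    positive_first <- grepl("^1", colnames(d0)[1])
    if (isTRUE(hp$calibrate)) {
      # internal k-fold cross-validated scores keep the sigmoid honest
      kc <- hp$calibration_folds
      cv_scores <- rep(NA_real_, length(y))
      folds <- with_seed(derive_seed(spec$seed, "platt"),
                         sample(rep(seq_len(kc), length.out = length(y))))
      for (f in seq_len(kc)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) next
        sub <- e1071::svm(Xm[tr, , drop = FALSE], yf[tr], kernel = hp$kernel,
                          cost = hp$cost, scale = FALSE)
        dsub <- attr(stats::predict(sub, Xm[!tr, , drop = FALSE],
                                    decision.values = TRUE),
                     "decision.values")
        s <- dsub[, 1]
        if (!grepl("^1", colnames(dsub)[1])) s <- -s
        cv_scores[!tr] <- s
      }
      ok <- !is.na(cv_scores)
      calibrator <- fit_platt_calibration(cv_scores[ok], y[ok])
    }
  } else if (spec$method == "NN") {
    fit <- mlp_fit(as.matrix(X), y, hidden = hp$hidden,
                   activations = hp$activations, lr = hp$lr,
                   epochs = hp$epochs, batch_size = hp$batch_size,
                   seed = spec$seed)
  } else { # CNN_GRU
    fit <- cnn_gru_fit(X, y, hp = hp, seed = spec$seed)
  }
  structure(list(spec = spec, fit = fit, calibrator = calibrator,
                 positive_first = positive_first, hyperparams = hp),
            class = "trained_model")
}

#' Predict active-class probabilities from a trained first-level model
#' @param object A `trained_model`.
#' @param X Features in the model's representation.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`.
#' @export
predict.trained_model <- function(object, X, ...) {
  m <- object$spec$method
  p <- switch(m,
    RF = stats::predict(object$fit, as.matrix(X), type = "prob")[, "1"],
    GBM = stats::predict(object$fit, xgboost::xgb.DMatrix(as.matrix(X))),
    SVM = {
      s <- svm_oriented_scores(object$fit, as.matrix(X),
                               object$positive_first)
      if (!is.null(object$calibrator)) apply_calibration(object$calibrator, s)
      else .sigmoid(s)
    },
    NN = stats::predict(object$fit, X),
    CNN_GRU = stats::predict(object$fit, X))
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

## Bagging -------------------------------------------------------------------

#' Train a bagged (bootstrap-aggregated) first-level model
#'
#' Each member is trained on an `n`-sized bootstrap resample (about 63.2%
#' unique compounds per bag for large `n`); the bagged prediction is the
#' uniform mean of the member probabilities. Bagging targets the variance
#' component of the error and is particularly helpful on class-imbalanced
#' screens.
#'
#' @param spec A `learner_spec`.
#' @param X,y Training features and 0/1 labels.
#' @param n_bags Number of bootstrap members (>= 1).
#' @param seed Integer seed for the resamples (member `i` additionally
#'   derives its own model seed).
#' @param resample If `FALSE` (with `n_bags = 1`), trains a single model on
#'   the original data — identical to [train_base()].
#' @return A `bagged_model`.
#' @export
train_bagged <- function(spec, X, y, n_bags = 10, seed = 1, resample = TRUE) {
  if (n_bags < 1) stop_qsar("n_bags must be >= 1", class = "qsar_spec_error")
  n <- if (length(dim(X)) == 3) dim(X)[1] else nrow(X)
  members <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    rows <- if (resample)
      with_seed(derive_seed(seed, "bag", b), sample(n, n, replace = TRUE))
    else seq_len(n)
    sb <- spec
    sb$seed <- derive_seed(seed, "bagseed", b)
    if (!resample && n_bags == 1) sb$seed <- spec$seed
    Xb <- if (length(dim(X)) == 3) X[rows, , , drop = FALSE]
          else X[rows, , drop = FALSE]
    for (a in c("representation", "vocab")) attr(Xb, a) <- attr(X, a)
    members[[b]] <- train_base(sb, Xb, y[rows])
  }
  structure(list(spec = spec, members = members, n_bags = n_bags,
                 seed = seed),
            class = "bagged_model")
}

#' @rdname train_bagged
#' @param object A `bagged_model`.
#' @param ... Unused.
#' @export
predict.bagged_model <- function(object, X, ...) {
  preds <- vapply(object$members, function(m) predict(m, X),
                  numeric(if (length(dim(X)) == 3) dim(X)[1] else nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Expected uniqueness of bootstrap resamples
#'
#' Simulates `replicates` n-sized bootstrap draws and returns the mean
#' fraction of distinct originals per draw. For large `n` this converges to
#' `1 - 1/e` (about 63.2%) — the diversity argument behind bagging.
#'
#' @param n Sample size.
#' @param replicates Number of simulated resamples.
#' @param seed Integer seed.
#' @return Mean unique fraction in `(0, 1)`.
#' @export
bootstrap_unique_fraction <- function(n, replicates = 200, seed = 1) {
  with_seed(seed, {
    mean(vapply(seq_len(replicates), function(r)
      length(unique(sample.int(n, n, replace = TRUE))) / n, numeric(1)))
  })
}
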