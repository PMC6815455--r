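test_that("the OOF matrix has stacking shape and passes its audit", {
  n <- 30
  X <- fake_fingerprints(n, d = 10, seed = 1)
  y <- rep_len(c(1, 0, 1), n)
  ds <- bioassay_dataset(paste0("c", 1:n), rep("CC", n), y)
  plan <- split_train_test(ds, train_fraction = 2 / 3, k = 5, seed = 2)
  specs <- list(cheap_spec(seed = 1), cheap_spec(seed = 2))
  oof <- generate_oof(specs, list(MACCS = X), y, plan)
  expect_equal(dim(oof$P), c(20L, 2L))
  expect_true(all(oof$P >= 0 & oof$P <= 1))
  expect_true(audit_oof(oof))
  # each fold contributes its block of rows for every model
  expect_equal(unname(table(oof$fold_provenance)), rep(4L, 5),
               ignore_attr = TRUE)
})

test_that("OOF entries equal hand-computed fold training means", {
  # constant features force an intercept-only boosted model, whose
  # prediction converges to its training fold's label mean; with folds
  # {1,2} {3,4} {5,6} the held-out entries are enumerable by hand
  X <- matrix(0L, 6, 4); attr(X, "representation") <- "MACCS"
  y <- c(1, 0, 1, 1, 0, 0)
  plan <- manual_plan(c(1, 1, 2, 2, 3, 3))
  spec <- learner_spec("GBM", "MACCS", hyperparams = list(nrounds = 200L),
                       seed = 1)
  oof <- generate_oof(list(spec), list(MACCS = X), y, plan)
  expected <- c(mean(y[3:6]), mean(y[3:6]),       # fold 1 held out
                mean(y[c(1, 2, 5, 6)]), mean(y[c(1, 2, 5, 6)]),
                mean(y[1:4]), mean(y[1:4]))
  expect_equal(unname(oof$P[, 1]), expected, tolerance = 0.01)
})

test_that("meta-learning recovers the informative model", {
  pc <- generate_probability_columns(500, oracle_strength = 0.8, n_noise = 4,
                                     seed = 19)
  meta <- train_meta(pc$P, pc$labels, combiner = "SVM", seed = 19)
  imp <- model_importance(meta)
  expect_equal(names(which.max(imp)), "oracle")
  expect_equal(sum(imp), 1)

  # a column equal to the labels dominates importance outright
  qsarstack:::with_seed(20, {
    y <- rbinom(500, 1, 0.5)
    P <- cbind(exact = y, matrix(runif(500 * 3), 500, 3))
    colnames(P) <- c("exact", paste0("n", 1:3))
    m2 <- train_meta(P, y, combiner = "LOGISTIC")
    expect_equal(names(which.max(model_importance(m2))), "exact")
  })

  # uniform combiner: all weights 1/n
  mu <- train_meta(pc$P, pc$labels, combiner = "UNIFORM")
  expect_equal(unname(model_importance(mu)), rep(1 / 5, 5))

  # single-column meta prediction preserves the column's ranking
  qsarstack:::with_seed(21, {
    y <- rbinom(200, 1, 0.5); y[1:2] <- c(0, 1)
    P1 <- matrix(runif(200), 200, 1, dimnames = list(NULL, "only"))
    P1[, 1] <- 0.7 * y + 0.3 * P1[, 1]
    m1 <- train_meta(P1, y, combiner = "SVM")
    pr <- predict(m1, P1)
    # monotone non-decreasing in the column (ties allowed where the steep
    # calibrated sigmoid saturates in double precision)
    expect_true(all(diff(pr[order(P1[, 1])]) >= 0))
    expect_gt(cor(pr, P1[, 1], method = "spearman"), 0.9)
  })

  expect_error(train_meta(pc$P, rep(1, 500), combiner = "SVM"),
               class = "qsar_single_class_error")
})

test_that("importance normalizes absolute weights and needs linearity", {
  meta <- structure(list(combiner = "OLS", weights = c(2, -1, 1),
                         model_order = c("a", "b", "c"), n_models = 3),
                    class = "meta_model")
  expect_equal(unname(model_importance(meta)), c(0.5, 0.25, 0.25))
  # invariant to positive rescaling
  meta$weights <- meta$weights * 7.3
  expect_equal(unname(model_importance(meta)), c(0.5, 0.25, 0.25))
  nl <- structure(list(combiner = "RF", weights = NULL), class = "meta_model")
  expect_error(model_importance(nl), class = "qsar_interpretation_error")

  # uniform over thirteen models
  u <- train_meta(matrix(runif(26 * 13), 26, 13), rep_len(0:1, 26),
                  combiner = "UNIFORM")
  expect_equal(unname(model_importance(u)), rep(1 / 13, 13))
})

test_that("uniform averaging and ensemble prediction behave as means", {
  expect_equal(uniform_average(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(uniform_average(0.37), 0.37)
  expect_equal(uniform_average(rep(0.7, 13)), 0.7)
  expect_error(uniform_average(numeric(0)), class = "qsar_spec_error")

  # constant base outputs pass through a uniform meta unchanged
  mu <- structure(list(combiner = "UNIFORM", weights = rep(1 / 3, 3),
                       model_order = c("a", "b", "c"), n_models = 3),
                  class = "meta_model")
  P <- matrix(0.3, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(mu, P), rep(0.3, 5))

  # order mismatch is an error
  Pbad <- P; colnames(Pbad) <- c("b", "a", "c")
  expect_error(predict(mu, Pbad), class = "qsar_spec_error")

  # a single base model under a uniform meta is the identity
  m1 <- structure(list(combiner = "UNIFORM", weights = 1,
                       model_order = "a", n_models = 1),
                  class = "meta_model")
  p <- matrix(runif(10), 10, 1, dimnames = list(NULL, "a"))
  expect_equal(predict(m1, p), unname(p[, 1]))
})

test_that("the stacked ensemble ranks above noise-only columns out of sample", {
  # planted-oracle construction, held-out half: the meta ensemble must beat
  # every pure-noise model it combines
  pc <- generate_probability_columns(600, oracle_strength = 0.7, n_noise = 4,
                                     seed = 33)
  tr <- 1:300; te <- 301:600
  meta <- train_meta(pc$P[tr, ], pc$labels[tr], combiner = "SVM", seed = 33)
  pr <- predict(meta, pc$P[te, ])
  auc_ens <- roc_auc(pc$labels[te], pr)
  for (j in 2:5)
    expect_gte(auc_ens, roc_auc(pc$labels[te], pc$P[te, j]))
})

test_that("train_ensemble end-to-end predicts the held-out set", {
  n <- 90
  X <- fake_fingerprints(n, d = 16, seed = 3)
  y <- separable_labels(X)
  ds <- bioassay_dataset(paste0("c", 1:n), rep("CC", n), y)
  plan <- split_train_test(ds, seed = 5, k = 3)
  specs <- list(cheap_spec(seed = 1), cheap_spec(seed = 2))
  ens <- train_ensemble(specs, list(MACCS = X), y, plan, combiner = "LOGISTIC")
  pr <- predict(ens, list(MACCS = X))
  expect_length(pr$probability, length(plan$test_indices))
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_gte(roc_auc(y[plan$test_indices], pr$probability), 0.9)
  # fold-model averaging path
  ens2 <- train_ensemble(specs, list(MACCS = X), y, plan,
                         combiner = "UNIFORM", refit = FALSE)
  pr2 <- predict(ens2, list(MACCS = X))
  expect_length(pr2$probability, length(plan$test_indices))
  # bagged first level
  ens3 <- train_ensemble(specs[1], list(MACCS = X), y, plan,
                         combiner = "UNIFORM", n_bags = 2)
  expect_s3_class(ens3$base_models[[1]], "bagged_model")
})
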