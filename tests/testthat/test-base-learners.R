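test_that("exactly thirteen method/representation combinations are valid", {
  valid <- 0
  for (m in c("RF", "SVM", "GBM", "NN", "CNN_GRU"))
    for (r in c("PUBCHEM", "ECFP", "MACCS", "SMILES")) {
      ok <- tryCatch({ learner_spec(m, r); TRUE },
                     qsar_spec_error = function(e) FALSE)
      valid <- valid + ok
    }
  expect_equal(valid, 13)
  expect_error(learner_spec("CNN_GRU", "PUBCHEM"), class = "qsar_spec_error")
  expect_error(learner_spec("RF", "SMILES"), class = "qsar_spec_error")
  expect_length(all_default_specs(), 13)
  expect_equal(spec_label(all_default_specs()[[13]]), "SMILES-CNN_GRU")
})

test_that("default hyperparameters follow the reference protocol", {
  sv <- default_spec("SVM", "ECFP")
  expect_equal(sv$hyperparams$cost, 0.05)
  expect_equal(sv$hyperparams$kernel, "linear")
  expect_true(sv$hyperparams$calibrate)
  nn <- default_spec("NN", "MACCS")
  expect_equal(nn$hyperparams$epochs, 30L)
  expect_equal(nn$hyperparams$batch_size, 256L)
  expect_equal(nn$hyperparams$lr, 0.001)
  expect_equal(nn$hyperparams$hidden, c(512L, 64L))
  expect_equal(default_spec("RF", "ECFP")$hyperparams$ntree, 100L)
  gb <- default_spec("GBM", "ECFP")$hyperparams
  expect_equal(gb$nrounds, 100L); expect_equal(gb$max_depth, 3L)
  cg <- default_spec("CNN_GRU", "SMILES")$hyperparams
  expect_equal(cg$n_filters, 384L); expect_equal(cg$filter_width, 17L)
  expect_equal(cg$gru_units, 9L); expect_equal(cg$epochs, 120L)
  expect_equal(unname(cg$dropout), c(0.9, 0.6, 0.6))
})

test_that("every method separates a linearly separable toy screen", {
  X <- fake_fingerprints(40, d = 16, seed = 2)
  y <- separable_labels(X)
  for (m in c("RF", "SVM", "GBM")) {
    fit <- train_base(default_spec(m, "MACCS", seed = 3), X, y)
    p <- predict(fit, X)
    expect_equal(roc_auc(y, p), 1)
    expect_true(all(p >= 0 & p <= 1) && !anyNA(p))
  }
  nn_spec <- default_spec("NN", "MACCS", seed = 3)
  nn_spec$hyperparams$batch_size <- 16L
  expect_equal(roc_auc(y, predict(train_base(nn_spec, X, y), X)), 1)

  # calibrated SVM probabilities live strictly inside (0, 1)
  psvm <- predict(train_base(default_spec("SVM", "MACCS", seed = 3), X, y), X)
  expect_true(all(psvm > 0 & psvm < 1))

  expect_error(train_base(default_spec("RF", "MACCS"), X, rep(1, 40)),
               class = "qsar_single_class_error")
  Xe <- X; attr(Xe, "representation") <- "ECFP"
  expect_error(train_base(default_spec("RF", "MACCS"), Xe, y),
               class = "qsar_spec_error")
})

test_that("deterministic learners reproduce bit-identical predictions", {
  X <- fake_fingerprints(60, d = 20, seed = 5)
  y <- qsarstack:::with_seed(6, rbinom(60, 1, 0.4))
  Xnew <- fake_fingerprints(30, d = 20, seed = 9)
  for (m in c("RF", "SVM", "GBM")) {
    s <- default_spec(m, "MACCS", seed = 11)
    p1 <- predict(train_base(s, X, y), Xnew)
    p2 <- predict(train_base(s, X, y), Xnew)
    expect_identical(p1, p2)
  }
})

test_that("Platt calibration recovers a planted sigmoid and degenerates sanely", {
  a <- -2; b <- 0.5
  qsarstack:::with_seed(8, {
    s <- rnorm(3000)
    p_true <- 1 / (1 + exp(a * s + b))
    y <- rbinom(3000, 1, p_true)
    cal <- fit_platt_calibration(s, y)
    grid <- seq(-2, 2, by = 0.25)
    expect_lt(max(abs(apply_calibration(cal, grid) -
                        1 / (1 + exp(a * grid + b)))), 0.05)
    # monotone non-decreasing
    out <- apply_calibration(cal, sort(rnorm(100)))
    expect_true(all(diff(out) >= 0))
  })
  flat <- fit_platt_calibration(rep(0, 10), c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(apply_calibration(flat, c(-1, 0, 7)), rep(0.3, 3))
  expect_error(fit_platt_calibration(1:5, rep(1, 5)),
               class = "qsar_single_class_error")
})

test_that("bagged predictions are the uniform mean of member predictions", {
  X <- fake_fingerprints(50, d = 12, seed = 4)
  y <- separable_labels(X)
  bag <- train_bagged(cheap_spec(seed = 2), X, y, n_bags = 3, seed = 2)
  expect_length(bag$members, 3)
  Xnew <- fake_fingerprints(20, d = 12, seed = 13)
  member_preds <- vapply(bag$members, function(m) predict(m, Xnew),
                         numeric(20))
  expect_equal(predict(bag, Xnew), rowMeans(member_preds))
  expect_equal(uniform_average(c(0.2, 0.4, 0.9)), 0.5)

  # n_bags = 1 without resampling is exactly the plain model
  single <- train_bagged(cheap_spec(seed = 2), X, y, n_bags = 1, seed = 2,
                         resample = FALSE)
  plain <- train_base(cheap_spec(seed = 2), X, y)
  expect_identical(predict(single, Xnew), predict(plain, Xnew))
})

test_that("bootstrap resamples contain about 63.2% unique compounds", {
  frac <- bootstrap_unique_fraction(2000, replicates = 50, seed = 3)
  expect_lt(abs(frac - (1 - exp(-1))), 0.01)
})

test_that("bagging does not increase prediction variance across seeds", {
  # noisy screen: the variance of bagged test predictions over training
  # seeds must not exceed that of single networks (variance-error argument)
  Xtr <- fake_fingerprints(120, d = 20, seed = 21)
  Xte <- fake_fingerprints(40, d = 20, seed = 22)
  ytr <- qsarstack:::with_seed(23, {
    p <- 0.15 + 0.7 * (Xtr[, 1] * 0.5 + Xtr[, 2] * 0.5)
    rbinom(120, 1, p)
  })
  hp <- list(hidden = c(8L), activations = "relu", epochs = 10L,
             batch_size = 32L)
  single <- bagged <- matrix(NA_real_, 40, 20)
  for (s in 1:20) {
    spec <- learner_spec("NN", "MACCS", hyperparams = hp, seed = s)
    single[, s] <- predict(train_base(spec, Xtr, ytr), Xte)
    bagged[, s] <- predict(train_bagged(spec, Xtr, ytr, n_bags = 5,
                                        seed = s), Xte)
  }
  var_single <- mean(apply(single, 1, var))
  var_bagged <- mean(apply(bagged, 1, var))
  expect_lte(var_bagged, var_single)
})

test_that("the SMILES sequence model learns a planted activity motif", {
  cfg <- synthetic_assay_config(400, imbalance_ratio = 2, label_noise = 0.05,
                                seed = 11)
  ds <- generate_synthetic_assay(cfg)
  plan <- split_train_test(ds, seed = 5)
  vocab <- build_vocabulary(ds$smiles[plan$train_indices])
  X <- encode_smiles_set(ds$smiles, vocab)
  spec <- default_spec("CNN_GRU", "SMILES", seed = 3)
  # desk-scale geometry: fewer filters and milder dropout keep 30 epochs
  # sufficient on a few hundred compounds
  spec$hyperparams <- utils::modifyList(
    spec$hyperparams,
    list(epochs = 30L, n_filters = 96L,
         dropout = c(conv = 0.5, gru = 0.3, dense = 0.3)))
  m <- train_base(spec, X[plan$train_indices, , ], ds$label[plan$train_indices])
  p <- predict(m, X[plan$test_indices, , ])
  expect_gt(roc_auc(ds$label[plan$test_indices], p), 0.9)
  expect_true(all(p >= 0 & p <= 1))
})
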