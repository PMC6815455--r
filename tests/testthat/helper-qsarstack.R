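# Shared fixtures and oracles, built in code at test time.

# tiny deterministic bioassay table on disk
write_assay_csv <- function(path, rows) {
  writeLines(c("cid,smiles,outcome", rows), path)
  path
}

# random binary "fingerprint" features carrying a representation tag;
# avoids the chemistry toolkit where the test only exercises learning code
fake_fingerprints <- function(n, d = 24, representation = "MACCS", seed = 1) {
  X <- qsarstack:::with_seed(seed, matrix(rbinom(n * d, 1, 0.3), n, d))
  attr(X, "representation") <- representation
  X
}

# labels linearly separable from the first two feature columns
separable_labels <- function(X) as.integer(X[, 1] + X[, 2] >= 1)

# exhaustive pairwise-concordance AUC: the independent oracle roc_auc is
# checked against (ties scored 1/2)
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# hand-constructed split plan (all rows in training) for fold-level checks
manual_plan <- function(folds) {
  n <- length(folds)
  structure(list(train_indices = seq_len(n), test_indices = integer(0),
                 fold_assignment = stats::setNames(folds, seq_len(n)),
                 k = max(folds), seed = 1L, assay_id = "manual"),
            class = "split_plan")
}

# cheap deterministic learner spec for structural (non-accuracy) tests
cheap_spec <- function(representation = "MACCS", seed = 1)
  learner_spec("GBM", representation, hyperparams = list(nrounds = 3L),
               seed = seed)
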