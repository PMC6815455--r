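## Synthetic bioassays: desk-scale datasets with the statistical structure
## the ensemble assumes — parseable SMILES assembled from chemically valid
## building-block fragments, activity planted through motif fragments, and
## configurable class imbalance. The fragments exist to exercise the code
## paths (featurization, learning, stacking); no pharmacological realism is
## claimed.

#' Default fragment alphabet
#'
#' Small alkyl, aromatic and heteroatom fragments whose concatenation in any
#' order remains a parseable SMILES string (ring closures are balanced
#' within each fragment and no fragment starts with a bond symbol).
#'
#' @return Character vector of SMILES fragments.
#' @export
default_fragment_alphabet <- function() {
  path <- system.file("extdata", "fragment_alphabet.tsv",
                      package = "qsarstack", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)$fragment
}

#' Configuration for a synthetic bioassay
#'
#' @param n_compounds Number of compounds.
#' @param imbalance_ratio Majority:minority ratio (>= 1); actives are the
#'   minority class, matching typical screens. Default 2, the benchmark
#'   panel's average.
#' @param motif_fragments SMILES fragments whose presence determines
#'   activity (default the amide fragment `"C(=O)N"`).
#' @param label_noise Probability of independently flipping each label
#'   (default 0, must be `< 0.5`).
#' @param fragment_alphabet Building-block fragments
#'   (default [default_fragment_alphabet()]).
#' @param seed Integer seed.
#' @return A `synthetic_assay_config`.
#' @export
synthetic_assay_config <- function(n_compounds, imbalance_ratio = 2,
                                   motif_fragments = "C(=O)N",
                                   label_noise = 0,
                                   fragment_alphabet = default_fragment_alphabet(),
                                   seed = 1) {
  if (imbalance_ratio < 1)
    stop_qsar("imbalance_ratio must be >= 1", class = "qsar_config_error")
  if (label_noise < 0 || label_noise >= 0.5)
    stop_qsar("label_noise must be in [0, 0.5)", class = "qsar_config_error")
  if (!length(setdiff(fragment_alphabet, motif_fragments)))
    stop_qsar("alphabet must contain non-motif fragments",
              class = "qsar_config_error")
  structure(list(n_compounds = as.integer(n_compounds),
                 imbalance_ratio = imbalance_ratio,
                 motif_fragments = motif_fragments,
                 label_noise = label_noise,
                 fragment_alphabet = fragment_alphabet,
                 seed = as.integer(seed)),
            class = "synthetic_assay_config")
}

#' Generate a synthetic bioassay
#'
#' Each compound is assembled by concatenating 3-8 building-block fragments.
#' Active compounds (the minority class, sized to hit the requested
#' imbalance ratio) contain at least one motif fragment; inactive compounds
#' contain none. After assembly each label is flipped independently with
#' probability `label_noise`. Deterministic given the config seed.
#'
#' @param cfg A [synthetic_assay_config()].
#' @return A [bioassay_dataset()] with assay id `"synthetic-<seed>"`.
#' @export
generate_synthetic_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_assay_config"))
  n <- cfg$n_compounds
  n_active <- round(n / (1 + cfg$imbalance_ratio))
  if (n_active < 1 || n - n_active < 1)
    stop_qsar("imbalance ratio %.2f unreachable with n=%d",
              cfg$imbalance_ratio, n, class = "qsar_generation_error")
  plain <- setdiff(cfg$fragment_alphabet, cfg$motif_fragments)
  with_seed(cfg$seed, {
    labels <- c(rep(1L, n_active), rep(0L, n - n_active))
    labels <- sample(labels)
    smiles <- character(n)
    for (i in seq_len(n)) {
      k <- sample(3:8, 1)
      frags <- sample(plain, k, replace = TRUE)
      if (labels[i] == 1) {
        pos <- sample(k, 1)
        frags[pos] <- sample(cfg$motif_fragments, 1)
      }
      smiles[i] <- paste(frags, collapse = "")
    }
    observed <- labels
    if (cfg$label_noise > 0) {
      flip <- stats::rbinom(n, 1, cfg$label_noise) == 1
      observed[flip] <- 1L - observed[flip]
    }
    ds <- bioassay_dataset(sprintf("SYN%05d", seq_len(n)), smiles, observed,
                          assay_id = paste0("synthetic-", cfg$seed))
    attr(ds, "true_label") <- labels
    ds
  })
}

#' Synthetic first-level probability columns for meta-learner tests
#'
#' Builds a harness for the second-level learner: one "oracle" column that
#' blends the labels with uniform noise (`oracle_strength` of the label,
#' `1 - oracle_strength` of the noise) and `n_noise` pure-noise columns.
#' Used to check that meta-learning and the importance interpretation
#' recover the informative model.
#'
#' @param n Number of rows (>= 10).
#' @param oracle_strength Label weight in the oracle column, in `[0, 1]`.
#' @param n_noise Number of uninformative uniform columns.
#' @param seed Integer seed.
#' @return List with `labels` (0/1 vector) and `P` (`n x (1 + n_noise)`
#'   matrix; the oracle is column 1, named `"oracle"`).
#' @export
generate_probability_columns <- function(n, oracle_strength, n_noise,
                                         seed = 1) {
  if (n < 10) stop_qsar("n must be >= 10", class = "qsar_config_error")
  stopifnot(oracle_strength >= 0, oracle_strength <= 1)
  with_seed(seed, {
    y <- stats::rbinom(n, 1, 0.5)
    # guarantee both classes so downstream fits are well-posed
    if (length(unique(y)) < 2) { y[1] <- 0L; y[2] <- 1L }
    oracle <- oracle_strength * y + (1 - oracle_strength) * stats::runif(n)
    P <- cbind(oracle, matrix(stats::runif(n * n_noise), n, n_noise))
    colnames(P) <- c("oracle", paste0("noise", seq_len(n_noise)))
    list(labels = y, P = P)
  })
}
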