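## Bioassay datasets: construction, IO, cleaning, splitting.

#' Construct a bioassay dataset
#'
#' A `bioassay_dataset` holds one row per screened compound: an opaque
#' compound identifier, its SMILES string, and a binary activity outcome
#' (1 = active, 0 = inactive; active is the positive class throughout the
#' package).
#'
#' @param compound_id Character vector of compound identifiers.
#' @param smiles Character vector of SMILES strings (non-empty).
#' @param label Integer/numeric vector of 0/1 outcomes.
#' @param assay_id Single string naming the assay.
#' @return An object of class `bioassay_dataset` (a data.frame with columns
#'   `compound_id`, `smiles`, `label` and an `assay_id` attribute).
#' @export
bioassay_dataset <- function(compound_id, smiles, label, assay_id = "assay") {
  compound_id <- as.character(compound_id)
  smiles <- as.character(smiles)
  if (length(compound_id) != length(smiles) || length(smiles) != length(label))
    stop_qsar("compound_id, smiles and label must have equal length",
              class = "qsar_format_error")
  if (any(!nzchar(smiles)))
    stop_qsar("empty SMILES at row %d", which(!nzchar(smiles))[1],
              class = "qsar_format_error")
  if (!all(label %in% c(0, 1)))
    stop_qsar("labels must be 0/1; offending value '%s'",
              as.character(label[!label %in% c(0, 1)][1]),
              class = "qsar_format_error")
  ds <- data.frame(compound_id = compound_id, smiles = smiles,
                   label = as.integer(label), stringsAsFactors = FALSE)
  attr(ds, "assay_id") <- as.character(assay_id)
  class(ds) <- c("bioassay_dataset", "data.frame")
  ds
}

#' @export
print.bioassay_dataset <- function(x, ...) {
  cat(sprintf("<bioassay_dataset '%s': %d compounds, %d active / %d inactive>\n",
              assay_id(x), nrow(x), sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

#' Assay identifier of a dataset
#' @param ds A `bioassay_dataset`.
#' @return The assay id string.
#' @export
assay_id <- function(ds) attr(ds, "assay_id") %||% "assay"

#' Read a bioassay table from CSV/TSV
#'
#' Expects a header row with columns for the compound id, the SMILES string
#' and the activity outcome (names configurable). Outcomes may be coded
#' `Active`/`Inactive` (case-insensitive) or `1`/`0`.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @param columns Named character vector mapping roles to column names;
#'   defaults to `c(id = "cid", smiles = "smiles", outcome = "outcome")`.
#' @param assay_id Assay identifier; defaults to the file stem.
#' @return A [bioassay_dataset()].
#' @export
read_bioassay <- function(path, format = c("csv", "tsv"),
                          columns = c(id = "cid", smiles = "smiles",
                                      outcome = "outcome"),
                          assay_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_qsar("file not found: %s", path, class = "qsar_format_error")
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", check.names = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop_qsar("missing column(s): %s", paste(missing, collapse = ", "),
              class = "qsar_format_error")
  outcome <- df[[columns[["outcome"]]]]
  lab <- map_outcome(outcome)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop_qsar("unmappable outcome value '%s' at data row %d",
              as.character(outcome[bad]), bad, class = "qsar_parse_error")
  }
  bioassay_dataset(df[[columns[["id"]]]], df[[columns[["smiles"]]]], lab,
                   assay_id = assay_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @noRd
map_outcome <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[tolower(x) == "active" | x == "1"] <- 1L
  out[tolower(x) == "inactive" | x == "0"] <- 0L
  out
}

#' Deduplicate compounds and drop label-inconsistent ones
#'
#' Each compound id is kept only once (its first occurrence); any compound
#' observed with both an active and an inactive outcome is removed entirely.
#' Relative order of the survivors is preserved, and the operation is
#' idempotent.
#'
#' @param ds A `bioassay_dataset`.
#' @return The cleaned `bioassay_dataset` (possibly empty).
#' @export
deduplicate_bioassay <- function(ds) {
  labsets <- tapply(ds$label, ds$compound_id, function(v) length(unique(v)))
  inconsistent <- names(labsets)[labsets > 1]
  keep <- !duplicated(ds$compound_id) & !(ds$compound_id %in% inconsistent)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assay_id") <- assay_id(ds)
  class(out) <- class(ds)
  out
}

#' Class imbalance ratio
#'
#' Majority-class count over minority-class count, as used to describe
#' bioassay panels (e.g. 2,601 active / 10,826 inactive is a 1:4.2 assay).
#'
#' @param ds A `bioassay_dataset` containing both classes.
#' @return A real number >= 1.
#' @export
imbalance_ratio <- function(ds) {
  n1 <- sum(ds$label == 1); n0 <- sum(ds$label == 0)
  if (n1 == 0 || n0 == 0)
    stop_qsar("imbalance ratio undefined: dataset has a single class",
              class = "qsar_single_class_error")
  max(n1, n0) / min(n1, n0)
}

## Splits --------------------------------------------------------------------

#' Random train/test split with cross-validation folds
#'
#' Draws the experimental protocol's random partition: `train_fraction` of
#' the compounds form the training set (the rest are held out for testing),
#' and the training set is partitioned uniformly at random into `k` folds of
#' sizes differing by at most one. The random stream is seeded from
#' `(seed, assay_id)` so different assays receive independent randomness
#' under one master seed.
#'
#' @param ds A `bioassay_dataset`.
#' @param train_fraction Fraction of compounds used for training (default 0.75).
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer master seed.
#' @param stratify If `TRUE`, the train/test draw preserves class proportions.
#'   Default `FALSE` (a plain uniform draw, matching a protocol that states
#'   only "randomly divided").
#' @return A `split_plan`: list with `train_indices`, `test_indices`,
#'   `fold_assignment` (named integer vector over the training indices),
#'   `k`, and `seed`.
#' @export
split_train_test <- function(ds, train_fraction = 0.75, k = 5, seed = 1,
                             stratify = FALSE) {
  n <- nrow(ds)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_qsar("train_fraction must be in (0,1)", class = "qsar_format_error")
  if (k < 2) stop_qsar("k must be >= 2", class = "qsar_format_error")
  n_train <- round(train_fraction * n)
  if (n < k || n_train < k)
    stop_qsar("dataset too small for %d folds (n=%d)", k, n,
              class = "qsar_format_error")
  stream <- derive_seed(seed, assay_id(ds), "split")
  plan <- with_seed(stream, {
    if (stratify) {
      idx1 <- which(ds$label == 1); idx0 <- which(ds$label == 0)
      t1 <- round(train_fraction * length(idx1))
      t1 <- min(max(t1, n_train - length(idx0)), length(idx1), n_train)
      train <- c(sample(idx1, t1), sample(idx0, n_train - t1))
      train <- sample(train)           # shuffle class blocks together
    } else {
      train <- sample(n, n_train)
    }
    folds <- sort(rep(seq_len(k), length.out = n_train))
    fold_assignment <- stats::setNames(folds, train)  # train already random order
    list(train_indices = sort(train),
         test_indices = setdiff(seq_len(n), train),
         fold_assignment = fold_assignment,
         k = as.integer(k), seed = as.integer(seed),
         assay_id = assay_id(ds))
  })
  class(plan) <- "split_plan"
  plan
}

#' Fold of each training index
#' @param plan A `split_plan`.
#' @param indices Original dataset indices (must be training indices).
#' @return Integer fold labels.
#' @export
fold_of <- function(plan, indices) {
  out <- plan$fold_assignment[as.character(indices)]
  if (anyNA(out)) stop_qsar("index not in the training set",
                            class = "qsar_format_error")
  unname(out)
}

#' Serialize / restore a split plan
#'
#' The JSON sidecar records indices, the fold map and the seed so a run can
#' be reproduced exactly.
#' @param plan A `split_plan`.
#' @param path Output / input file path.
#' @return `read_split_plan` returns the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(train_indices = plan$train_indices, test_indices = plan$test_indices,
         fold_assignment = as.list(plan$fold_assignment), k = plan$k,
         seed = plan$seed, assay_id = plan$assay_id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- list(train_indices = as.integer(x$train_indices),
               test_indices = as.integer(x$test_indices),
               fold_assignment = stats::setNames(
                 as.integer(unlist(x$fold_assignment)), names(x$fold_assignment)),
               k = as.integer(x$k), seed = as.integer(x$seed),
               assay_id = x$assay_id)
  class(plan) <- "split_plan"
  plan
}

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by their Bemis-Murcko scaffold (ring systems plus
#' linkers; see [murcko_scaffold()]) and assigns whole groups to subsets so
#' that structurally related molecules never straddle a boundary. Groups are
#' assigned largest-first: a group goes to the training set while it fits
#' under the training cutoff, then to validation, then to test — the
#' benchmark convention for scaffold splitting.
#'
#' @param ds A `bioassay_dataset`.
#' @param fractions Length-3 numeric of train/valid/test fractions
#'   (default `c(0.8, 0.1, 0.1)`).
#' @return List with integer index vectors `train`, `valid`, `test`, the
#'   scaffold `groups` map, and `n_excluded` (unparseable SMILES, dropped
#'   with a warning).
#' @export
scaffold_split <- function(ds, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  keys <- vapply(ds$smiles, function(s) {
    tryCatch(murcko_scaffold(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  bad <- which(is.na(keys))
  if (length(bad))
    warning(sprintf("%d unparseable SMILES excluded from scaffold split",
                    length(bad)))
  ok <- setdiff(seq_len(nrow(ds)), bad)
  groups <- split(ok, keys[ok])
  sizes <- vapply(groups, length, integer(1))
  # largest first; ties broken by scaffold key for determinism
  ord <- order(-sizes, names(groups))
  n <- length(ok)
  cut_train <- fractions[1] * n
  cut_valid <- fractions[2] * n
  train <- integer(0); valid <- integer(0); test <- integer(0)
  # greedy fill: a group goes to train while train is below its target,
  # then to valid, then to test; an oversized group may overflow its subset
  # (groups are indivisible).
  for (g in groups[ord]) {
    if (length(train) < cut_train - 1e-9) train <- c(train, g)
    else if (length(valid) < cut_valid - 1e-9) valid <- c(valid, g)
    else test <- c(test, g)
  }
  list(train = sort(train), valid = sort(valid), test = sort(test),
       groups = groups, n_excluded = length(bad))
}
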