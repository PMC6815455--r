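## Molecular fingerprints: ECFP (hashed circular environments), MACCS
## structure keys, and the 881-bit PubChem keys (accepted as precomputed
## input only — their generation algorithm lives in the PubChem service).

.fp_lengths <- c(PUBCHEM = 881L, MACCS = 166L)

#' Fingerprint length for a family
#' @param family `"PUBCHEM"`, `"ECFP"` or `"MACCS"`.
#' @param nbits ECFP folded width (default 2048).
#' @return Integer vector length.
#' @export
fingerprint_length <- function(family, nbits = 2048) {
  family <- match.arg(family, c("PUBCHEM", "ECFP", "MACCS"))
  if (family == "ECFP") as.integer(nbits) else .fp_lengths[[family]]
}

.pubchem_registry <- new.env(parent = emptyenv())

#' Register precomputed PubChem fingerprints
#'
#' The 881-bit PubChem substructure fingerprint is generated by the PubChem
#' service; this package consumes it as precomputed input. Register a named
#' character vector (or a TSV file `compound_id<TAB>bitstring`) mapping
#' compound ids to 881-character 0/1 strings.
#'
#' @param x Named character vector of bit-strings, or a file path.
#' @return Invisibly, the number of registered compounds.
#' @export
register_pubchem_fingerprints <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    x <- stats::setNames(df[[2]], df[[1]])
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_qsar("PubChem bit-strings must be named by compound id",
              class = "qsar_config_error")
  bad <- which(nchar(x) != 881 | grepl("[^01]", x))
  if (length(bad))
    stop_qsar("entry '%s' is not an 881-character 0/1 string", names(x)[bad[1]],
              class = "qsar_config_error")
  for (nm in names(x)) assign(nm, x[[nm]], envir = .pubchem_registry)
  invisible(length(x))
}

#' Clear the PubChem fingerprint registry
#' @export
clear_pubchem_registry <- function() {
  rm(list = ls(.pubchem_registry), envir = .pubchem_registry)
  invisible(NULL)
}

#' Compute a molecular fingerprint
#'
#' ECFP (radius 2, i.e. diameter-4 circular environments, hashed and folded
#' to `nbits`) and MACCS (166 structure keys) are computed from the SMILES
#' string with OpenBabel. `PUBCHEM` fingerprints are looked up in the
#' registry (see [register_pubchem_fingerprints()]); pass the compound id as
#' `key`.
#'
#' @param smiles A single SMILES string (ignored for `PUBCHEM`).
#' @param family `"ECFP"`, `"MACCS"` or `"PUBCHEM"`.
#' @param nbits,radius ECFP parameters (defaults 2048 bits, radius 2).
#' @param key Registry key for `PUBCHEM` (defaults to `smiles`).
#' @return Integer 0/1 vector of the family's fixed length.
#' @export
compute_fingerprint <- function(smiles, family = c("ECFP", "MACCS", "PUBCHEM"),
                                nbits = 2048, radius = 2, key = smiles) {
  family <- match.arg(family)
  if (family == "PUBCHEM") {
    if (!exists(key, envir = .pubchem_registry))
      stop_qsar(paste0("no PubChem fingerprint registered for '%s'; ",
                       "register a precomputed source first"), key,
                class = "qsar_config_error")
    return(as.integer(strsplit(get(key, envir = .pubchem_registry), "")[[1]]))
  }
  compute_fingerprint_matrix(smiles, family, nbits = nbits, radius = radius)[1, ]
}

#' Fingerprints for a vector of SMILES
#'
#' Vectorized form of [compute_fingerprint()] for the structure-derived
#' families. The `"rdkit"` backend shells out to the RDKit python toolkit and
#' is roughly two orders of magnitude faster for ECFP; use it for large
#' simulated screens. Both backends produce valid fingerprints of the same
#' family but their bit assignments differ (different hash functions), so do
#' not mix backends within one model.
#'
#' @param smiles Character vector of SMILES.
#' @param family `"ECFP"` or `"MACCS"`.
#' @param nbits,radius ECFP parameters.
#' @param backend `"chemmineob"` (default) or `"rdkit"`.
#' @return Integer 0/1 matrix, one row per molecule.
#' @export
compute_fingerprint_matrix <- function(smiles, family = c("ECFP", "MACCS"),
                                       nbits = 2048, radius = 2,
                                       backend = c("chemmineob", "rdkit")) {
  family <- match.arg(family)
  backend <- match.arg(backend)
  if (any(!nzchar(trimws(smiles))))
    stop_qsar("empty SMILES at position %d",
              which(!nzchar(trimws(smiles)))[1],
              class = "qsar_featurize_error")
  if (backend == "rdkit")
    return(rdkit_fingerprints(smiles, family, nbits, radius))
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, collapse = "\n"),
                           identity),
    error = function(e) stop_qsar("unparseable SMILES in input: %s",
                                  conditionMessage(e),
                                  class = "qsar_featurize_error"))
  if (length(mols) != length(smiles))
    stop_qsar("OpenBabel parsed %d of %d SMILES", length(mols),
              length(smiles), class = "qsar_featurize_error")
  if (family == "MACCS") {
    fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
    if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1)
    out <- fp[, seq_len(166), drop = FALSE]
  } else {
    ob_name <- paste0("ECFP", 2 * radius)
    fp <- ChemmineOB::fingerprint_OB(mols, ob_name)
    out <- fold_fingerprint(fp, nbits)
  }
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Fold a fingerprint matrix to a smaller width by OR-ing blocks
#' @noRd
fold_fingerprint <- function(fp, nbits) {
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1)
  w <- ncol(fp)
  if (w == nbits) return(fp)
  if (w %% nbits != 0)
    stop_qsar("cannot fold width %d to %d bits", w, nbits,
              class = "qsar_config_error")
  out <- matrix(0L, nrow(fp), nbits)
  for (b in seq_len(w / nbits)) {
    blk <- fp[, ((b - 1) * nbits + 1):(b * nbits), drop = FALSE]
    out <- pmax(out, blk)
  }
  storage.mode(out) <- "integer"
  out
}

#' @noRd
rdkit_fingerprints <- function(smiles, family, nbits, radius) {
  infile <- tempfile(fileext = ".smi"); outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)))
  writeLines(smiles, infile)
  script <- sprintf(
    "import sys
from rdkit import Chem, RDLogger
RDLogger.DisableLog('rdApp.*')
from rdkit.Chem import rdFingerprintGenerator, MACCSkeys
smis = open(%s).read().splitlines()
fam, nbits, radius = %s, %d, %d
gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
with open(%s, 'w') as out:
    for i, s in enumerate(smis):
        m = Chem.MolFromSmiles(s)
        if m is None:
            sys.stderr.write('PARSEFAIL %%d\\n' %% (i + 1)); sys.exit(3)
        fp = gen.GetFingerprint(m) if fam == 'ECFP' else MACCSkeys.GenMACCSKeys(m)
        bits = fp.ToBitString()
        out.write((bits if fam == 'ECFP' else bits[1:]) + '\\n')
",
    deparse(infile), deparse(family), as.integer(nbits), as.integer(radius),
    deparse(outfile))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  status <- attr(res, "status") %||% 0
  if (status != 0)
    stop_qsar("rdkit backend failed: %s", paste(res, collapse = " "),
              class = "qsar_featurize_error")
  lines <- readLines(outfile)
  out <- matrix(0L, length(lines),
                if (family == "ECFP") nbits else 166L)
  for (i in seq_along(lines))
    out[i, ] <- as.integer(strsplit(lines[i], "")[[1]])
  out
}

#' Featurize a whole dataset under one representation
#'
#' @param ds A [bioassay_dataset()].
#' @param representation `"ECFP"`, `"MACCS"`, `"PUBCHEM"` or `"SMILES"`.
#' @param vocab For `"SMILES"`, an optional [build_vocabulary()] result; by
#'   default the vocabulary is built from `ds` itself.
#' @param max_len One-hot grid length for `"SMILES"` (default 100).
#' @param ... Passed to [compute_fingerprint_matrix()] (`nbits`, `radius`,
#'   `backend`).
#' @return For fingerprints, an integer matrix with attribute
#'   `representation`; for SMILES, a `smiles_tensor` (see
#'   [encode_smiles_set()]).
#' @export
featurize_dataset <- function(ds, representation, vocab = NULL, max_len = 100,
                              ...) {
  representation <- match.arg(representation,
                              c("ECFP", "MACCS", "PUBCHEM", "SMILES"))
  if (representation == "SMILES") {
    if (is.null(vocab)) vocab <- build_vocabulary(ds$smiles)
    return(encode_smiles_set(ds$smiles, vocab, max_len = max_len))
  }
  if (representation == "PUBCHEM") {
    X <- t(vapply(ds$compound_id,
                  function(id) compute_fingerprint("", "PUBCHEM", key = id),
                  integer(881)))
    rownames(X) <- NULL
  } else {
    X <- compute_fingerprint_matrix(ds$smiles, representation, ...)
  }
  attr(X, "representation") <- representation
  X
}
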