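## Character-level one-hot encoding of SMILES strings for the sequence model.
## Tokenization is strictly single-character, so two-letter element symbols
## (Cl, Br) occupy two positions; the encoder reserves one trailing channel
## (OTHERS) for every character outside the kept set.

#' Build a character vocabulary from a SMILES corpus
#'
#' Keeps the `max_chars` most frequent single characters over the corpus
#' (fewer if the corpus has fewer distinct characters); every other character
#' maps to a shared OTHERS channel, so the encoding dimension is
#' `length(kept) + 1`. Frequency ties are broken lexicographically for
#' determinism.
#'
#' @param corpus Character vector of SMILES strings.
#' @param max_chars Maximum number of kept characters (default 9, giving an
#'   encoding dimension of at most 10).
#' @return A `char_vocabulary`: list with `kept_chars` (ordered by
#'   decreasing frequency) and `total_dim`.
#' @export
build_vocabulary <- function(corpus, max_chars = 9) {
  if (length(corpus) == 0 || all(!nzchar(corpus)))
    stop_qsar("empty corpus", class = "qsar_format_error")
  chars <- unlist(strsplit(corpus, ""), use.names = FALSE)
  tab <- table(chars)
  ord <- order(-as.integer(tab), names(tab))
  kept <- names(tab)[ord][seq_len(min(max_chars, length(tab)))]
  if (max_chars == 0) kept <- character(0)
  vocab <- list(kept_chars = kept, total_dim = length(kept) + 1L)
  class(vocab) <- "char_vocabulary"
  vocab
}

#' @export
print.char_vocabulary <- function(x, ...) {
  cat(sprintf("<char_vocabulary: [%s] + OTHERS (dim %d)>\n",
              paste(x$kept_chars, collapse = ""), x$total_dim))
  invisible(x)
}

#' Serialize / restore a vocabulary as JSON
#' @param vocab A `char_vocabulary`.
#' @param path File path.
#' @return `read_vocabulary` returns the restored vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(kept_chars = vocab$kept_chars), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kept <- as.character(x$kept_chars)
  vocab <- list(kept_chars = kept, total_dim = length(kept) + 1L)
  class(vocab) <- "char_vocabulary"
  vocab
}

#' One-hot encode a SMILES string
#'
#' Produces a `max_len x total_dim` binary grid: position `t` carries a 1 in
#' the channel of character `t` (or in the OTHERS channel when the character
#' is not in the vocabulary). Strings longer than `max_len` keep their first
#' `max_len` characters (the head carries the canonical SMILES root);
#' shorter strings are zero-padded at the tail.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [build_vocabulary()] result.
#' @param max_len Grid length (default 100).
#' @return A `smiles_onehot` matrix with attribute `effective_length`.
#' @export
encode_smiles <- function(smiles, vocab, max_len = 100) {
  stopifnot(inherits(vocab, "char_vocabulary"), length(smiles) == 1)
  chars <- strsplit(smiles, "")[[1]]
  eff <- min(length(chars), max_len)
  grid <- matrix(0L, max_len, vocab$total_dim,
                 dimnames = list(NULL, c(vocab$kept_chars, "OTHERS")))
  if (eff > 0) {
    idx <- match(chars[seq_len(eff)], vocab$kept_chars)
    idx[is.na(idx)] <- vocab$total_dim          # OTHERS is always last
    grid[cbind(seq_len(eff), idx)] <- 1L
  }
  attr(grid, "effective_length") <- eff
  class(grid) <- c("smiles_onehot", class(grid))
  grid
}

#' Decode a one-hot grid back to a string
#'
#' Inverse of [encode_smiles()] over the kept characters; OTHERS positions
#' decode to `"?"`. Round-trips exactly for strings containing only kept
#' characters and length at most `max_len`.
#'
#' @param grid A `smiles_onehot` grid.
#' @param vocab The vocabulary used to encode it.
#' @return The decoded string.
#' @export
decode_smiles <- function(grid, vocab) {
  eff <- attr(grid, "effective_length")
  if (eff == 0) return("")
  symbols <- c(vocab$kept_chars, "?")
  idx <- apply(grid[seq_len(eff), , drop = FALSE], 1, which.max)
  paste(symbols[idx], collapse = "")
}

#' One-hot encode a set of SMILES strings
#'
#' @param smiles Character vector.
#' @inheritParams encode_smiles
#' @return A `smiles_tensor`: numeric array `n x max_len x total_dim` with
#'   attributes `vocab`, `effective_lengths` and `representation = "SMILES"`.
#' @export
encode_smiles_set <- function(smiles, vocab, max_len = 100) {
  n <- length(smiles)
  X <- array(0, dim = c(n, max_len, vocab$total_dim))
  eff <- integer(n)
  for (i in seq_len(n)) {
    g <- encode_smiles(smiles[i], vocab, max_len)
    X[i, , ] <- unclass(g)
    eff[i] <- attr(g, "effective_length")
  }
  attr(X, "vocab") <- vocab
  attr(X, "effective_lengths") <- eff
  attr(X, "representation") <- "SMILES"
  class(X) <- c("smiles_tensor", class(X))
  X
}

#' @export
`[.smiles_tensor` <- function(x, i, ...) {
  out <- unclass(x)[i, , , drop = FALSE]
  attr(out, "vocab") <- attr(x, "vocab")
  attr(out, "effective_lengths") <- attr(x, "effective_lengths")[i]
  attr(out, "representation") <- "SMILES"
  class(out) <- c("smiles_tensor", class(out))
  out
}
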