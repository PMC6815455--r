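#' @keywords internal
"_PACKAGE"

## Seed plumbing -------------------------------------------------------------

#' Derive a child seed from a master seed and a tag
#'
#' All randomness in the package fans out from one master seed through this
#' counter scheme, so that different stages (splits, folds, learners, repeats)
#' draw from independent, reproducible streams. The tag is hashed with a
#' 31-multiplier polynomial rolling hash modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param ... Character/numeric tag components identifying the stream.
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                      character(1)), collapse = "::")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Misc ---------------------------------------------------------------------

#' Round half away from zero at a fixed number of decimals
#'
#' Published tables round 0.0005 up; R's `round()` rounds to even. Used when
#' recomputing printed column means.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_qsar <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "qsarstack_error")))
}
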