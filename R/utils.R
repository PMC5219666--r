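#' @keywords internal
"_PACKAGE"

# Genotype codes used throughout: integer 0 = aa, 1 = ab, 2 = bb, NA = missing.
GENO_CODES <- c("aa", "ab", "bb")
MISSING_CODE <- "--"

#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used when reporting percentages and
#' map distances: 0.975 rounds to 0.98, unlike [round()] which rounds to
#' even.  A tiny epsilon absorbs binary floating-point representation error
#' (e.g. a sum that is 0.97499999999 when 0.975 was meant).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.975, 2)   # 0.98
#' round_half_up(12.003, 1)  # 12.0
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Convert between integer genotype codes and text codes
#'
#' Integer codes are 0 (aa), 1 (ab), 2 (bb) and NA (missing); text codes are
#' `"aa"`, `"ab"`, `"bb"` and `"--"`.
#'
#' @param g integer matrix/vector of genotypes in 0/1/2/NA coding.
#' @return character object of the same shape.
#' @export
geno_to_char <- function(g) {
  out <- ifelse(is.na(g), MISSING_CODE, GENO_CODES[g + 1L])
  if (is.matrix(g)) out <- matrix(out, nrow(g), ncol(g), dimnames = dimnames(g))
  out
}

#' @rdname geno_to_char
#' @param ch character genotypes (`"aa"`, `"ab"`, `"bb"`, `"--"` or NA).
#' @export
char_to_geno <- function(ch) {
  out <- match(ch, GENO_CODES) - 1L
  if (is.matrix(ch)) out <- matrix(out, nrow(ch), ncol(ch), dimnames = dimnames(ch))
  out
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

stop_if_not_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}
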