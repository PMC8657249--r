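#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG state seeded at `seed`; the caller's RNG stream is
# untouched. All exported stochastic operations route their randomness through
# this so a pipeline run is reproducible from a single integer.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside the
# 32-bit signed range R requires of set.seed().
child_seed <- function(seed, stream) {
  # double arithmetic: products overflow 32-bit ints long before doubles
  # lose integer precision at this magnitude
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (0.7605 -> 0.761 at three
#' decimals), the convention used when reporting the test-set metric table.
#' Base R's `round()` rounds half to even and would give 0.760.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up((0.738 + 0.783) / 2, 3) # 0.761
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
}
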