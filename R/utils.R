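#' Round half away from zero
#'
#' Deterministic half-up rounding used for all reported figures. Base
#' [round()] rounds half to even, which does not match how costing tables
#' are conventionally presented.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2)  # 2.68, not 2.67
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # tiny nudge guards against values like 2.675 stored just below the half
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate with a local RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state so package functions never perturb user-level randomness.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Deterministic string hash
#'
#' 31-base polynomial rolling hash modulo 2^31 - 1, used to derive
#' independent, stable random streams per cost category from one root seed:
#' adding a category never perturbs another category's draws.
#'
#' @param s Character scalar.
#' @return Integer in [0, 2^31 - 2].
#' @keywords internal
string_hash <- function(s) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  as.integer(h)
}
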