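# Internal helpers shared across modules.

# Deterministic sub-seed for a named generator stream. Streams are decoupled
# so that adding a draw to one generator does not shift any other stream.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009L)
  (as.integer(seed) * 48271L + h) %% 2147483399L
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}

#' Round half away from zero
#'
#' The rounding convention used for reported percentages and ratios
#' (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return `x` rounded half-up to `digits`.
#' @examples
#' round_half_up(85.65)  # 85.7
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample() that never interprets a length-1 numeric vector as 1:n
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
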