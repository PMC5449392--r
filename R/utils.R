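# Internal helpers shared across modules.

# round `x` to `digits` decimals, half-up or truncating toward zero.
# Plain round() is banker's rounding; half-up is what printed precision
# tables use. A tiny relative nudge absorbs binary representation error
# (e.g. 100*28/91 stored fractionally below 30.769...5).
round_mode <- function(x, digits = 2, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  scaled <- x * 10^digits * (1 + 8 * .Machine$double.eps)
  if (mode == "half_up") {
    floor(scaled + 0.5) / 10^digits
  } else {
    trunc(scaled) / 10^digits
  }
}

assert_fraction <- function(x, name = deparse(substitute(x)), closed_zero = FALSE) {
  lo_ok <- if (closed_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a single value in %s0, 1]",
                  name, if (closed_zero) "[" else "("))
  }
  invisible(x)
}

assert_genes <- function(x, name = deparse(substitute(x))) {
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    abort(sprintf("`%s` must be a character vector of non-empty gene identifiers", name))
  }
  invisible(x)
}

# half-up rounding for list sizes: round(f * n) with deterministic .5 handling
size_round <- function(x) floor(x + 0.5)

# sample() that never falls into the scalar-x trap
resample <- function(x, k) x[sample.int(length(x), k)]
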