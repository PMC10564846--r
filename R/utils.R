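# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals. Display values in the
# station tables use this convention; base round() would round half to even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-stage seed derivation from one global seed, so stages can
# be re-run in isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  idx <- sum(utf8ToInt(stage))
  as.integer((abs(seed) * 1009 + idx * 9176) %% 2147483647L)
}

assert_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a fraction in %s0, 1].", name,
                  if (allow_zero) "[" else "("))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
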