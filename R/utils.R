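# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage offset.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Percentile with the linear-interpolation convention used throughout the
# package (stats::quantile type 7), on valid (finite) values only.
pctl <- function(x, q) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no valid values for percentile", call. = FALSE)
  stats::quantile(x, probs = q / 100, type = 7, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
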