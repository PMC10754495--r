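# Internal helpers shared across modules.

variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic fan-out of one user seed into per-stage seeds (< 2^31),
# so pipeline stages are independently reproducible.
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (as.numeric(seed) %% m) * 2654435) %% m)
}

# set.seed only when a seed was supplied; NULL leaves the RNG stream alone.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

assert_scalar_prob <- function(x, name, lo = 0, hi = 1,
                               lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}
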