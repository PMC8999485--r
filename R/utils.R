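# internal helpers shared across modules

# Derive a reproducible child seed from a parent seed and a stage label, so
# pipeline stages are independently re-runnable. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; if `seed` is
# NULL the global RNG stream is used as-is.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Truncated normal draw by resampling (ranges here are wide relative to sd,
# so rejection is cheap); falls back to clamping after 100 attempts.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(100L)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
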