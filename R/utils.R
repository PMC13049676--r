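# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (NULL = use the current stream). Restores the caller's RNG afterwards.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw from a normal truncated to (lo, hi) by inverse-CDF sampling.
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

is_count_ <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == round(x)
}
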