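# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (config, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative log-normal noise factors with unit mean: for a fractional
# coefficient of variation cv, sdlog = sqrt(log(1 + cv^2)) and
# meanlog = -sdlog^2/2 give E[factor] = 1 and CV[factor] = cv exactly.
# cv = 0 returns a vector of exact 1s (noise-free contract).
lnorm_factor <- function(n, cv) {
  stopifnot(cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
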