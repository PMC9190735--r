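# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-stage child seeds derived from a global seed, kept
# within 32-bit integer range.
childSeed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  ks <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in ks) {
    h <- (h * 48271 + as.double(k) %% 2147483647) %% 2147483647
  }
  as.integer(h)
}

# Symmetric inverse matrix square root via eigendecomposition.
invMatSqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix is not positive-definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Onset envelope: 0 before `onset`, linear ramp of `ramp` ms, then 1.
onsetEnvelope <- function(timeMs, onset, ramp) {
  if (ramp <= 0) return(as.numeric(timeMs > onset))
  pmin(1, pmax(0, (timeMs - onset) / ramp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
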