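# internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic components of the package go through this so
# that pipelines are reproducible end to end.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a string (polynomial rolling hash).
# Exact in double arithmetic: intermediate values stay below 2^53.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Combine a token hash with a user seed into a valid set.seed() value.
token_seed <- function(token, seed) {
  (string_hash(token) + (abs(seed) %% 2147483647) * 7919 + 1) %% 2147483647
}

l2_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared Euclidean distances between rows of A (n x d) and B (m x d)
cross_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# value with NA fallback (scalar)
`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
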