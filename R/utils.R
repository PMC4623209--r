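# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise just evaluate it.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed for sub-operations, kept inside 32-bit range
# (double arithmetic: composed children would overflow integer multiply).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69 + 1013 * as.numeric(k)) %% 2147483587)
}

stop_bad <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

# Matrix exponential of a small dense matrix: eigendecomposition when the
# eigenbasis is well conditioned, otherwise scaling and squaring with a
# Taylor core (blocks here are tiny, so this is both fast and accurate).
expm_small <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(matrix(exp(m[1, 1]), 1L, 1L))
  e <- tryCatch(eigen(m), error = function(err) NULL)
  if (!is.null(e)) {
    v <- e$vectors
    vi <- tryCatch(solve(v), error = function(err) NULL)
    if (!is.null(vi)) {
      out <- Re(v %*% (exp(e$values) * vi))
      # accept only if the decomposition actually reproduces m
      chk <- Re(v %*% (e$values * vi))
      if (max(abs(chk - m)) <= 1e-9 * max(1, max(abs(m)))) return(out)
    }
  }
  s <- max(0, ceiling(log2(max(1, norm(m, "1")))))
  a <- m / 2^s
  res <- diag(n)
  term <- diag(n)
  for (k in 1:40) {
    term <- term %*% a / k
    res <- res + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) res <- res %*% res
  res
}
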