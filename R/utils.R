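# misc internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower-triangle pair index order used throughout: (1,2),(1,3),...,(2,3),...
pair_index <- function(p) {
  if (p < 2) return(matrix(integer(0), ncol = 2))
  t(combn(p, 2))
}

# numeric Jacobian by central differences (rows = f components, cols = params)
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Cholesky-based multivariate normal draws; tolerates PSD matrices
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  if (p == 0) return(matrix(0, n, 0))
  ev <- eigen(Sigma, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  L <- ev$vectors %*% diag(sqrt(ev$values), p)
  sweep(matrix(rnorm(n * p), n, p) %*% t(L), 2, mu, "+")
}

is_psd <- function(S, tol = 1e-10) {
  if (nrow(S) == 2)               # closed form for the common 2x2 case
    return(S[1, 1] >= -tol && S[2, 2] >= -tol &&
             S[1, 1] * S[2, 2] - S[1, 2]^2 >= -tol * (1 + abs(S[1, 2])))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

# derive a reproducible child seed (< 2^31) from a master seed and a tag;
# double arithmetic stays exact well past the 32-bit range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1013) %%
               2147483563) + 1L
}
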