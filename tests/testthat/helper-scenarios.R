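# shared fixtures, all generated in code

`%||%` <- ordalt:::`%||%`

# small wide panel with known margins
tiny_panel <- function() {
  x <- matrix(c(0, 1, 2, 3, 0, 1,
                1, 1, 2, 3, 0, 1,
                2, 2, 2, 3, 0, 1,
                3, 3, 2, 3, 0, 1,
                0, 0, 1, 2, 3, 1,
                1, 2, 1, 2, 3, 0,
                2, 3, 1, 2, 3, 0,
                3, 0, 1, 2, 3, 0,
                0, 1, 0, 1, 2, 3,
                1, 2, 0, 1, 2, 3), nrow = 10, byrow = TRUE)
  ordinal_panel(x, n_occasions = 6)
}

# linear-growth scenario under the threshold-anchored parameterization
lgm_alt2_scenario <- function(n = 3000, T = 6, C = 4) {
  spec <- model_spec("lgm", "alt2", n_occasions = T, n_cat = C,
                     invariant = TRUE)
  th <- c(mu_alpha = 0.3, mu_beta = 0.2, psi_aa = 1, psi_ab = 0.1,
          psi_bb = 0.09, tau3 = 1.8)
  th[sprintf("theta_t%d", 1:T)] <- 0.8
  sim_scenario(spec, th, n)
}

# standard-parameterization AR(1) truth with balanced categories
ar1_standard_scenario <- function(n = 2000, T = 5, C = 4, rho = 0.5) {
  spec <- model_spec("ar1", "standard", n_occasions = T, n_cat = C)
  th <- stats::setNames(spec$pt$start[spec$pt$free], free_params(spec))
  th[sprintf("rho_t%d", 2:T)] <- rho
  mom <- ordalt:::implied_moments(spec, th)
  sds <- sqrt(diag(mom$Sigma))
  cuts <- stats::qnorm(seq_len(C - 1) / C) + 0.25
  for (t in 1:T) th[sprintf("tau%d_t%d", seq_len(C - 1), t)] <- cuts * sds[t]
  sim_scenario(spec, th, n)
}

# panel whose thresholds are truly time-invariant while the latent
# means/variances drift (used by the invariance diagnostics)
invariant_threshold_panel <- function(n = 4000, T = 6, seed = 2,
                                      perturb = 0) {
  set.seed(seed)
  Y <- matrix(rnorm(n * T), n, T)
  common <- rnorm(n)
  for (t in 1:T) Y[, t] <- Y[, t] * (1 + 0.08 * t) + 0.1 * t + 0.8 * common
  tau <- c(-0.6, 0.9, 2.0)
  X <- matrix(0L, n, T)
  for (t in 1:T) {
    tt <- tau
    if (perturb != 0 && t == T) tt[2] <- tt[2] + perturb
    X[, t] <- findInterval(Y[, t], tt)
  }
  ordinal_panel(X, T)
}

expect_equal_tol <- function(a, b, tol) testthat::expect_lt(max(abs(a - b)), tol)
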