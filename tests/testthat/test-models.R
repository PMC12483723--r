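test_that("growth-model implied moments match the closed form", {
  m0 <- implied_moments_lgm(c(0, 0), matrix(0, 2, 2), rep(1, 4), 4)
  expect_equal(m0$mu, rep(0, 4))
  expect_equal(m0$Sigma, diag(4))

  m1 <- implied_moments_lgm(c(0, 0.5), diag(c(1, 0.25)), rep(1, 4), 4)
  expect_equal(m1$mu, 0.5 * (0:3))
  expect_equal(m1$Sigma[4, 4], 1 + 9 * 0.25 + 1)
  L <- cbind(1, 0:3)
  expect_equal(m1$Sigma, L %*% diag(c(1, 0.25)) %*% t(L) + diag(4))
})

test_that("autoregressive implied moments match recursion algebra", {
  m0 <- implied_moments_ar1(c(0.3, 0.1, 0.2), numeric(2), c(2, 1, 1), 3)
  expect_equal(m0$mu, c(0.3, 0.1, 0.2))
  expect_equal(m0$Sigma, diag(c(2, 1, 1)))

  # stationary chain: var 4/3, lag-k covariance (4/3) 0.5^k
  T <- 6
  m1 <- implied_moments_ar1(rep(0, T), rep(0.5, T - 1),
                            c(4 / 3, rep(1, T - 1)), T)
  for (k in 0:3)
    expect_equal(m1$Sigma[1, 1 + k], (4 / 3) * 0.5^k)
  # unit-diagonal triangular system is always solvable
  m2 <- implied_moments_ar1(rep(0, 4), c(5, -4, 3), rep(1, 4), 4)
  expect_true(all(is.finite(m2$Sigma)))
})

test_that("ALT moments nest the growth and autoregressive models", {
  T <- 5
  psi <- matrix(c(0.5, 0.05, 0.05, 0.1), 2)
  # rho = 0 with matched occasion-one moments reduces to the growth model
  alt0 <- implied_moments_alt(nu1 = 0.3, mu_eta = c(0.3, 0.2),
                              psi_eta = psi, psi_1eta = c(0.5, 0.05),
                              rho = rep(0, T - 1),
                              theta_eps = c(0.5 + 0.7, rep(0.7, T - 1)), T)
  lgm <- implied_moments_lgm(c(0.3, 0.2), psi, rep(0.7, T), T)
  expect_lt(max(abs(alt0$Sigma - lgm$Sigma)), 1e-12)
  expect_lt(max(abs(alt0$mu - lgm$mu)), 1e-12)

  # zero growth reduces to AR(1)
  alt1 <- implied_moments_alt(nu1 = 0.2, mu_eta = c(0, 0),
                              psi_eta = matrix(0, 2, 2),
                              psi_1eta = c(0, 0), rho = rep(0.4, T - 1),
                              theta_eps = rep(1, T), T)
  ar <- implied_moments_ar1(c(0.2, rep(0, T - 1)), rep(0.4, T - 1),
                            rep(1, T), T)
  expect_lt(max(abs(alt1$Sigma - ar$Sigma)), 1e-12)
  expect_lt(max(abs(alt1$mu - ar$mu)), 1e-12)
})

test_that("every family agrees with the generic reduced-form evaluator", {
  set.seed(21)
  specs <- list(
    model_spec("lgm", "alt2", n_occasions = 5, n_cat = 4, invariant = TRUE),
    model_spec("ar1", "alt2", n_occasions = 5, n_cat = 4, invariant = TRUE),
    model_spec("alt", "alt2", n_occasions = 5, n_cat = 4, invariant = TRUE))
  for (spec in specs) {
    th <- ordalt:::random_admissible(spec)
    ex <- ordalt:::expand_params(spec, th)
    mom <- ordalt:::implied_moments(spec, th)
    sys <- ordalt:::reduced_form_system(
      spec$family, spec$T,
      nu = if (spec$family == "ar1") ex$nu else
        c(ex$nu1 %||% 0, rep(0, spec$T - 1)),
      rho = ex$rho %||% numeric(spec$T - 1),
      theta_eps = mom$theta_eps,
      mu_eta = ex$mu_eta %||% c(0, 0),
      psi_eta = ex$psi_eta %||% matrix(0, 2, 2),
      psi_1eta = ex$psi_1eta %||% c(0, 0))
    rf <- reduced_form_moments(sys$nu, sys$B, sys$Psi, sys$nsel)
    expect_lt(max(abs(mom$mu - rf$mu)), 1e-12)
    expect_lt(max(abs(mom$Sigma - rf$Sigma)), 1e-12)
  }
  # multivariate ALT against its stacked system
  sc <- nlsy_like_scenario(n = 10)
  sys <- ordalt:::malt_system(sc$spec, sc$theta)
  rf <- reduced_form_moments(sys$nu, sys$B, sys$Psi, sys$nsel)
  mom <- ordalt:::implied_moments(sc$spec, sc$theta)
  expect_lt(max(abs(mom$mu - rf$mu)), 1e-12)
  expect_lt(max(abs(mom$Sigma - rf$Sigma)), 1e-12)
})

test_that("multivariate ALT blocks collapse to univariate ALT", {
  spec <- model_spec("malt", "alt1", n_occasions = 4, n_cat = c(4, 4),
                     var_names = c("a", "b"), invariant = TRUE)
  th <- setNames(spec$pt$start[spec$pt$free], free_params(spec))
  th[grepl("^b_a_b|^b_b_a", names(th))] <- 0      # no cross-lags
  th[grepl("^cove_", names(th))] <- 0             # no concomitant effects
  th[grepl("^psi_a_.*_b_|psi11|psi1_a_b|psi1_b_a", names(th))] <- 0
  th["b_a_a_t2"] <- 0.3; th["b_a_a_t3"] <- 0.25; th["b_a_a_t4"] <- 0.2
  th[sprintf("a_theta_t%d", 2:4)] <- 0.8
  ex <- ordalt:::expand_params(spec, th)
  mom <- ordalt:::implied_moments(spec, th)
  # block for variable a should equal a univariate ALT with its params
  uni <- implied_moments_alt(nu1 = ex$nu1[1], mu_eta = ex$mu_eta[1, ],
                             psi_eta = ex$psi_g[1:2, 1:2],
                             psi_1eta = ex$psi_1g[1, 1:2],
                             rho = ex$B[1, 1, ],
                             theta_eps = ex$theta_eps[1, ], 4)
  expect_lt(max(abs(mom$Sigma[1:4, 1:4] - uni$Sigma)), 1e-12)
  # cross blocks vanish
  expect_lt(max(abs(mom$Sigma[1:4, 5:8])), 1e-12)
})

test_that("implied moments match large-sample simulated moments", {
  sc <- lgm_alt2_scenario(n = 200000)
  pan <- simulate_panel(sc, seed = 77, latent = TRUE)
  Y <- attr(pan, "latent")
  mom <- ordalt:::implied_moments(sc$spec, sc$theta)
  n <- nrow(Y)
  se_mu <- sqrt(diag(mom$Sigma) / n)
  expect_true(all(abs(colMeans(Y) - mom$mu) < 4 * se_mu))
  S <- cov(Y)
  for (i in 1:6) for (j in i:6) {
    se <- sqrt((mom$Sigma[i, i] * mom$Sigma[j, j] + mom$Sigma[i, j]^2) / n)
    expect_lt(abs(S[i, j] - mom$Sigma[i, j]), 4 * se + 1e-12)
  }
})

test_that("degrees of freedom follow the information count", {
  # binary AR(1): all four rows share df = (T-1)(T-2)/2
  dfb <- sapply(list(
    model_spec("ar1", "standard", n_occasions = 4, n_cat = 2),
    model_spec("ar1", "alt1", n_occasions = 4, n_cat = 2,
               binary_alt1 = "myt"),
    model_spec("ar1", "alt1", n_occasions = 4, n_cat = 2,
               binary_alt1 = "mm"),
    model_spec("ar1", "alt2", n_occasions = 4, n_cat = 2)), count_df)
  expect_true(all(dfb == 3))

  # ordinal growth model: standard and anchored specifications differ
  df_std <- count_df(model_spec("lgm", "standard", n_occasions = 4,
                                n_cat = 4))
  df_inv <- count_df(model_spec("lgm", "alt1", n_occasions = 4, n_cat = 4,
                                invariant = TRUE))
  expect_equal(df_std, 3)
  expect_equal(df_inv, 8)
  expect_false(df_std == df_inv)
  # the two anchored specifications share df
  expect_equal(df_inv, count_df(model_spec("lgm", "alt2", n_occasions = 4,
                                           n_cat = 4, invariant = TRUE)))

  # one extra equality constraint adds exactly one df
  free_rho <- model_spec("ar1", "standard", n_occasions = 3, n_cat = 3)
  tied_rho <- model_spec("ar1", "standard", n_occasions = 3, n_cat = 3,
                         stationary = TRUE)
  expect_equal(count_df(tied_rho), count_df(free_rho) + 1)
})

test_that("local identification ranks match the wave requirements", {
  # growth and autoregressive models are identified with four waves
  for (spec in list(
    model_spec("lgm", "standard", n_occasions = 4, n_cat = 4),
    model_spec("lgm", "standard", n_occasions = 4, n_cat = 4,
               placement = "theta"),
    model_spec("lgm", "alt1", n_occasions = 4, n_cat = 4, invariant = TRUE),
    model_spec("lgm", "alt2", n_occasions = 4, n_cat = 4, invariant = TRUE),
    model_spec("ar1", "standard", n_occasions = 4, n_cat = 4),
    model_spec("ar1", "alt1", n_occasions = 4, n_cat = 4, invariant = TRUE),
    model_spec("ar1", "alt2", n_occasions = 4, n_cat = 4, invariant = TRUE)))
    expect_equal(check_identification(spec, n_draws = 3, seed = 3)$identified,
                 "yes")
  # the ALT model needs five waves
  id5 <- check_identification(model_spec("alt", "alt1", n_occasions = 5,
                                         n_cat = 4, invariant = TRUE),
                              n_draws = 3, seed = 3)
  expect_equal(id5$identified, "yes")
  id4 <- check_identification(model_spec("alt", "alt1", n_occasions = 4,
                                         n_cat = 4, invariant = TRUE),
                              n_draws = 3, seed = 3)
  expect_equal(id4$identified, "no")
  expect_equal(id4$rank, id4$n_free - 1)
  expect_named(id4$null_direction)
})
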