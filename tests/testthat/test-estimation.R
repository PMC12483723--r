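test_that("threshold variances match the delta-method form", {
  sc <- lgm_alt2_scenario(n = 4000)
  pan <- simulate_panel(sc, seed = 8)
  st <- sample_stats(pan)
  mg <- margins(pan)
  # Var(qnorm(p_hat)) ~ p(1-p) / (n phi(tau)^2) for a single threshold
  for (j in c(1, 3)) {
    p1 <- cumsum(mg[[j]]$props)[1]
    tau <- qnorm(p1)
    v_delta <- p1 * (1 - p1) / (pan$n * dnorm(tau)^2)
    k <- (j - 1) * 3 + 1
    expect_lt(abs(st$Gamma[k, k] - v_delta) / v_delta, 0.02)
  }
})

test_that("bootstrap Gamma is seed-deterministic and near the analytic
           form", {
  sc <- lgm_alt2_scenario(n = 800, T = 4)
  pan <- simulate_panel(sc, seed = 9)
  g1 <- estimate_acov(pan, method = "bootstrap", B = 150, seed = 3)
  g2 <- estimate_acov(pan, method = "bootstrap", B = 150, seed = 3)
  expect_identical(g1, g2)
  expect_warning(estimate_acov(pan, method = "bootstrap", B = 50, seed = 1),
                 "100")
  ga <- estimate_acov(pan, method = "analytic")
  # agreement of the two estimators on the diagonal, within MC error
  rel <- abs(diag(g1) - diag(ga)) / diag(ga)
  expect_lt(stats::median(rel), 0.25)
})

test_that("Gamma scales like 1/n", {
  sc1 <- lgm_alt2_scenario(n = 2000, T = 4)
  sc2 <- lgm_alt2_scenario(n = 8000, T = 4)
  g1 <- estimate_acov(simulate_panel(sc1, seed = 10), method = "analytic")
  g2 <- estimate_acov(simulate_panel(sc2, seed = 10), method = "analytic")
  ratio <- diag(g1) / diag(g2)
  expect_gt(stats::median(ratio), 3)
  expect_lt(stats::median(ratio), 5.3)
})

test_that("sandwich covariance collapses and scales correctly", {
  set.seed(13)
  D <- matrix(rnorm(30), 10, 3)
  G <- crossprod(matrix(rnorm(100), 10)) / 10
  w <- diag(G)
  # Gamma = diag weight case: sandwich equals the naive covariance
  r0 <- robust_se(D, diag(w), w)
  naive <- solve(crossprod(D, D / w))
  expect_lt(max(abs(r0$acov - naive)), 1e-10)
  # scaling Gamma by 4 doubles the standard errors
  r1 <- robust_se(D, G, w)
  r4 <- robust_se(D, 4 * G, w)
  expect_equal(r4$se, 2 * r1$se)
})

test_that("saturated models fit perfectly with zero df", {
  sc <- lgm_alt2_scenario(n = 1500, T = 4)
  pan <- simulate_panel(sc, seed = 14)
  st <- sample_stats(pan)
  spec <- model_spec("aux", "standard", n_occasions = 4, n_cat = 4)
  expect_equal(count_df(spec), 0)
  fit <- dwls_fit(st, spec)
  expect_lt(fit$F_min, 1e-16)
  expect_equal(fit$chi2_adj, 0)
  expect_equal(fit$fit_indices[["cfi"]], 1)
  expect_equal(fit$fit_indices[["rmsea"]], 0)
})

test_that("degenerate weights are refused", {
  sc <- lgm_alt2_scenario(n = 1000, T = 4)
  pan <- simulate_panel(sc, seed = 15)
  st <- sample_stats(pan)
  st$Gamma[1, 1] <- 0
  expect_error(dwls_fit(st, sc$spec), "non-positive weight")
})

test_that("adjusted statistic reduces sensibly in limiting cases", {
  # df = 0: statistic reported as zero
  a0 <- adjusted_chi2(0.3, NULL, diag(4), 0)
  expect_equal(a0$chi2_adj, 0)
  # independent homoskedastic statistics with W = Gamma = I: no free
  # parameters, T already chi-square with df = dim
  a1 <- adjusted_chi2(5, NULL, diag(6), 6, w = rep(1, 6))
  expect_equal(a1$chi2_adj, 5)
  expect_equal(a1$df_eff, 6)
})

test_that("fit indices follow their formulas", {
  fi <- fit_indices(10, 10, 200, 15, 500)
  expect_equal(fi[["rmsea"]], 0)
  fi2 <- fit_indices(0, 5, 100, 10, 500)
  expect_equal(fi2[["cfi"]], 1)
  expect_lt(fi2[["bic_prime"]], 0)
  expect_equal(fi2[["bic_prime"]], -5 * log(500))
})

test_that("misspecified fits are rejected with growing power", {
  # strong AR(1) data fitted by a growth model
  sc <- ar1_standard_scenario(n = 4000, T = 5, rho = 0.7)
  pan <- simulate_panel(sc, seed = 16)
  st <- sample_stats(pan)
  lgm <- model_spec("lgm", "standard", n_occasions = 5, n_cat = 4)
  fit <- dwls_fit(st, lgm)
  expect_lt(fit$pvalue, 0.001)
})
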