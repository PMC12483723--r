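test_that("thresholds are standard-normal percentiles of the margins", {
  expect_equal(as.numeric(estimate_thresholds(c(50, 50))), 0)
  tau <- estimate_thresholds(c(25, 25, 25, 25))
  expect_equal(as.numeric(tau), c(qnorm(0.25), 0, qnorm(0.75)))
  b <- estimate_thresholds(c(10, 0))
  expect_true(is.infinite(b[1]) && b[1] > 0)
  expect_true(attr(b, "boundary"))
})

test_that("polychoric estimator maximizes the Olsson likelihood", {
  # independence: cells proportional to the product of margins
  tab <- outer(c(10, 20, 30, 40), c(40, 30, 20, 10)) / 10
  ta <- estimate_thresholds(rowSums(tab))
  tb <- estimate_thresholds(colSums(tab))
  pc <- polychoric_rho(tab, ta, tb)
  expect_lt(abs(pc$rho), 1e-4)

  # all mass on the main diagonal of a 2x2 table: boundary
  pc2 <- polychoric_rho(matrix(c(50, 0, 0, 50), 2), 0, 0)
  expect_true(pc2$boundary)
  expect_gt(pc2$rho, 0.99)

  # Monte-Carlo recovery from a discretized bivariate normal
  set.seed(4)
  n <- 10000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  cuts <- c(-0.8, 0.1, 0.9)
  pan <- ordinal_panel(cbind(findInterval(z1, cuts),
                             findInterval(z2, cuts)), 2)
  ta <- estimate_thresholds(margins(pan)[[1]])
  tb <- estimate_thresholds(margins(pan)[[2]])
  pc3 <- polychoric_rho(crosstab(pan, 1, 2), ta, tb)
  expect_lt(abs(pc3$rho - 0.5), 0.03)
})

test_that("polychoric estimate agrees with a dense grid-search oracle", {
  set.seed(11)
  for (k in 1:4) {
    tab <- matrix(rpois(16, 30) + 1, 4)
    ta <- estimate_thresholds(rowSums(tab))
    tb <- estimate_thresholds(colSums(tab))
    pc <- polychoric_rho(tab, ta, tb)
    grid <- seq(-0.995, 0.995, by = 1e-4)
    ll <- vapply(grid, function(r)
      ordalt:::polychoric_loglik_cpp(tab, ta, tb, r, 1e-12), numeric(1))
    expect_lt(abs(pc$rho - grid[which.max(ll)]), 1e-4)
  }
})

test_that("bivariate normal CDF matches 1-D quadrature", {
  oracle <- function(a, b, r)
    integrate(function(x) dnorm(x) * pnorm((b - r * x) / sqrt(1 - r^2)),
              -Inf, a, rel.tol = 1e-12)$value
  for (r in c(-0.95, -0.4, 0, 0.6, 0.95))
    for (a in c(-1.5, 0, 1)) for (b in c(-0.5, 0.8))
      expect_lt(abs(pbvnorm(a, b, r) - oracle(a, b, r)), 1e-12)
})

test_that("alternative parameterizations are exact reparameterizations", {
  sc <- lgm_alt2_scenario(n = 2000)
  pan <- simulate_panel(sc, seed = 5)
  aux <- build_auxiliary(pan, "standard")
  expect_equal(aux$mu_star, rep(0, 6))
  expect_equal(aux$sigma_star, rep(1, 6))
  expect_equal(unname(diag(aux$P_star)), rep(1, 6))

  a1 <- build_auxiliary(pan, "alt1")
  expect_equal(a1$mu_star[1], 0)
  expect_equal(a1$sigma_star[1], 1)
  expect_equal(a1$tau[[1]], aux$tau[[1]])   # occasion one unchanged

  # threshold-anchored map: tau_std (-0.5, 0.5) gives sd 1, mean 0.5
  tmat <- matrix(c(-0.5, 0.5, 1.5), 3, 1)
  am <- ordalt:::aux_affine(tmat, "alt2")
  expect_equal(am$sigma[1], 1)
  expect_equal(am$mu[1], 0.5)
  expect_equal(am$tau[1:2, 1], c(0, 1))

  # round trip standard -> alt2 -> standard is the identity
  a2 <- build_auxiliary(pan, "alt2")
  back <- reparameterize(a2, "standard")
  expect_lt(max(abs(unlist(back$tau) - unlist(aux$tau))), 1e-10)
  expect_lt(max(abs(back$P_star - aux$P_star)), 1e-10)
  # and alt1 -> alt2 composes consistently with the direct map
  a12 <- reparameterize(a1, "alt2")
  expect_lt(max(abs(unlist(a12$tau) - unlist(a2$tau))), 1e-10)

  # discretization probabilities are invariant across parameterizations
  for (j in c(1, 4)) {
    p_std <- pnorm(aux$tau[[j]], 0, 1)
    p_a2 <- pnorm(a2$tau[[j]], a2$mu_star[j], a2$sigma_star[j])
    expect_lt(max(abs(p_std - p_a2)), 1e-12)
  }
})

test_that("threshold-difference ratios diagnose invariance", {
  # identical thresholds at all occasions: all ratios one
  pan <- invariant_threshold_panel()
  aux <- build_auxiliary(pan, "standard")
  T <- 6
  tmat <- do.call(cbind, aux$tau)
  # constructed case: thresholds at occasion 2 = scaled/shifted occasion 1
  tc <- cbind(tmat[, 1], 2 * tmat[, 1] + 0.7)
  ratios <- apply(combn(3, 2), 2, function(p)
    (tc[p[2], 1] - tc[p[1], 1]) / (tc[p[2], 2] - tc[p[1], 2]))
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(ratios[1], 0.5)

  # sampled invariant-threshold data: no occasion pair flagged
  rd <- invariance_ratio_diagnostic(aux)
  expect_equal(sum(attr(rd, "flags")), 0)

  # perturbing one threshold at one occasion raises a flag there
  pan2 <- invariant_threshold_panel(perturb = 0.5)
  rd2 <- invariance_ratio_diagnostic(build_auxiliary(pan2, "standard"))
  flags <- attr(rd2, "flags")
  expect_gt(sum(flags), 0)
  expect_true(all(grepl(" 6$", names(flags)[flags])))

  expect_error(invariance_ratio_diagnostic(
    build_auxiliary(ordinal_panel(cbind(c(0, 1, 1, 2), c(1, 0, 2, 1)), 2),
                    "standard")), "4 categories")
})

test_that("threshold-invariance test is anchored-parameterization
           invariant", {
  pan <- invariant_threshold_panel()
  st <- sample_stats(pan)
  f1 <- test_threshold_invariance(pan, "alt1_inv", stats = st)
  f2 <- test_threshold_invariance(pan, "alt2_inv", stats = st)
  expect_equal(f1$df, f2$df)
  expect_equal(f1$df, 6 * 3 - (3 + 2 * 5))   # T(C-1) - [(C-1) + 2(T-1)]
  expect_lt(abs(f1$chi2 - f2$chi2), 1e-6)
  expect_lt(abs(f1$chi2_adj - f2$chi2_adj), 1e-6)
  # truly invariant thresholds: the restriction should not be rejected
  expect_gt(f1$pvalue, 0.05)
  expect_lt(f1$fit_indices["bic_prime"], 0)

  pb <- ordinal_panel(matrix(rbinom(400, 1, 0.4), 100), 4)
  expect_error(test_threshold_invariance(pb), "not testable")
})
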