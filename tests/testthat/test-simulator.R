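test_that("simulation is seed-deterministic and symmetric where it
           should be", {
  sc <- lgm_alt2_scenario(n = 500, T = 4)
  p1 <- simulate_panel(sc, seed = 40)
  p2 <- simulate_panel(sc, seed = 40)
  expect_identical(p1$data, p2$data)
  p3 <- simulate_panel(sc, seed = 41)
  expect_false(identical(p1$data, p3$data))

  # zero-mean latents with symmetric thresholds give symmetric margins
  spec <- model_spec("ar1", "standard", n_occasions = 3, n_cat = 3)
  th <- setNames(spec$pt$start[spec$pt$free], free_params(spec))
  th[sprintf("rho_t%d", 2:3)] <- 0
  for (t in 1:3) th[sprintf("tau%d_t%d", 1:2, t)] <- c(-0.6, 0.6)
  pan <- simulate_panel(sim_scenario(spec, th, 60000), seed = 42)
  pr <- margins(pan)[[1]]$props
  expect_lt(abs(pr[1] - pr[3]), 0.02)
})

test_that("inadmissible truths are refused before sampling", {
  spec <- model_spec("lgm", "alt2", n_occasions = 4, n_cat = 4,
                     invariant = TRUE)
  th <- setNames(spec$pt$start[spec$pt$free], free_params(spec))
  th["psi_aa"] <- 1; th["psi_bb"] <- 0.01; th["psi_ab"] <- 0.5  # non-PSD
  expect_error(sim_scenario(spec, th, 100), "inadmissible")
})

test_that("latent sample moments converge to the implied moments", {
  sc <- ar1_standard_scenario(n = 300000, T = 4, rho = 0.5)
  pan <- simulate_panel(sc, seed = 43, latent = TRUE)
  Y <- attr(pan, "latent")
  mom <- ordalt:::implied_moments(sc$spec, sc$theta)
  n <- nrow(Y)
  for (i in 1:4) for (j in i:4) {
    se <- sqrt((mom$Sigma[i, i] * mom$Sigma[j, j] + mom$Sigma[i, j]^2) / n)
    expect_lt(abs(cov(Y)[i, j] - mom$Sigma[i, j]), 4 * se + 1e-12)
  }
})

test_that("finer discretization recovers the latent correlation better", {
  set.seed(44)
  n <- 20000
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  rec <- sapply(c(3, 7), function(C) {
    cuts <- qnorm(seq_len(C - 1) / C)
    pan <- ordinal_panel(cbind(findInterval(z1, cuts),
                               findInterval(z2, cuts)), 2)
    ta <- estimate_thresholds(margins(pan)[[1]])
    tb <- estimate_thresholds(margins(pan)[[2]])
    polychoric_rho(crosstab(pan, 1, 2), ta, tb)$rho
  })
  expect_lt(abs(rec[2] - 0.6), abs(rec[1] - 0.6) + 0.01)
  expect_lt(abs(rec[2] - 0.6), 0.02)
})

test_that("the packaged trivariate scenario has the documented shape and
           trend", {
  sc <- nlsy_like_scenario(n = 5000)
  pan <- simulate_panel(sc, seed = 45)
  expect_equal(dim(pan$data), c(5000L, 18L))
  expect_equal(pan$C, c(2L, 4L, 4L))
  mg <- margins(pan)
  drug_yes <- vapply(1:6, function(t) mg[[t]]$props[2], numeric(1))
  # declining propensity to use drugs across the six waves
  expect_lt(drug_yes[6], drug_yes[1])
  expect_lt(mean(diff(drug_yes)), 0)
})

test_that("the packaged scenario round-trips through the fitting and
           equivalence machinery", {
  sc <- nlsy_like_scenario(n = 1500)
  pan <- simulate_panel(sc, seed = 46)
  st <- sample_stats(pan)
  # multivariate auxiliary layer with invariant thresholds
  aux_spec <- model_spec("aux", "alt1", n_occasions = 6,
                         n_cat = c(2, 4, 4),
                         var_names = c("drug", "depr", "health"),
                         invariant = TRUE, binary_alt1 = "myt")
  fit <- dwls_fit(st, aux_spec)
  expect_true(fit$converged)
  expect_gt(fit$df, 0)
  # threshold invariance holds in truth: not rejected
  expect_gt(fit$pvalue, 0.01)
})

test_that("recovery studies run seeded and flag short runs", {
  sc <- lgm_alt2_scenario(n = 800, T = 4)
  expect_warning(r <- recovery_study(sc, reps = 4, seed = 2), "50")
  expect_equal(r$n_converged, 4)
  expect_true(all(c("bias", "rmse", "coverage") %in% names(r$table)))
  r2 <- suppressWarnings(recovery_study(sc, reps = 4, seed = 2))
  expect_identical(r$table$mean_est, r2$table$mean_est)
})
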