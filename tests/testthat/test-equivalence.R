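# map fixtures
lgm_A <- model_spec("lgm", "alt1", n_occasions = 4, n_cat = 4,
                    invariant = TRUE, placement = "delta")
lgm_B <- model_spec("lgm", "alt2", n_occasions = 4, n_cat = 4,
                    invariant = TRUE)
lgm_D <- model_spec("lgm", "alt1", n_occasions = 4, n_cat = 4,
                    invariant = TRUE, placement = "theta")
ar1_E <- model_spec("ar1", "alt1", n_occasions = 4, n_cat = 4,
                    invariant = TRUE)
ar1_F <- model_spec("ar1", "alt2", n_occasions = 4, n_cat = 4,
                    invariant = TRUE)
bin_G <- model_spec("ar1", "standard", n_occasions = 4, n_cat = 2)
bin_H <- model_spec("ar1", "alt1", n_occasions = 4, n_cat = 2,
                    binary_alt1 = "myt")
bin_I <- model_spec("ar1", "alt1", n_occasions = 4, n_cat = 2,
                    binary_alt1 = "mm")
bin_L <- model_spec("ar1", "alt2", n_occasions = 4, n_cat = 2)

map_pairs <- list(list(lgm_A, lgm_B), list(lgm_A, lgm_D),
                  list(ar1_E, ar1_F), list(bin_G, bin_H),
                  list(bin_G, bin_I), list(bin_G, bin_L))

test_that("every shipped map preserves the implied statistics and
           round-trips to the identity", {
  set.seed(31)
  for (pair in map_pairs) {
    a <- pair[[1]]; b <- pair[[2]]
    for (k in 1:40) {
      th <- ordalt:::random_admissible(a)
      names(th) <- free_params(a)
      if (identical(a, bin_G)) {
        # keep standardized thresholds one-signed for the Muthen-Muthen map
        mom <- ordalt:::implied_moments(a, th)
        th[sprintf("tau1_t%d", 1:4)] <- 0.8 * sqrt(diag(mom$Sigma))
      }
      mapped <- transform_params(th, a, b)
      expect_lt(max(abs(implied_stats(b, mapped) -
                          implied_stats(a, th))), 1e-10)
      back <- transform_params(mapped, b, a)
      expect_lt(max(abs(back - th[names(back)])), 1e-10)
    }
  }
})

test_that("maps into non-equivalent pairs are refused", {
  alt_a <- model_spec("alt", "alt1", n_occasions = 5, n_cat = 4,
                      invariant = TRUE)
  alt_b <- model_spec("alt", "alt2", n_occasions = 5, n_cat = 4,
                      invariant = TRUE)
  th <- ordalt:::random_admissible(alt_a)
  expect_error(transform_params(th, alt_a, alt_b), "not equivalent|not tabled")
})

test_that("a specification is equivalent to itself and df equality is
           necessary", {
  sc <- lgm_alt2_scenario(n = 1200, T = 4)
  panels <- list(simulate_panel(sc, seed = 33))
  ce <- check_equivalence(lgm_B, lgm_B, panels = panels)
  expect_equal(ce$verdict, "EQUIVALENT")
  # different df: growth model vs saturated auxiliary layer
  aux <- model_spec("aux", "alt2", n_occasions = 4, n_cat = 4,
                    invariant = TRUE)
  ce2 <- check_equivalence(lgm_B, aux, panels = panels)
  expect_equal(ce2$verdict, "NOT_EQUIVALENT")
  expect_false(ce2$df[1] == ce2$df[2])
})

test_that("covariance-structure constraint counts and distinctness", {
  # growth model, four occasions: seven constraints on the covariance
  # structure under both variance placements, but different ones
  s_delta <- model_spec("lgm", "standard", n_occasions = 4, n_cat = 4,
                        placement = "delta")
  s_theta <- model_spec("lgm", "standard", n_occasions = 4, n_cat = 4,
                        placement = "theta")
  r1 <- omega_constraint_report(s_delta, n_draws = 60, seed = 4)
  r2 <- omega_constraint_report(s_theta, n_draws = 60, seed = 4)
  expect_equal(r1$n_constraints, 7)
  expect_equal(r2$n_constraints, 7)
  expect_true(r1$linear_verified)
  # the delta-parameterization constraints are violated by theta-implied
  # covariance matrices (and the families are mutually non-nested)
  d12 <- omega_distinct(s_theta, s_delta, n_draws = 3, seed = 5)
  expect_gt(d12$max_min_residual, 1e-4)
  # stationary ALT at five occasions: three distinct specifications
  alts <- list(
    model_spec("alt", "standard", n_occasions = 5, n_cat = 4,
               stationary = TRUE),
    model_spec("alt", "alt1", n_occasions = 5, n_cat = 4,
               invariant = TRUE, stationary = TRUE),
    model_spec("alt", "alt2", n_occasions = 5, n_cat = 4,
               invariant = TRUE, stationary = TRUE))
  reports <- lapply(alts, omega_constraint_report, n_draws = 10, seed = 6)
  counts <- vapply(reports, function(r) r$n_constraints, numeric(1))
  expect_true(all(counts >= 1))
  # the standard specification constrains the covariance structure more
  # strongly than the anchored ones (fixed unit error variances)
  expect_gt(counts[1], counts[2])
})
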