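# Recursion-based simulator for ordinal panels.  Latent trajectories are
# generated by drawing the disturbances and running the structural
# recursion subject by subject (vectorized over subjects) -- never by a
# Cholesky factor of the implied covariance -- so the simulator is an
# independent oracle for the implied-moment algebra.

#' Define a simulation scenario
#'
#' @param spec a [model_spec()]; its free parameters define the truth.
#' @param theta true values for the free parameters (named or in
#'   [free_params()] order).
#' @param n number of subjects.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(spec, theta, n) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(names(theta))) {
    nm <- free_params(spec)
    if (!all(nm %in% names(theta)))
      stop("missing true values for: ",
           paste(setdiff(nm, names(theta)), collapse = ", "))
    theta <- theta[nm]
  }
  if (length(theta) != sum(spec$pt$free))
    stop("theta length does not match the free parameters")
  det <- implied_stats(spec, theta, detail = TRUE)
  if (!det$admissible)
    stop("true parameter vector implies an inadmissible process ",
         "(negative variance or non-PSD covariance)")
  structure(list(spec = spec, theta = as.numeric(theta), n = n),
            class = "sim_scenario")
}

# draw latent trajectories for a univariate family
simulate_latent_univ <- function(spec, ex, mom, n) {
  T <- spec$T
  fam <- spec$family
  th <- mom$theta_eps
  if (fam == "lgm") {
    G <- rmvn(n, ex$mu_eta, ex$psi_eta)
    E <- matrix(rnorm(n * T), n, T) %*% diag(sqrt(th), T)
    L <- cbind(1, 0:(T - 1))
    return(G %*% t(L) + E)
  }
  Y <- matrix(0, n, T)
  if (fam == "ar1") {
    Y[, 1] <- ex$nu[1] + rnorm(n, 0, sqrt(th[1]))
    for (t in 2:T)
      Y[, t] <- ex$nu[t] + ex$rho[t - 1] * Y[, t - 1] +
        rnorm(n, 0, sqrt(th[t]))
    return(Y)
  }
  # alt: joint draw of (zeta_1, alpha, beta) then forward recursion
  S3 <- matrix(0, 3, 3)
  S3[1, 1] <- th[1]
  S3[1, 2:3] <- S3[2:3, 1] <- ex$psi_1eta
  S3[2:3, 2:3] <- ex$psi_eta
  Z <- rmvn(n, c(ex$nu1, ex$mu_eta), S3)
  Y[, 1] <- Z[, 1]
  for (t in 2:T)
    Y[, t] <- ex$rho[t - 1] * Y[, t - 1] + Z[, 2] + (t - 1) * Z[, 3] +
      rnorm(n, 0, sqrt(th[t]))
  Y
}

simulate_latent_malt <- function(spec, ex, mom, n) {
  V <- spec$V; T <- spec$T
  th <- mom$theta_eps                 # V x T, remainders resolved
  q0 <- V + 2 * V                     # (y*_1 vector, growth factors)
  S0 <- matrix(0, q0, q0)
  S0[1:V, 1:V] <- ex$psi_11; diag(S0)[1:V] <- th[, 1]
  S0[1:V, V + 1:(2 * V)] <- ex$psi_1g
  S0[V + 1:(2 * V), 1:V] <- t(ex$psi_1g)
  S0[V + 1:(2 * V), V + 1:(2 * V)] <- ex$psi_g
  Z <- rmvn(n, c(ex$nu1, as.vector(t(ex$mu_eta))), S0)
  Y <- array(0, c(n, V, T))
  Y[, , 1] <- Z[, 1:V]
  G <- Z[, V + 1:(2 * V), drop = FALSE]
  for (t in 2:T) {
    lam <- t - 1
    Et <- ex$conc; diag(Et) <- th[, t]
    E <- rmvn(n, rep(0, V), Et)
    Bt <- matrix(ex$B[, , t - 1], V, V)
    gpart <- vapply(seq_len(V), function(v)
      G[, 2 * v - 1] + lam * G[, 2 * v], numeric(n))
    Y[, , t] <- Y[, , t - 1] %*% t(Bt) + gpart + E
  }
  # flatten to variable-block-major columns
  out <- matrix(0, n, V * T)
  for (v in seq_len(V)) out[, (v - 1) * T + 1:T] <- Y[, v, ]
  out
}

#' Simulate an ordinal panel from a scenario
#'
#' Draws latent trajectories by the structural recursion and discretizes
#' them with the scenario's model-metric thresholds (`y = c` iff
#' `tau_c < y* <= tau_{c+1}`).
#'
#' @param scenario a [sim_scenario()].
#' @param seed RNG seed (deterministic output for a given seed).
#' @param latent logical; also return the latent matrix.
#' @return an [ordinal_panel()]; if `latent = TRUE`, the latent matrix is
#'   attached as attribute `"latent"`.
#' @export
simulate_panel <- function(scenario, seed = 1, latent = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  spec <- scenario$spec
  set.seed(seed)
  ex <- expand_params(spec, scenario$theta)
  mom <- implied_moments(spec, scenario$theta)
  n <- scenario$n
  Y <- if (spec$family == "malt")
    simulate_latent_malt(spec, ex, mom, n)
  else simulate_latent_univ(spec, ex, mom, n)
  p <- spec$V * spec$T
  X <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    tau <- ex$tau_model[[j]]
    X[, j] <- findInterval(Y[, j], vec = sort(tau))
  }
  panel <- ordinal_panel(X, spec$T, var_names = spec$var_names,
                         n_cat = spec$C)
  if (latent) attr(panel, "latent") <- Y
  panel
}

#' Parameter-recovery study
#'
#' Repeatedly simulates panels from a scenario, fits a specification, and
#' summarizes per-parameter bias, RMSE, and 95% confidence-interval
#' coverage (robust standard errors).
#'
#' @param scenario a [sim_scenario()] (truth).
#' @param fit_spec specification to fit (defaults to the scenario's).
#' @param reps number of replications (warning below 50).
#' @param seed master seed; replicate `r` uses a derived child seed.
#' @param acov_method passed to [sample_stats()].
#' @return object of class `recovery_study`: data.frame `table` with
#'   `truth`, `mean_est`, `bias`, `rmse`, `coverage`, plus `n_converged`.
#' @export
recovery_study <- function(scenario, fit_spec = NULL, reps = 200, seed = 1,
                           acov_method = "analytic") {
  if (reps < 50) warning("fewer than 50 replications")
  spec <- scenario$spec
  if (is.null(fit_spec)) fit_spec <- spec
  same <- identical(fit_spec$pt$name, spec$pt$name)
  truth <- scenario$theta
  nm <- free_params(fit_spec)
  est <- se <- matrix(NA_real_, reps, length(nm),
                      dimnames = list(NULL, nm))
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    panel <- simulate_panel(scenario, seed = child_seed(seed, r))
    fit <- tryCatch({
      st <- sample_stats(panel, method = acov_method)
      dwls_fit(st, fit_spec)
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      est[r, ] <- fit$theta
      se[r, ] <- fit$se_robust
      ok[r] <- TRUE
    }
  }
  est <- est[ok, , drop = FALSE]; se <- se[ok, , drop = FALSE]
  tab <- data.frame(param = nm,
                    truth = if (same) truth else NA_real_,
                    mean_est = colMeans(est),
                    sd_est = apply(est, 2, sd),
                    mean_se = colMeans(se))
  if (same) {
    tab$bias <- tab$mean_est - truth
    tab$rmse <- sqrt(colMeans(sweep(est, 2, truth)^2))
    lo <- est - 1.959964 * se; hi <- est + 1.959964 * se
    tab$coverage <- colMeans(sweep(lo, 2, truth) <= 0 &
                               sweep(hi, 2, truth) >= 0)
  }
  structure(list(table = tab, n_converged = sum(ok), reps = reps),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("recovery study: %d/%d converged replications\n",
              x$n_converged, x$reps))
  print(transform(x$table, truth = round(truth, 3),
                  mean_est = round(mean_est, 3)), digits = 3)
  invisible(x)
}

#' Packaged trivariate panel scenario
#'
#' A synthetic multivariate ALT scenario emulating a three-variable
#' national youth panel: one binary series (illegal drug use) and two
#' 4-category ordinal series (depressive symptoms, general health) over
#' six biennial waves, with autoregressive, cross-lagged and concomitant
#' structure, a declining drug-use propensity and time-invariant
#' thresholds.  All true values are documented in the returned scenario's
#' `theta` (see the methods vignette for the rationale).
#'
#' @param n subjects (default 5000).
#' @return a [sim_scenario()].
#' @export
nlsy_like_scenario <- function(n = 5000) {
  vn <- c("drug", "depr", "health")
  spec <- model_spec("malt", "alt1", n_occasions = 6,
                     n_cat = c(2, 4, 4), var_names = vn, invariant = TRUE,
                     stationary = TRUE, concomitant = TRUE,
                     binary_alt1 = "myt")
  th <- spec$pt$start[spec$pt$free]
  names(th) <- free_params(spec)
  set_th <- function(nm, val) {
    stopifnot(all(nm %in% names(th)))
    th[nm] <<- val
  }
  # time-invariant thresholds (occasion-one anchoring)
  set_th("drug_tau1", 0.85)
  set_th(sprintf("depr_tau%d", 1:3), c(-0.4, 0.7, 1.6))
  set_th(sprintf("health_tau%d", 1:3), c(-1.5, -0.5, 0.6))
  # growth means: declining drug-use and depression propensities, slowly
  # declining perceived health
  set_th("drug_mu_alpha", 0.05);   set_th("drug_mu_beta", -0.07)
  set_th("depr_mu_alpha", 0.02);   set_th("depr_mu_beta", -0.05)
  set_th("health_mu_alpha", 0.02); set_th("health_mu_beta", -0.03)
  # free error variances from the second occasion on
  for (v in c("depr", "health"))
    set_th(sprintf("%s_theta_t%d", v, 2:6), rep(0.75, 5))
  # stationary autoregressive and cross-lagged effects
  set_th("b_drug_drug", 0.30); set_th("b_depr_depr", 0.35)
  set_th("b_health_health", 0.40)
  set_th("b_drug_depr", 0.08); set_th("b_drug_health", -0.05)
  set_th("b_depr_drug", 0.05); set_th("b_depr_health", -0.10)
  set_th("b_health_drug", -0.06); set_th("b_health_depr", -0.08)
  # growth-factor covariance: modest variances, slight intercept-slope
  # coupling within series, cross-series intercept correlations
  g <- c("drug_alpha", "drug_beta", "depr_alpha", "depr_beta",
         "health_alpha", "health_beta")
  for (i in seq_along(g)) for (j in i:length(g))
    set_th(sprintf("psi_%s_%s", g[i], g[j]), 0)
  set_th("psi_drug_alpha_drug_alpha", 0.25)
  set_th("psi_drug_beta_drug_beta", 0.010)
  set_th("psi_depr_alpha_depr_alpha", 0.30)
  set_th("psi_depr_beta_depr_beta", 0.012)
  set_th("psi_health_alpha_health_alpha", 0.30)
  set_th("psi_health_beta_health_beta", 0.012)
  set_th("psi_drug_alpha_drug_beta", -0.02)
  set_th("psi_depr_alpha_depr_beta", -0.02)
  set_th("psi_health_alpha_health_beta", -0.015)
  set_th("psi_drug_alpha_depr_alpha", 0.06)
  set_th("psi_depr_alpha_health_alpha", -0.08)
  set_th("psi_drug_alpha_health_alpha", -0.05)
  # predetermined first occasions
  for (v in vn) for (j in g) set_th(sprintf("psi1_%s_%s", v, j), 0)
  set_th("psi1_drug_drug_alpha", 0.08)
  set_th("psi1_depr_depr_alpha", 0.10)
  set_th("psi1_health_health_alpha", 0.10)
  set_th("psi11_drug_depr", 0.10)
  set_th("psi11_drug_health", -0.08)
  set_th("psi11_depr_health", -0.15)
  # concomitant error covariances
  set_th("cove_drug_depr", 0.05)
  set_th("cove_drug_health", -0.04)
  set_th("cove_depr_health", -0.08)
  sim_scenario(spec, th, n)
}
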