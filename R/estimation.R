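# Stage 2: diagonally weighted least squares on the stage-1 statistics.
#
# The fitted statistics vector is always expressed in the standard metric:
# standardized thresholds (per variable-occasion column) followed by the
# polychoric correlations.  Every parameterization implies this same
# vector through its own parameters, which keeps chi-square values
# comparable across specifications fitted to one panel.

#' Stage-1 sample statistics and their asymptotic covariance
#'
#' Computes the standard-parameterization thresholds and polychoric
#' correlations of a panel together with the asymptotic covariance matrix
#' `Gamma` of the stacked statistics.  `method = "analytic"` uses the
#' estimating-equation (influence-function) form of the two-step
#' estimator: thresholds are standard-normal percentiles with influence
#' `(1{y <= c} - P_c)/phi(tau_c)`, and each polychoric correlation is an
#' M-estimator whose influence combines its Olsson score with the
#' propagated threshold influences.  `method = "bootstrap"` resamples
#' subjects (`B` replicates, seeded).
#'
#' @param panel an [ordinal_panel()].
#' @param method `"analytic"` or `"bootstrap"`.
#' @param B bootstrap replicates (a warning is issued below 100).
#' @param seed seed for the bootstrap resampling.
#' @return object of class `sample_stats`: `s` (named statistics vector),
#'   `Gamma`, `n`, `tau` (per-column list), `R`, `pairs`, `flags`.
#' @export
sample_stats <- function(panel, method = c("analytic", "bootstrap"),
                         B = 500, seed = 1) {
  method <- match.arg(method)
  st <- stage1_estimates(panel)
  p <- ncol(panel$data)
  if (any(vapply(st$tau, function(x) any(!is.finite(x)), logical(1))))
    stop("infinite thresholds (empty extreme categories); estimation ",
         "cannot proceed on this panel")
  s <- c(unlist(st$tau), st$rho)
  names(s) <- c(unlist(lapply(seq_len(p), function(j)
    paste0("tau_", colnames(panel$data)[j], "_c", seq_len(col_ncat(panel, j) - 1)))),
    apply(st$pairs, 1, function(z) sprintf("rho_%d_%d", z[1], z[2])))
  Gamma <- estimate_acov(panel, st, method = method, B = B, seed = seed)
  dimnames(Gamma) <- list(names(s), names(s))
  structure(list(s = s, Gamma = Gamma, n = panel$n, tau = st$tau,
                 R = st$R, pairs = st$pairs, flags = st$flags,
                 C = panel$C, T = panel$T, V = length(panel$var_names)),
            class = "sample_stats")
}

#' Asymptotic covariance of the stage-1 statistics
#'
#' @param panel an [ordinal_panel()].
#' @param stage1 optional precomputed internal stage-1 estimates.
#' @param method,B,seed see [sample_stats()].
#' @return the `Gamma` matrix (covariance of the stacked thresholds and
#'   polychoric correlations, already on the `1/n` scale).
#' @export
estimate_acov <- function(panel, stage1 = NULL,
                          method = c("analytic", "bootstrap"),
                          B = 500, seed = 1) {
  method <- match.arg(method)
  if (is.null(stage1)) stage1 <- stage1_estimates(panel)
  if (method == "bootstrap") {
    if (B < 100) warning("fewer than 100 bootstrap replicates")
    set.seed(seed)
    n <- panel$n
    reps <- matrix(NA_real_, B, length(unlist(stage1$tau)) +
                     nrow(stage1$pairs))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- panel
      pb$data <- panel$data[idx, , drop = FALSE]
      sb <- tryCatch(stage1_estimates(pb), error = function(e) NULL)
      if (!is.null(sb)) reps[b, ] <- c(unlist(sb$tau), sb$rho)
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    return(stats::cov(reps))
  }
  influence_acov(panel, stage1)
}

# estimating-equation Gamma
influence_acov <- function(panel, st) {
  n <- panel$n
  p <- ncol(panel$data)
  ntau <- vapply(seq_len(p), function(j) col_ncat(panel, j) - 1L, integer(1))
  tau_off <- c(0L, cumsum(ntau))
  npair <- nrow(st$pairs)
  q <- sum(ntau) + npair
  IF <- matrix(0, n, q)
  # thresholds
  for (j in seq_len(p)) {
    tau <- st$tau[[j]]
    Pc <- pnorm(tau)
    y <- panel$data[, j]
    for (c in seq_along(tau))
      IF[, tau_off[j] + c] <- ((y <= c - 1) - Pc[c]) / dnorm(tau[c])
  }
  # polychoric correlations
  for (k in seq_len(npair)) {
    i <- st$pairs[k, 1]; j <- st$pairs[k, 2]
    ta <- st$tau[[i]]; tb <- st$tau[[j]]
    rho <- st$rho[k]
    tab <- crosstab(panel, i, j)
    score_cells <- function(ta, tb, r) {
      P <- cell_probs_cpp(ta, tb, r)
      dP <- cell_dprobs_cpp(ta, tb, r)
      dP / pmax(P, 1e-12)
    }
    SC <- score_cells(ta, tb, rho)
    mean_score <- function(ta, tb, r)
      sum(tab * score_cells(ta, tb, r)) / n
    h <- 1e-5
    A_rho <- (mean_score(ta, tb, rho + h) -
                mean_score(ta, tb, rho - h)) / (2 * h)
    # derivative of the mean score w.r.t. each fixed threshold
    A_ta <- vapply(seq_along(ta), function(c) {
      tp <- ta; tp[c] <- ta[c] + h
      tm <- ta; tm[c] <- ta[c] - h
      (mean_score(tp, tb, rho) - mean_score(tm, tb, rho)) / (2 * h)
    }, numeric(1))
    A_tb <- vapply(seq_along(tb), function(c) {
      tp <- tb; tp[c] <- tb[c] + h
      tm <- tb; tm[c] <- tb[c] - h
      (mean_score(ta, tp, rho) - mean_score(ta, tm, rho)) / (2 * h)
    }, numeric(1))
    cell <- cbind(panel$data[, i] + 1L, panel$data[, j] + 1L)
    sc_i <- SC[cell]
    prop <- IF[, tau_off[i] + seq_along(ta), drop = FALSE] %*% A_ta +
      IF[, tau_off[j] + seq_along(tb), drop = FALSE] %*% A_tb
    IF[, sum(ntau) + k] <- -(sc_i + drop(prop)) / A_rho
  }
  IFc <- scale(IF, center = TRUE, scale = FALSE)
  crossprod(IFc) / (n * (n - 1))
}

# ---------------------------------------------------------------------------
# DWLS fitting

#' Robust (sandwich) standard errors for a DWLS fit
#'
#' `acov = (D'W^{-1}D)^{-1} D'W^{-1} Gamma W^{-1} D (D'W^{-1}D)^{-1}` with
#' `D` the Jacobian of the implied statistics, `W = diag(Gamma)` the DWLS
#' weight matrix and `Gamma` the full asymptotic covariance of the
#' statistics.  When `Gamma` equals `W` the expression collapses to the
#' naive covariance `(D'W^{-1}D)^{-1}`.
#'
#' @param Delta Jacobian matrix (statistics x parameters).
#' @param Gamma asymptotic covariance of the statistics.
#' @param w optional weight vector (defaults to `diag(Gamma)`).
#' @return list `se` (robust standard errors) and `acov`.
#' @export
robust_se <- function(Delta, Gamma, w = diag(Gamma)) {
  WD <- Delta / w
  H <- crossprod(Delta, WD)
  Hinv <- tryCatch(solve(H), error = function(e)
    stop("rank-deficient Jacobian: model not locally identified at the ",
         "estimate"))
  meat <- crossprod(WD, Gamma %*% WD)
  acov <- Hinv %*% meat %*% Hinv
  list(se = sqrt(pmax(diag(acov), 0)), acov = acov)
}

#' Mean-and-variance-adjusted chi-square
#'
#' Scales the DWLS discrepancy so that its first two moments match a
#' reference chi-square (Satterthwaite-type second-order adjustment): with
#' `U = W^{-1} - W^{-1} D (D'W^{-1}D)^{-1} D'W^{-1}` and `M = U Gamma`,
#' the adjusted statistic is `T tr(M)/tr(M^2)` referred to
#' `df_eff = tr(M)^2/tr(M^2)`.
#'
#' @param T_raw raw discrepancy (`F_min` on the `Gamma` scale).
#' @param Delta Jacobian at the estimate (`NULL` for a model with no free
#'   parameters).
#' @param Gamma asymptotic covariance of the statistics.
#' @param df model degrees of freedom.
#' @param w optional weight vector (defaults to `diag(Gamma)`).
#' @return list `chi2_adj`, `df_eff`, `pvalue`, `trM`, `trM2`.
#' @export
adjusted_chi2 <- function(T_raw, Delta, Gamma, df, w = diag(Gamma)) {
  if (df <= 0)
    return(list(chi2_adj = 0, df_eff = 0, pvalue = NA_real_,
                trM = 0, trM2 = 0))
  Winv <- 1 / w
  if (is.null(Delta) || ncol(Delta) == 0) {
    M <- Winv * Gamma
  } else {
    WD <- Delta * Winv
    H <- crossprod(Delta, WD)
    P <- WD %*% solve(H, t(WD))
    M <- (Winv * Gamma) - P %*% Gamma
  }
  trM <- sum(diag(M))
  trM2 <- sum(M * t(M))
  chi2_adj <- T_raw * trM / trM2
  df_eff <- trM^2 / trM2
  list(chi2_adj = chi2_adj, df_eff = df_eff,
       pvalue = pchisq(chi2_adj, df_eff, lower.tail = FALSE),
       trM = trM, trM2 = trM2)
}

#' Fit indices from adjusted statistics
#'
#' CFI, TLI, RMSEA and the Raftery-style `BIC' = chi2 - df log(n)`
#' computed from the adjusted chi-squares of the target and baseline
#' (independence) models.  A saturated model (`df = 0`) gets `CFI = 1`,
#' `RMSEA = 0` by convention.
#'
#' @param chi2,df target-model adjusted chi-square and effective df.
#' @param chi2_b,df_b baseline-model values.
#' @param n sample size.
#' @return named numeric vector `cfi`, `tli`, `rmsea`, `bic_prime`.
#' @export
fit_indices <- function(chi2, df, chi2_b, df_b, n) {
  if (df <= 0)
    return(c(cfi = 1, tli = 1, rmsea = 0, bic_prime = 0))
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli <- if (df_b > 0 && chi2_b / df_b > 1)
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1) else 1
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  c(cfi = cfi, tli = tli, rmsea = rmsea,
    bic_prime = chi2 - df * log(n))
}

# Moment-informed start values on the spec's own metric
start_values <- function(spec, stats) {
  pt <- spec$pt
  start <- pt$start
  names(start) <- pt$name
  T <- spec$T; V <- spec$V
  upd <- function(nm, val) {
    i <- match(nm, pt$name)
    ok <- !is.na(i) & pt$free[i] & is.finite(val)
    start[i[ok]] <<- val[ok]
  }
  for (v in seq_len(V)) {
    cols <- (v - 1) * T + seq_len(T)
    tmat <- do.call(cbind, stats$tau[cols])
    C <- spec$C[v]
    vn <- if (V > 1) paste0(spec$var_names[v], "_") else ""
    binary <- C == 2
    if (spec$param == "standard" || (binary && spec$param == "alt1" &&
                                     spec$binary_alt1 == "myt")) {
      mu_h <- rep(0, T); sd_h <- rep(1, T)
    }
    if (spec$param == "standard") {
      for (t in 1:T) upd(sprintf("%stau%d_t%d", vn, 1:(C - 1), t), tmat[, t])
      mu_h <- rep(0, T); sd_h <- rep(1, T)
    } else if (binary) {
      ts <- drop(tmat)
      if (spec$param == "alt1" && spec$binary_alt1 == "myt") {
        upd(sprintf("%stau1", vn), ts[1])
        mu_h <- ts[1] - ts; sd_h <- rep(1, T)
      } else if (spec$param == "alt1") {
        upd(sprintf("%stau1", vn), ts[1])
        mu_h <- rep(0, T)
        sd_h <- if (all(abs(ts) > 1e-3)) ts[1] / ts else rep(1, T)
      } else {
        mu_h <- -ts; sd_h <- rep(1, T)
      }
    } else {
      am <- tryCatch(aux_affine(tmat, spec$param), error = function(e) NULL)
      if (is.null(am)) { mu_h <- rep(0, T); sd_h <- rep(1, T) }
      else {
        mu_h <- am$mu; sd_h <- am$sigma
        if (spec$invariant) {
          for (c in seq_len(C - 1))
            upd(sprintf("%stau%d", vn, c), mean(am$tau[c, ]))
        } else {
          upd(sprintf("%stau%d", vn, 1), am$tau[1, 1])
          upd(sprintf("%stau%d", vn, 2), am$tau[2, 1])
          if (C > 3) for (t in 1:T)
            upd(sprintf("%stau%d_t%d", vn, 3:(C - 1), t), am$tau[-(1:2), t])
        }
      }
    }
    # structural starts from the implied-by-sample moments in this metric
    Rv <- stats$R[cols, cols]
    Sig <- diag(sd_h) %*% Rv %*% diag(sd_h)
    if (spec$family == "aux") {
      upd(sprintf("%smustar_t%d", vn, 1:T), mu_h)
      upd(sprintf("%ssigstar_t%d", vn, 1:T), pmax(sd_h, 0.05))
    } else if (spec$family == "lgm") {
      L <- cbind(1, 0:(T - 1))
      mfit <- stats::lm.fit(L, mu_h)$coefficients
      upd("mu_alpha", mfit[1]); upd("mu_beta", mfit[2])
      pr <- pair_index(T)
      X <- cbind(1, pr[, 1] + pr[, 2] - 2, (pr[, 1] - 1) * (pr[, 2] - 1))
      yv <- Sig[pr]
      ps <- tryCatch(stats::lm.fit(X, yv)$coefficients,
                     error = function(e) c(0.3, 0, 0.05))
      upd("psi_aa", max(ps[1], 0.01))
      upd("psi_ab", ps[2])
      upd("psi_bb", max(ps[3], 0.005))
      G <- L %*% matrix(c(max(ps[1], 0.01), ps[2], ps[2],
                          max(ps[3], 0.005)), 2) %*% t(L)
      upd(sprintf("theta_t%d", 1:T), pmax(diag(Sig) - diag(G), 0.05))
    } else if (spec$family %in% c("ar1", "alt")) {
      rho_h <- vapply(2:T, function(t) Sig[t, t - 1] / Sig[t - 1, t - 1],
                      numeric(1))
      if (spec$family == "ar1") {
        upd(sprintf("rho_t%d", 2:T), rho_h)
        if (spec$stationary) upd("rho", mean(rho_h))
        upd("nu_t1", mu_h[1])
        upd(sprintf("nu_t%d", 2:T), mu_h[-1] - rho_h * mu_h[-T])
        th <- c(Sig[1, 1], vapply(2:T, function(t)
          Sig[t, t] - rho_h[t - 1]^2 * Sig[t - 1, t - 1], numeric(1)))
        upd(sprintf("theta_t%d", 1:T), pmax(th, 0.05))
      } else {
        upd(sprintf("rho_t%d", 2:T), 0.5 * rho_h)
        if (spec$stationary) upd("rho", 0.5 * mean(rho_h))
        upd("nu_t1", mu_h[1])
        L <- cbind(1, 0:(T - 1))
        mfit <- stats::lm.fit(L, mu_h - c(0, 0.5 * rho_h * mu_h[-T]))
        upd("mu_alpha", mfit$coefficients[1])
        upd("mu_beta", mfit$coefficients[2])
        upd(sprintf("theta_t%d", 1:T),
            pmax(0.4 * diag(Sig), 0.05))
      }
    }
  }
  if (spec$family == "malt") {
    # per-variable AR-style heuristics
    for (v in seq_len(V)) {
      cols <- (v - 1) * T + seq_len(T)
      Rv <- stats$R[cols, cols]
      rho_h <- vapply(2:T, function(t) Rv[t, t - 1], numeric(1))
      vn <- spec$var_names[v]
      upd(sprintf("b_%s_%s_t%d", vn, vn, 2:T), 0.5 * rho_h)
      if (spec$stationary) upd(sprintf("b_%s_%s", vn, vn), 0.5 * mean(rho_h))
    }
  }
  start[pt$free]
}

#' Diagonally weighted least squares fit
#'
#' Minimizes `F(theta) = (s - sigma(theta))' W^{-1} (s - sigma(theta))`
#' with `W = diag(Gamma)` over the free parameters of `spec`, from
#' multiple starting points (moment-informed, table defaults, perturbed),
#' refined by damped Gauss-Newton polishing.  Returns robust sandwich
#' standard errors, the raw and mean-and-variance-adjusted chi-square,
#' degrees of freedom, and fit indices against the independence baseline
#' (free thresholds, zero correlations).
#'
#' @param stats a [sample_stats()] object.
#' @param spec a [model_spec()] (dimensions must match the panel's).
#' @param start optional starting vector (free-parameter order).
#' @param n_starts number of additional perturbed starts.
#' @param control list: `rel_tol` (Gauss-Newton stopping, default 1e-12),
#'   `iter_max`.
#' @return object of class `fit_result`.
#' @export
dwls_fit <- function(stats, spec, start = NULL, n_starts = 2,
                     control = list()) {
  stopifnot(inherits(stats, "sample_stats"), inherits(spec, "model_spec"))
  p <- spec$V * spec$T
  if (length(stats$s) != sum(rep(spec$C, each = spec$T) - 1) + p * (p - 1) / 2)
    stop("statistics vector does not match the specification's dimensions")
  w <- diag(stats$Gamma)
  if (any(w <= 0)) stop("non-positive weight in diag(Gamma)")
  s <- stats$s
  free <- spec$free_ix
  pt <- spec$pt
  lo <- pt$lower[free]; hi <- pt$upper[free]

  objective <- function(th) {
    r <- s - implied_stats(spec, th)
    sum(r * r / w)
  }

  starts <- list()
  starts[[1]] <- if (is.null(start)) start_values(spec, stats) else start
  if (is.null(start)) {
    # deterministic perturbations (do not touch the global RNG stream)
    for (k in seq_len(max(n_starts - 1, 0)))
      starts[[1 + k]] <- starts[[1]] +
        0.12 * sin(seq_along(free) * 1.7 + k)
  }

  rel_tol <- control$rel_tol %||% 1e-12
  iter_max <- control$iter_max %||% 200

  # damped (Levenberg-style) Gauss-Newton: the DWLS objective is a
  # weighted least-squares problem, so this converges in a handful of
  # Jacobian evaluations from a decent start
  gauss_newton <- function(th) {
    th <- pmin(pmax(th, lo), hi)
    F0 <- objective(th)
    if (!is.finite(F0)) return(NULL)
    lambda <- 1e-8
    for (it in seq_len(iter_max)) {
      r <- s - implied_stats(spec, th)
      J <- num_jacobian(function(x) implied_stats(spec, x), th)
      WJ <- J / w
      H <- crossprod(J, WJ)
      g <- crossprod(WJ, r)
      improved <- FALSE
      for (tries in 1:12) {
        step <- tryCatch(drop(solve(H + lambda * diag(diag(H) + 1e-12),
                                    g)), error = function(e) NULL)
        if (!is.null(step)) {
          cand <- pmin(pmax(th + step, lo), hi)
          Fc <- objective(cand)
          if (is.finite(Fc) && Fc < F0) {
            improved <- Fc < F0 - rel_tol * (F0 + rel_tol)
            th <- cand; F0 <- Fc
            lambda <- max(lambda / 5, 1e-10)
            break
          }
        }
        lambda <- lambda * 8
      }
      if (!improved) break
    }
    list(par = th, objective = F0, iterations = it)
  }

  best <- NULL
  for (st0 in starts) {
    opt <- gauss_newton(st0)
    if (!is.null(opt) &&
        (is.null(best) || opt$objective < best$objective)) best <- opt
  }
  # quasi-Newton fallback when the least-squares path fails outright
  if (is.null(best)) {
    opt <- tryCatch(
      nlminb(pmin(pmax(starts[[1]], lo), hi), objective, lower = lo,
             upper = hi, control = list(eval.max = 5000, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(opt)) stop("all optimizer starts failed")
    best <- gauss_newton(opt$par) %||%
      list(par = opt$par, objective = opt$objective, iterations = NA)
  }
  th <- best$par
  F0 <- best$objective

  r <- s - implied_stats(spec, th)
  J <- num_jacobian(function(x) implied_stats(spec, x), th)
  WJ <- J / w
  grad <- drop(-2 * crossprod(WJ, r))
  df <- count_df(spec)
  T_raw <- F0

  rse <- tryCatch(robust_se(J, stats$Gamma, w), error = function(e) e)
  if (inherits(rse, "error")) {
    se <- rep(NA_real_, length(th)); acov <- NULL
    ident_ok <- FALSE
  } else {
    se <- rse$se; acov <- rse$acov; ident_ok <- TRUE
  }

  adj <- adjusted_chi2(T_raw, J, stats$Gamma, df, w)
  # independence baseline: free thresholds, zero correlations
  ntau <- length(s) - nrow(stats$pairs)
  Db <- rbind(diag(ntau), matrix(0, nrow(stats$pairs), ntau))
  rb <- c(rep(0, ntau), s[(ntau + 1):length(s)])
  Tb <- sum(rb^2 / w)
  dfb <- nrow(stats$pairs)
  adjb <- adjusted_chi2(Tb, Db, stats$Gamma, dfb, w)
  fi <- fit_indices(adj$chi2_adj, adj$df_eff, adjb$chi2_adj, adjb$df_eff,
                    stats$n)

  det <- implied_stats(spec, th, detail = TRUE)
  names(th) <- pt$name[free]
  names(se) <- names(th)
  heywood <- !det$admissible
  structure(list(theta = th, se_robust = se, acov = acov,
                 chi2 = T_raw, chi2_adj = adj$chi2_adj, df = df,
                 df_eff = adj$df_eff, pvalue = adj$pvalue,
                 baseline = list(chi2_adj = adjb$chi2_adj,
                                 df_eff = adjb$df_eff),
                 fit_indices = fi, F_min = F0,
                 converged = max(abs(grad)) < 1e-4 * (1 + T_raw) && ident_ok,
                 gradient_norm = max(abs(grad)), n_iter = best$iterations,
                 heywood = heywood, n = stats$n, spec = spec,
                 implied = det),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("DWLS fit: %s / %s%s  (n = %d)\n", x$spec$family,
              x$spec$param,
              if (x$spec$param != "standard" && x$spec$invariant)
                " (invariant thresholds)" else "", x$n))
  cat(sprintf("  chi2 = %.4f, adjusted chi2 = %.4f on df = %d (eff. %.2f), p = %s\n",
              x$chi2, x$chi2_adj, x$df, x$df_eff,
              ifelse(is.na(x$pvalue), "NA", sprintf("%.4f", x$pvalue))))
  fi <- x$fit_indices
  cat(sprintf("  CFI = %.3f  TLI = %.3f  RMSEA = %.3f  BIC' = %.2f\n",
              fi["cfi"], fi["tli"], fi["rmsea"], fi["bic_prime"]))
  if (!x$converged) cat("  WARNING: not converged (gradient norm ",
                        format(x$gradient_norm), ")\n", sep = "")
  if (x$heywood) cat("  NOTE: inadmissible solution (negative remainder ",
                     "variance or non-PSD growth covariance)\n", sep = "")
  est <- cbind(estimate = x$theta, se = x$se_robust)
  print(round(est, 4))
  invisible(x)
}
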