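# Stage 1: the auxiliary measurement layer linking each observed ordinal
# response y to its underlying normal variable y* through thresholds.
# Under the standard parameterization y*_t ~ N(0, 1) at every occasion and
# the thresholds are standard-normal percentiles of the cumulative margins;
# the alternative parameterizations re-express the same distribution with
# free means/variances and anchored thresholds.

#' Threshold estimates from a category margin
#'
#' Standard-parameterization thresholds: `tau_c = qnorm(P(y <= c-1))`.
#' Empty extreme categories give infinite thresholds; an empty interior
#' category gives tied thresholds, flagged as degenerate.
#'
#' @param margin one element of [margins()] (fields `counts`, `n`), or a
#'   vector of category counts.
#' @return numeric vector of `C-1` thresholds with attributes `boundary`
#'   (any infinite threshold) and `degenerate` (tied interior thresholds).
#' @export
estimate_thresholds <- function(margin) {
  cnt <- if (is.list(margin)) margin$counts else margin
  n <- sum(cnt)
  C <- length(cnt)
  tau <- qnorm(cumsum(cnt)[-C] / n)
  boundary <- any(!is.finite(tau))
  degenerate <- any(diff(tau) <= 0 & is.finite(tau[-1]) &
                      is.finite(tau[-length(tau)]))
  attr(tau, "boundary") <- boundary
  attr(tau, "degenerate") <- degenerate || any(duplicated(tau[is.finite(tau)]))
  tau
}

#' Pseudo maximum likelihood polychoric correlation
#'
#' Maximizes the Olsson log-likelihood of the bivariate contingency table
#' over the correlation, with the thresholds held fixed at their univariate
#' (margin) estimates -- the conditional two-step estimator.  The search is
#' a 1-D bounded maximization on the Fisher-z scale over
#' `rho in (-1+eps, 1-eps)`; cell probabilities below `1e-12` are floored
#' inside the log-likelihood only.
#'
#' @param tab contingency table of counts ([crosstab()]).
#' @param tau_row,tau_col fixed threshold vectors for the row and column
#'   variables.
#' @param eps boundary inset for the admissible interval.
#' @param tol convergence tolerance on rho.
#' @return list with `rho`, `loglik`, `boundary` (estimate within `1e-4`
#'   of +/-1), `degenerate` (table or thresholds unusable).
#' @export
polychoric_rho <- function(tab, tau_row, tau_col, eps = 1e-6, tol = 1e-8) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0 || any(!is.finite(tau_row)) || any(!is.finite(tau_col)))
    return(list(rho = NA_real_, loglik = NA_real_, boundary = TRUE,
                degenerate = TRUE))
  if (any(diff(tau_row) <= 0) || any(diff(tau_col) <= 0))
    return(list(rho = NA_real_, loglik = NA_real_, boundary = TRUE,
                degenerate = TRUE))
  nll <- function(z) -polychoric_loglik_cpp(tab, tau_row, tau_col,
                                            tanh(z), 1e-12)
  zmax <- atanh(1 - eps)
  opt <- optimize(nll, lower = -zmax, upper = zmax, tol = tol)
  rho <- tanh(opt$minimum)
  list(rho = rho, loglik = -opt$objective,
       boundary = abs(rho) > 1 - 1e-4, degenerate = FALSE)
}

# Stage-1 summary for a whole panel: thresholds per column and the full
# polychoric correlation matrix (standard parameterization).
stage1_estimates <- function(panel) {
  mg <- margins(panel)
  p <- ncol(panel$data)
  tau <- lapply(seq_len(p), function(j) estimate_thresholds(mg[[j]]))
  names(tau) <- colnames(panel$data)
  pairs <- pair_index(p)
  R <- diag(p)
  flags <- character(0)
  rho <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pc <- polychoric_rho(crosstab(panel, i, j), tau[[i]], tau[[j]])
    rho[r] <- pc$rho
    if (isTRUE(pc$boundary))
      flags <- c(flags, sprintf("pair (%d,%d) at or near boundary", i, j))
    R[i, j] <- R[j, i] <- pc$rho
  }
  dimnames(R) <- list(colnames(panel$data), colnames(panel$data))
  list(tau = tau, R = R, rho = rho, pairs = pairs, flags = flags,
       margins = mg, n = panel$n)
}

aux_parameterizations <- c("standard", "alt1", "alt1_inv", "alt2", "alt2_inv")

# closed-form occasion-affine maps between the no-invariance
# parameterizations of one variable's threshold block (C >= 3).
# 'tau_std' is the (C-1) x T matrix of standard-metric thresholds.
aux_affine <- function(tau_std, parameterization) {
  C1 <- nrow(tau_std); T <- ncol(tau_std)
  mu <- rep(0, T); sigma <- rep(1, T)
  tau <- tau_std
  if (parameterization == "standard") {
    # identity
  } else if (parameterization == "alt1") {
    if (C1 < 3) stop("alternative 1 requires at least 4 categories for a ",
                     "free third threshold; use the binary variants for C=2")
    for (t in 2:T) {
      sigma[t] <- (tau_std[2, 1] - tau_std[1, 1]) /
        (tau_std[2, t] - tau_std[1, t])
      mu[t] <- tau_std[1, 1] - sigma[t] * tau_std[1, t]
      tau[, t] <- mu[t] + sigma[t] * tau_std[, t]
    }
  } else if (parameterization == "alt2") {
    if (C1 < 2) stop("alternative 2 requires at least 3 categories")
    if (C1 == 1) stop("alternative 2 undefined for binary data")
    for (t in 1:T) {
      sigma[t] <- 1 / (tau_std[2, t] - tau_std[1, t])
      mu[t] <- -tau_std[1, t] * sigma[t]
      tau[, t] <- mu[t] + sigma[t] * tau_std[, t]
    }
  } else stop("unknown parameterization: ", parameterization)
  list(tau = tau, mu = mu, sigma = sigma)
}

#' Auxiliary-model estimate under a chosen parameterization
#'
#' Estimates the measurement layer of an ordinal panel: thresholds, the
#' means and standard deviations of the underlying variables, and the
#' polychoric correlation (standard) or covariance (alternative)
#' matrix.  For the no-invariance parameterizations (`"standard"`,
#' `"alt1"`, `"alt2"`) the estimate is an exact closed-form
#' reparameterization of the standard two-step estimate (the models are
#' just identified and fit identically); the `"_inv"` variants restrict
#' all thresholds to be time-invariant and are estimated by a DWLS fit of
#' the constrained auxiliary model (see [test_threshold_invariance()]).
#'
#' @param panel an [ordinal_panel()].
#' @param parameterization one of `"standard"`, `"alt1"`, `"alt1_inv"`,
#'   `"alt2"`, `"alt2_inv"`.  For binary variables the alternative-1 family
#'   maps to the Millsap-Yun-Tein (`binary_alt1 = "myt"`) or Muthen-Muthen
#'   (`"mm"`) constraint row and alternative 2 to the Joreskog row.
#' @param binary_alt1 binary pairing for the alternative-1 family.
#' @return object of class `auxiliary_estimate`: `tau` (list of per-column
#'   threshold vectors), `mu_star`, `sigma_star`, `P_star` (correlation or
#'   covariance matrix), `parameterization`, `flags`, plus the fit result
#'   for constrained variants.
#' @export
build_auxiliary <- function(panel, parameterization = "standard",
                            binary_alt1 = c("myt", "mm")) {
  stopifnot(inherits(panel, "ordinal_panel"))
  parameterization <- match.arg(parameterization, aux_parameterizations)
  binary_alt1 <- match.arg(binary_alt1)
  if (parameterization %in% c("alt2", "alt2_inv") && any(panel$C == 2))
    stop("alternative 2 requires C >= 3 ordered categories; for binary ",
         "variables use the Joreskog binary row via the '_inv' machinery ",
         "or the alternative 1 binary variants")

  st <- stage1_estimates(panel)
  V <- length(panel$var_names); T <- panel$T
  p <- ncol(panel$data)

  if (parameterization %in% c("alt1_inv", "alt2_inv")) {
    fit <- test_threshold_invariance(panel, parameterization,
                                     binary_alt1 = binary_alt1)
    return(structure(list(tau = fit$aux$tau, mu_star = fit$aux$mu_star,
                          sigma_star = fit$aux$sigma_star,
                          P_star = fit$aux$P_star,
                          parameterization = parameterization,
                          flags = st$flags, fit = fit, n = panel$n),
                     class = "auxiliary_estimate"))
  }

  mu_star <- rep(0, p); sigma_star <- rep(1, p)
  tau <- st$tau
  for (v in seq_len(V)) {
    cols <- (v - 1) * T + seq_len(T)
    tmat <- do.call(cbind, st$tau[cols])
    if (panel$C[v] == 2 && parameterization != "standard") {
      # binary rows of the constraint table (threshold invariance mandatory;
      # the model stays just identified so the maps are exact)
      ts <- drop(tmat)
      if (parameterization == "alt1" && binary_alt1 == "myt") {
        tau_inv <- ts[1]
        mu_star[cols] <- tau_inv - ts
        sigma_star[cols] <- 1
        for (t in seq_len(T)) tau[[cols[t]]] <- tau_inv
      } else if (parameterization == "alt1" && binary_alt1 == "mm") {
        tau_inv <- ts[1]
        if (any(abs(ts) < 1e-8) || any(sign(ts) != sign(ts[1])))
          stop("Muthen-Muthen binary map undefined when a standard ",
               "threshold is zero or changes sign across occasions")
        sigma_star[cols] <- tau_inv / ts
        mu_star[cols] <- 0
        for (t in seq_len(T)) tau[[cols[t]]] <- tau_inv
      } else { # alt2 -> Joreskog binary row: tau = 0, sigma = 1, mu free
        mu_star[cols] <- -ts
        sigma_star[cols] <- 1
        for (t in seq_len(T)) tau[[cols[t]]] <- 0
      }
    } else {
      am <- aux_affine(tmat, parameterization)
      mu_star[cols] <- am$mu
      sigma_star[cols] <- am$sigma
      for (t in seq_len(T)) tau[[cols[t]]] <- am$tau[, t]
    }
  }
  D <- diag(sigma_star, p)
  P_star <- D %*% st$R %*% D
  dimnames(P_star) <- dimnames(st$R)
  structure(list(tau = tau, mu_star = mu_star, sigma_star = sigma_star,
                 P_star = P_star, parameterization = parameterization,
                 flags = st$flags, n = panel$n),
            class = "auxiliary_estimate")
}

#' @export
print.auxiliary_estimate <- function(x, ...) {
  cat(sprintf("auxiliary estimate (%s parameterization), n = %d\n",
              x$parameterization, x$n))
  cat("mu*:    ", paste(sprintf("%.3f", x$mu_star), collapse = " "), "\n")
  cat("sigma*: ", paste(sprintf("%.3f", x$sigma_star), collapse = " "), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Map an auxiliary estimate into another no-invariance parameterization
#'
#' The no-invariance parameterizations describe one and the same
#' distribution for the underlying variables, so the map is the exact
#' occasion-wise affine change of scale `y* -> (y* - mu)/sigma`; round
#' trips are identities up to floating error.  Mapping into a constrained
#' (`_inv`) parameterization is refused: threshold invariance is a
#' restriction, not a reparameterization.
#'
#' @param aux an `auxiliary_estimate` from [build_auxiliary()].
#' @param target target parameterization (`"standard"`, `"alt1"`, `"alt2"`).
#' @return an `auxiliary_estimate` in the target parameterization.
#' @export
reparameterize <- function(aux, target) {
  stopifnot(inherits(aux, "auxiliary_estimate"))
  target <- match.arg(target, aux_parameterizations)
  if (grepl("_inv$", target))
    stop("threshold invariance is a restriction, not a reparameterization; ",
         "fit it with build_auxiliary(..., '", target, "')")
  if (grepl("_inv$", aux$parameterization))
    stop("constrained estimates cannot be reparameterized exactly")
  p <- length(aux$mu_star)
  # first return to the standard metric ...
  tau_std <- lapply(seq_len(p), function(j)
    (aux$tau[[j]] - aux$mu_star[j]) / aux$sigma_star[j])
  D <- diag(1 / aux$sigma_star, p)
  R <- D %*% aux$P_star %*% D
  # ... then apply the target map per variable block
  out <- aux
  out$parameterization <- target
  nb <- length(tau_std)
  # infer T from column names ("_t<k>")
  occ <- as.integer(sub(".*_t", "", names(aux$tau)))
  Tn <- max(occ)
  V <- nb / Tn
  mu_star <- rep(0, nb); sigma_star <- rep(1, nb)
  tau <- tau_std
  for (v in seq_len(V)) {
    cols <- (v - 1) * Tn + seq_len(Tn)
    tmat <- do.call(cbind, tau_std[cols])
    am <- aux_affine(tmat, target)
    mu_star[cols] <- am$mu; sigma_star[cols] <- am$sigma
    for (t in seq_len(Tn)) tau[[cols[t]]] <- am$tau[, t]
  }
  names(tau) <- names(aux$tau)
  Dt <- diag(sigma_star, nb)
  out$tau <- tau; out$mu_star <- mu_star; out$sigma_star <- sigma_star
  out$P_star <- Dt %*% R %*% Dt
  dimnames(out$P_star) <- dimnames(aux$P_star)
  out
}

#' Threshold-invariance ratio diagnostic
#'
#' If the thresholds of the alternative parameterizations are truly
#' time-invariant, the ratio of differences between any two
#' standard-parameterization thresholds at two occasions,
#' `(tau_c,t - tau_c',t) / (tau_c,t' - tau_c',t')`, is the same for every
#' threshold pair `(c, c')` (it equals the ratio of underlying standard
#' deviations).  Unequal ratios at an occasion pair indicate that at least
#' one threshold is not invariant there.
#'
#' @param aux a standard-parameterization `auxiliary_estimate`.
#' @param tol relative tolerance for the equality flags.
#' @return data.frame with one row per occasion pair and threshold-pair
#'   combination: `var`, `t1`, `t2`, `pair`, `ratio`, plus an attribute
#'   `flags` marking occasion pairs with unequal ratios.
#' @export
invariance_ratio_diagnostic <- function(aux, tol = 0.1) {
  stopifnot(inherits(aux, "auxiliary_estimate"))
  if (aux$parameterization != "standard")
    stop("diagnostic is defined on the standard parameterization")
  occ <- as.integer(sub(".*_t", "", names(aux$tau)))
  Tn <- max(occ)
  V <- length(aux$tau) / Tn
  rows <- list()
  for (v in seq_len(V)) {
    cols <- (v - 1) * Tn + seq_len(Tn)
    tmat <- do.call(cbind, aux$tau[cols])
    C1 <- nrow(tmat)
    if (C1 < 3)
      stop("ratio diagnostic needs at least 4 categories (two independent ",
           "threshold differences); C = ", C1 + 1)
    tp <- pair_index(C1)
    for (a in 1:(Tn - 1)) for (b in (a + 1):Tn) {
      for (r in seq_len(nrow(tp))) {
        c1 <- tp[r, 1]; c2 <- tp[r, 2]
        rows[[length(rows) + 1]] <- data.frame(
          var = v, t1 = a, t2 = b,
          pair = sprintf("(%d,%d)", c2, c1),
          ratio = (tmat[c2, a] - tmat[c1, a]) / (tmat[c2, b] - tmat[c1, b]))
      }
    }
  }
  out <- do.call(rbind, rows)
  # flag occasion pairs whose ratios disagree beyond tol (relative)
  key <- with(out, paste(var, t1, t2))
  flags <- vapply(split(out$ratio, key), function(r)
    diff(range(r)) > tol * max(abs(r)), logical(1))
  attr(out, "flags") <- flags
  out
}

#' Test threshold invariance by a constrained auxiliary fit
#'
#' Fits the auxiliary model in which each threshold is restricted to be
#' equal at all occasions (under the alternative-1 or alternative-2
#' anchoring) by diagonally weighted least squares, and returns the
#' adjusted chi-square, degrees of freedom and fit indices.  The two
#' anchorings describe the same restriction, so their chi-square and
#' degrees of freedom coincide.  For binary variables the restriction is
#' required for identification and is not testable.
#'
#' @param panel an [ordinal_panel()].
#' @param parameterization `"alt1_inv"` or `"alt2_inv"`.
#' @param stats optional precomputed [sample_stats()] for the panel.
#' @param binary_alt1 binary pairing for the alternative-1 family.
#' @return a `fit_result` (see [dwls_fit()]) with an extra element `aux`
#'   holding the constrained auxiliary estimate.
#' @export
test_threshold_invariance <- function(panel, parameterization = "alt1_inv",
                                      stats = NULL,
                                      binary_alt1 = c("myt", "mm")) {
  parameterization <- match.arg(parameterization, c("alt1_inv", "alt2_inv"))
  binary_alt1 <- match.arg(binary_alt1)
  if (all(panel$C == 2))
    stop("threshold invariance is required for identification with binary ",
         "data and is not testable")
  if (any(panel$C == 2) && parameterization == "alt2_inv" &&
      length(panel$C) == 1)
    stop("alternative 2 requires C >= 3")
  spec <- model_spec("aux", sub("_inv", "", parameterization),
                     n_occasions = panel$T, n_cat = panel$C,
                     invariant = TRUE, binary_alt1 = binary_alt1)
  if (is.null(stats)) stats <- sample_stats(panel)
  fit <- dwls_fit(stats, spec)
  fit$aux <- aux_from_fit(fit, spec, stats)
  fit
}

# package a fitted aux-family model as an auxiliary_estimate
aux_from_fit <- function(fit, spec, stats) {
  p <- spec$V * spec$T
  imp <- implied_stats(spec, fit$theta, detail = TRUE)
  sigma_star <- imp$sigma_star
  mu_star <- imp$mu_star
  tau <- imp$tau_model
  D <- diag(sigma_star, p)
  P_star <- D %*% imp$R %*% D
  structure(list(tau = tau, mu_star = mu_star, sigma_star = sigma_star,
                 P_star = P_star,
                 parameterization = paste0(spec$param, "_inv"),
                 flags = character(0), n = stats$n),
            class = "auxiliary_estimate")
}
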