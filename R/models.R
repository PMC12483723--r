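# Structural specifications for the underlying variables.
#
# A model_spec couples a structural family (linear growth "lgm", first-order
# autoregressive "ar1", autoregressive latent trajectory "alt", multivariate
# ALT "malt", or the saturated auxiliary layer "aux") with an identification
# parameterization of the threshold layer:
#
#   standard : mu*_t = 0, sd*_t = 1 on every occasion, thresholds free and
#              time-specific (the Mplus/lavaan default).  `placement`
#              decides whether the variance constraint sits on the
#              underlying variables ("delta") or the errors ("theta").
#   alt1     : occasion-one anchoring (Millsap & Yun-Tein / Muthen &
#              Asparouhov): mu*_1 = 0, sd*_1 = 1, later means/variances
#              free; two thresholds time-invariant, or all of them when
#              `invariant = TRUE`.
#   alt2     : threshold anchoring (Joreskog / Mehta): tau_1 = 0, tau_2 = 1
#              on every occasion, all means/variances free; remaining
#              thresholds free or time-invariant.
#
# Binary variables use the corresponding rows of the binary constraint
# table: alt1 maps to Millsap-Yun-Tein ("myt") or Muthen-Muthen ("mm"),
# alt2 to the Joreskog binary row (threshold fixed at zero).
#
# Internally a spec holds a parameter table (one row per model parameter,
# fixed or free) plus index maps so that the implied first- and
# second-order statistics of the underlying variables can be evaluated
# quickly from the free-parameter vector.

#' Construct a structural model specification
#'
#' @param family `"lgm"`, `"ar1"`, `"alt"`, `"malt"` or `"aux"` (the
#'   saturated auxiliary model, used for threshold-invariance testing).
#' @param param `"standard"`, `"alt1"` or `"alt2"`.
#' @param n_occasions occasions per variable.
#' @param n_cat categories per variable (scalar for univariate families).
#' @param invariant logical; restrict every threshold to be time-invariant
#'   (the `_inv` variants).  Ignored for `param = "standard"`.
#' @param placement `"delta"` (constraints on underlying-variable
#'   variances) or `"theta"` (constraints on error variances).  Families
#'   with autoregressive components use the theta side automatically.
#' @param stationary logical; force autoregressive (and cross-lagged)
#'   coefficients equal over time.
#' @param binary_alt1 `"myt"` or `"mm"`: which binary constraint row the
#'   alternative-1 family uses for binary variables.
#' @param var_names optional variable labels (malt/aux).
#' @param cross_lagged logical `V x V` matrix (malt): which lag-1 paths are
#'   free; diagonal entries are the autoregressions and always free.
#' @param concomitant logical (malt): include same-occasion error
#'   covariances between variables.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family, param = "standard", n_occasions, n_cat,
                       invariant = TRUE, placement = c("delta", "theta"),
                       stationary = FALSE, binary_alt1 = c("myt", "mm"),
                       var_names = NULL, cross_lagged = NULL,
                       concomitant = TRUE) {
  family <- match.arg(family, c("lgm", "ar1", "alt", "malt", "aux"))
  param <- match.arg(param, c("standard", "alt1", "alt2"))
  placement <- match.arg(placement)
  binary_alt1 <- match.arg(binary_alt1)
  T <- as.integer(n_occasions)
  C <- as.integer(n_cat)
  if (T < 2) stop("need at least two occasions")
  V <- if (family %in% c("malt", "aux")) length(C) else 1L
  if (family %in% c("lgm", "ar1", "alt") && length(C) != 1)
    stop("univariate families take a single category count")
  # binary variables under alt2 use the Joreskog binary row (threshold
  # fixed at zero); the ordinal tau_1 = 0, tau_2 = 1 anchoring needs C >= 3
  # and is rejected inside the threshold builder.
  if (is.null(var_names)) var_names <- paste0("y", seq_len(V))

  spec <- structure(list(family = family, param = param, T = T, C = C,
                         V = V, invariant = invariant,
                         placement = placement, stationary = stationary,
                         binary_alt1 = binary_alt1, var_names = var_names,
                         concomitant = concomitant),
                    class = "model_spec")
  if (family == "malt") {
    if (is.null(cross_lagged)) {
      cross_lagged <- matrix(TRUE, V, V)
    }
    diag(cross_lagged) <- TRUE
    spec$cross_lagged <- cross_lagged
  }
  spec <- build_par_table(spec)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  inv <- if (x$param == "standard") "" else
    if (x$invariant) " (invariant thresholds)" else " (partial invariance)"
  cat(sprintf("model_spec: %s / %s%s, T = %d, C = %s, %d free parameters\n",
              x$family, x$param, inv, x$T, paste(x$C, collapse = ","),
              sum(x$pt$free)))
  cat(sprintf("  statistics: %d thresholds + %d correlations, df = %d\n",
              sum(rep(x$C, each = x$T) - 1),
              (x$V * x$T) * (x$V * x$T - 1) / 2, count_df(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# parameter-table construction

new_pt <- function() {
  env <- new.env()
  env$name <- character(0); env$free <- logical(0)
  env$value <- numeric(0); env$start <- numeric(0)
  env$lower <- numeric(0); env$upper <- numeric(0)
  env
}

addpar <- function(pt, name, free, value = NA_real_, start = 0,
                   lower = -Inf, upper = Inf) {
  i <- match(name, pt$name)
  if (!is.na(i)) return(i)           # shared parameter: reuse the row
  pt$name <- c(pt$name, name); pt$free <- c(pt$free, free)
  pt$value <- c(pt$value, value); pt$start <- c(pt$start, start)
  pt$lower <- c(pt$lower, lower); pt$upper <- c(pt$upper, upper)
  length(pt$name)
}

# threshold rows for one variable: returns (C-1) x T index matrix
add_thresholds <- function(pt, spec, v) {
  T <- spec$T; C <- spec$C[v]
  vn <- if (spec$V > 1) paste0(spec$var_names[v], "_") else ""
  ix <- matrix(0L, C - 1, T)
  binary <- C == 2
  par <- spec$param
  tau0 <- qnorm(seq_len(C - 1) / C)  # generic equispaced starts
  for (t in seq_len(T)) for (c in seq_len(C - 1)) {
    nm <- sprintf("%stau%d_t%d", vn, c, t)
    shared <- sprintf("%stau%d", vn, c)
    if (par == "standard") {
      ix[c, t] <- addpar(pt, nm, TRUE, start = tau0[c])
    } else if (binary) {
      # binary rows: myt/mm share the single threshold, joreskog fixes it
      if (par == "alt2") ix[c, t] <- addpar(pt, shared, FALSE, value = 0)
      else ix[c, t] <- addpar(pt, shared, TRUE, start = tau0[c])
    } else if (par == "alt1") {
      if (spec$invariant || c <= 2)
        ix[c, t] <- addpar(pt, shared, TRUE, start = tau0[c])
      else ix[c, t] <- addpar(pt, nm, TRUE, start = tau0[c])
    } else { # alt2
      if (c == 1) ix[c, t] <- addpar(pt, shared, FALSE, value = 0)
      else if (c == 2) ix[c, t] <- addpar(pt, shared, FALSE, value = 1)
      else if (spec$invariant)
        ix[c, t] <- addpar(pt, shared, TRUE, start = c - 1.5)
      else ix[c, t] <- addpar(pt, nm, TRUE, start = c - 1.5)
    }
  }
  ix
}

# variance side for one variable: list(theta_ix (T), remainder (T) logical)
# kind: how each occasion's scale is handled under this spec
add_variances <- function(pt, spec, v, predetermined) {
  T <- spec$T; C <- spec$C[v]
  vn <- if (spec$V > 1) paste0(spec$var_names[v], "_") else ""
  binary <- C == 2
  par <- spec$param
  theta_ix <- integer(T); remainder <- logical(T)
  fix1 <- function(t) addpar(pt, sprintf("%stheta_t%d", vn, t), FALSE,
                             value = 1)
  # free error variances are unbounded below (Heywood solutions are
  # reported as inadmissible, not prevented); this keeps specifications
  # whose counterpart expresses the same variance as an unconstrained
  # remainder exactly equivalent
  free1 <- function(t) addpar(pt, sprintf("%stheta_t%d", vn, t), TRUE,
                              start = 0.8)
  rem1 <- function(t) {
    i <- addpar(pt, sprintf("%stheta_t%d", vn, t), FALSE, value = NA_real_)
    remainder[t] <<- TRUE
    i
  }
  if (par == "standard") {
    if (spec$placement == "delta" && !predetermined) {
      for (t in 1:T) theta_ix[t] <- rem1(t)        # sd*_t = 1, theta remainder
    } else {
      for (t in 1:T) theta_ix[t] <- fix1(t)        # theta_t = 1 fixed
    }
  } else if (binary) {
    if (par == "alt1" && spec$binary_alt1 == "myt") {
      for (t in 1:T) theta_ix[t] <- rem1(t)        # sd*_t = 1 on every t
    } else if (par == "alt1") {                    # Muthen-Muthen
      theta_ix[1] <- if (predetermined) fix1(1) else rem1(1)  # sd*_1 = 1
      for (t in 2:T) theta_ix[t] <- free1(t)
    } else {                                       # Joreskog binary
      for (t in 1:T) theta_ix[t] <- rem1(t)        # sd*_t = 1 on every t
    }
  } else if (par == "alt1") {
    # anchor the scale at occasion one
    if (spec$placement == "theta" && !predetermined) {
      theta_ix[1] <- fix1(1)                       # Model D: theta_1 = 1
    } else if (predetermined) {
      theta_ix[1] <- fix1(1)                       # var(y*_1) = psi_11 = 1
    } else {
      theta_ix[1] <- rem1(1)                       # Model C: sd*_1 = 1
    }
    for (t in 2:T) theta_ix[t] <- free1(t)
  } else { # alt2: every variance free
    for (t in 1:T) theta_ix[t] <- free1(t)
  }
  list(theta_ix = theta_ix, remainder = remainder)
}

build_par_table <- function(spec) {
  pt <- new_pt()
  T <- spec$T; V <- spec$V
  ix <- list()
  fam <- spec$family

  if (fam == "aux") {
    ix$tau <- lapply(seq_len(V), function(v) add_thresholds(pt, spec, v))
    ix$mustar <- ix$sigstar <- vector("list", V)
    for (v in seq_len(V)) {
      vn <- if (V > 1) paste0(spec$var_names[v], "_") else ""
      binary <- spec$C[v] == 2
      mi <- integer(T); si <- integer(T)
      for (t in 1:T) {
        mnm <- sprintf("%smustar_t%d", vn, t)
        snm <- sprintf("%ssigstar_t%d", vn, t)
        if (spec$param == "standard") {
          mi[t] <- addpar(pt, mnm, FALSE, value = 0)
          si[t] <- addpar(pt, snm, FALSE, value = 1)
        } else if (binary) {
          if (spec$param == "alt1" && spec$binary_alt1 == "myt") {
            mi[t] <- addpar(pt, mnm, t > 1, value = if (t == 1) 0 else NA)
            si[t] <- addpar(pt, snm, FALSE, value = 1)
          } else if (spec$param == "alt1") { # mm
            mi[t] <- addpar(pt, mnm, FALSE, value = 0)
            si[t] <- addpar(pt, snm, t > 1, value = if (t == 1) 1 else NA,
                            start = 1, lower = 1e-3)
          } else {                           # joreskog binary
            mi[t] <- addpar(pt, mnm, TRUE)
            si[t] <- addpar(pt, snm, FALSE, value = 1)
          }
        } else if (spec$param == "alt1") {
          mi[t] <- addpar(pt, mnm, t > 1, value = if (t == 1) 0 else NA)
          si[t] <- addpar(pt, snm, t > 1, value = if (t == 1) 1 else NA,
                          start = 1, lower = 1e-3)
        } else {
          mi[t] <- addpar(pt, mnm, TRUE)
          si[t] <- addpar(pt, snm, TRUE, start = 1, lower = 1e-3)
        }
      }
      ix$mustar[[v]] <- mi; ix$sigstar[[v]] <- si
    }
    p <- V * T
    pr <- pair_index(p)
    ix$r <- integer(nrow(pr))
    for (k in seq_len(nrow(pr)))
      ix$r[k] <- addpar(pt, sprintf("r_%d_%d", pr[k, 1], pr[k, 2]), TRUE,
                        start = 0.3, lower = -0.999, upper = 0.999)
  } else if (fam %in% c("lgm", "ar1", "alt")) {
    predet <- fam %in% c("ar1", "alt")
    ix$tau <- list(add_thresholds(pt, spec, 1))
    vv <- add_variances(pt, spec, 1, predetermined = predet)
    ix$theta <- vv$theta_ix; ix$remainder <- vv$remainder

    if (fam %in% c("ar1", "alt")) {
      ix$rho <- integer(T - 1)
      for (t in 2:T) {
        nm <- if (spec$stationary) "rho" else sprintf("rho_t%d", t)
        ix$rho[t - 1] <- addpar(pt, nm, TRUE, start = 0.3,
                                lower = -5, upper = 5)
      }
    }
    if (fam == "ar1") {
      ix$nu <- integer(T)
      free_nu1 <- spec$param == "alt2"
      free_nut <- spec$param != "standard"
      if (spec$C[1] == 2 && spec$param == "alt1" &&
          spec$binary_alt1 == "mm") free_nut <- FALSE  # means fixed at zero
      ix$nu[1] <- addpar(pt, "nu_t1", free_nu1, value = if (free_nu1) NA else 0)
      for (t in 2:T)
        ix$nu[t] <- addpar(pt, sprintf("nu_t%d", t), free_nut,
                           value = if (free_nut) NA else 0)
    }
    if (fam %in% c("lgm", "alt")) {
      # growth-factor means; under standard both zero, under alt1 the
      # occasion-one mean anchor pins mu_alpha (lgm) / nu_1 (alt)
      if (fam == "lgm") {
        free_ma <- spec$param == "alt2"
        free_mb <- spec$param != "standard"
        if (spec$C[1] == 2 && spec$param != "standard") {
          free_ma <- spec$param == "alt2" ||
            (spec$param == "alt1" && FALSE)
          free_mb <- !(spec$param == "alt1" && spec$binary_alt1 == "mm")
          if (spec$param == "alt1" && spec$binary_alt1 == "mm") free_ma <- FALSE
        }
        ix$mu_eta <- c(addpar(pt, "mu_alpha", free_ma,
                              value = if (free_ma) NA else 0),
                       addpar(pt, "mu_beta", free_mb,
                              value = if (free_mb) NA else 0))
      } else {
        free_nu1 <- spec$param == "alt2"
        free_mu <- spec$param != "standard"
        if (spec$C[1] == 2 && spec$param == "alt1" &&
            spec$binary_alt1 == "mm") free_mu <- FALSE
        ix$nu1 <- addpar(pt, "nu_t1", free_nu1, value = if (free_nu1) NA else 0)
        ix$mu_eta <- c(addpar(pt, "mu_alpha", free_mu,
                              value = if (free_mu) NA else 0),
                       addpar(pt, "mu_beta", free_mu,
                              value = if (free_mu) NA else 0))
      }
      ix$psi <- c(addpar(pt, "psi_aa", TRUE, start = 0.5, lower = 1e-6),
                  addpar(pt, "psi_ab", TRUE, start = 0),
                  addpar(pt, "psi_bb", TRUE, start = 0.1, lower = 1e-6))
    }
    if (fam == "alt")
      ix$psi1 <- c(addpar(pt, "psi_1a", TRUE, start = 0),
                   addpar(pt, "psi_1b", TRUE, start = 0))
  } else { # malt
    ix$tau <- lapply(seq_len(V), function(v) add_thresholds(pt, spec, v))
    ix$theta <- matrix(0L, V, T); ix$remainder <- matrix(FALSE, V, T)
    for (v in seq_len(V)) {
      vv <- add_variances(pt, spec, v, predetermined = TRUE)
      ix$theta[v, ] <- vv$theta_ix; ix$remainder[v, ] <- vv$remainder
    }
    # lag-1 coefficient blocks b_<to>_<from>_t (diagonal = autoregressive)
    ix$B <- array(0L, c(V, V, T - 1))
    for (t in 2:T) for (a in seq_len(V)) for (b in seq_len(V)) {
      if (!spec$cross_lagged[a, b] && a != b) {
        ix$B[a, b, t - 1] <- addpar(pt, sprintf("b_%s_%s_zero",
                                                spec$var_names[a],
                                                spec$var_names[b]),
                                    FALSE, value = 0)
      } else {
        nm <- if (spec$stationary)
          sprintf("b_%s_%s", spec$var_names[a], spec$var_names[b])
        else sprintf("b_%s_%s_t%d", spec$var_names[a], spec$var_names[b], t)
        ix$B[a, b, t - 1] <- addpar(pt, nm, TRUE,
                                    start = if (a == b) 0.2 else 0,
                                    lower = -5, upper = 5)
      }
    }
    # occasion-one means and growth means per variable
    ix$nu1 <- integer(V); ix$mu_eta <- matrix(0L, V, 2)
    for (v in seq_len(V)) {
      vn <- spec$var_names[v]
      free_nu1 <- spec$param == "alt2" && spec$C[v] > 2
      free_mu <- spec$param != "standard"
      if (spec$C[v] == 2 && spec$param == "alt1" &&
          spec$binary_alt1 == "mm") free_mu <- FALSE
      ix$nu1[v] <- addpar(pt, sprintf("%s_nu_t1", vn), free_nu1,
                          value = if (free_nu1) NA else 0)
      ix$mu_eta[v, ] <- c(addpar(pt, sprintf("%s_mu_alpha", vn), free_mu,
                                 value = if (free_mu) NA else 0),
                          addpar(pt, sprintf("%s_mu_beta", vn), free_mu,
                                 value = if (free_mu) NA else 0))
    }
    # growth-factor covariance (2V x 2V, full), predetermined covariances
    gnames <- as.vector(t(outer(spec$var_names, c("alpha", "beta"),
                                function(a, b) paste0(a, "_", b))))
    ix$psi_g <- matrix(0L, 2 * V, 2 * V)
    for (i in seq_len(2 * V)) for (j in i:(2 * V)) {
      ix$psi_g[i, j] <- ix$psi_g[j, i] <-
        addpar(pt, sprintf("psi_%s_%s", gnames[i], gnames[j]), TRUE,
               start = if (i == j) 0.3 else 0,
               lower = if (i == j) 1e-6 else -Inf)
    }
    ix$psi_1g <- matrix(0L, V, 2 * V)
    for (v in seq_len(V)) for (j in seq_len(2 * V))
      ix$psi_1g[v, j] <- addpar(pt, sprintf("psi1_%s_%s", spec$var_names[v],
                                            gnames[j]), TRUE, start = 0)
    # occasion-one covariances between variables
    ix$psi_11 <- matrix(0L, V, V)
    if (V > 1) for (v in 1:(V - 1)) for (w in (v + 1):V)
      ix$psi_11[v, w] <- ix$psi_11[w, v] <-
      addpar(pt, sprintf("psi11_%s_%s", spec$var_names[v],
                         spec$var_names[w]), TRUE, start = 0)
    # concomitant (same-occasion) error covariances, time-invariant
    ix$conc <- matrix(0L, V, V)
    if (spec$concomitant && V > 1) for (v in 1:(V - 1)) for (w in (v + 1):V)
      ix$conc[v, w] <- ix$conc[w, v] <-
      addpar(pt, sprintf("cove_%s_%s", spec$var_names[v],
                         spec$var_names[w]), TRUE, start = 0)
  }

  spec$pt <- data.frame(name = pt$name, free = pt$free, value = pt$value,
                        start = pt$start, lower = pt$lower, upper = pt$upper,
                        stringsAsFactors = FALSE)
  spec$ix <- ix
  spec$free_ix <- which(spec$pt$free)
  spec$pairs <- pair_index(spec$V * spec$T)
  if (!is.null(ix$remainder)) {
    tv <- ix$remainder
    tv[] <- ifelse(ix$remainder, 1, NA_real_)
    spec$target_var <- tv
  }
  spec
}

#' Free parameters of a specification
#' @param spec a [model_spec()].
#' @return character vector of free parameter names (the order of the
#'   parameter vector used by [dwls_fit()]).
#' @export
free_params <- function(spec) spec$pt$name[spec$pt$free]

# expand a free-parameter vector into the full named parameter vector
full_params <- function(spec, theta) {
  v <- spec$pt$value
  v[spec$free_ix] <- theta
  names(v) <- spec$pt$name
  v
}

# ---------------------------------------------------------------------------
# implied moments (direct recursions)

#' Implied moments of the linear growth model
#'
#' `mu = Lambda mu_eta`, `Sigma = Lambda Psi_eta Lambda' + Theta` with
#' `Lambda` the `T x 2` matrix of rows `(1, t-1)`.  Occasions whose
#' underlying-variable variance is constrained to one receive their error
#' variance as a remainder.
#'
#' @param mu_eta growth-factor means `(mu_alpha, mu_beta)`.
#' @param psi_eta `2 x 2` growth-factor covariance.
#' @param theta_eps length-`T` error variances (`NA` where determined as a
#'   remainder).
#' @param T number of occasions.
#' @param target_var length-`T` vector: `1` where `var(y*_t)` is fixed at
#'   one (remainder occasions), `NA` elsewhere.
#' @return list `mu`, `Sigma`, `theta_eps` (with remainders resolved),
#'   `admissible` (no negative remainder or non-PSD growth covariance).
#' @export
implied_moments_lgm <- function(mu_eta, psi_eta, theta_eps, T,
                                target_var = rep(NA_real_, T)) {
  L <- cbind(1, 0:(T - 1))
  G <- L %*% psi_eta %*% t(L)
  rem <- is.na(theta_eps)
  theta_eps[rem] <- target_var[rem] - diag(G)[rem]
  Sigma <- G + diag(theta_eps, T)
  list(mu = drop(L %*% mu_eta), Sigma = Sigma, theta_eps = theta_eps,
       admissible = all(theta_eps > 0) && is_psd(psi_eta))
}

#' Implied moments of the first-order autoregressive model
#'
#' `y*_1` is predetermined with mean `nu_1` and variance `theta_1`;
#' `y*_t = nu_t + rho_t y*_{t-1} + eps_t` for `t >= 2`.  Equivalent to the
#' reduced form `mu = (I-B)^{-1} nu`, `Sigma = (I-B)^{-1} Psi (I-B)^{-T}`.
#'
#' @param nu length-`T` intercepts (first element = predetermined mean).
#' @param rho length-`T-1` autoregressive coefficients (`rho[t-1]` acts at
#'   occasion `t`).
#' @param theta_eps,T,target_var as in [implied_moments_lgm()]; the first
#'   element is the predetermined variance `psi_11`.
#' @return list `mu`, `Sigma`, `theta_eps`, `admissible`.
#' @export
implied_moments_ar1 <- function(nu, rho, theta_eps, T,
                                target_var = rep(NA_real_, T)) {
  S <- matrix(0, T, T); m <- numeric(T)
  if (is.na(theta_eps[1])) theta_eps[1] <- target_var[1]
  m[1] <- nu[1]; S[1, 1] <- theta_eps[1]
  for (t in 2:T) {
    r <- rho[t - 1]
    m[t] <- nu[t] + r * m[t - 1]
    S[t, 1:(t - 1)] <- r * S[t - 1, 1:(t - 1)]
    S[1:(t - 1), t] <- S[t, 1:(t - 1)]
    prop <- r^2 * S[t - 1, t - 1]
    if (is.na(theta_eps[t])) theta_eps[t] <- target_var[t] - prop
    S[t, t] <- prop + theta_eps[t]
  }
  list(mu = m, Sigma = S, theta_eps = theta_eps,
       admissible = all(theta_eps > 0))
}

#' Implied moments of the autoregressive latent trajectory model
#'
#' `y*_1` is predetermined (mean `nu1`, variance `theta_1`, covariances
#' `psi_1eta` with the growth factors); for `t >= 2`,
#' `y*_t = rho_t y*_{t-1} + alpha + (t-1) beta + eps_t`.  Means are driven
#' by the growth-factor means, not by free occasion intercepts.  Setting
#' all `rho = 0` (with `nu1`, `theta_1`, `psi_1eta` matching) reduces to
#' the growth model; zero growth variance and means reduce to AR(1).
#'
#' @param nu1 predetermined mean of `y*_1`.
#' @param mu_eta,psi_eta growth-factor means and covariance.
#' @param psi_1eta covariances of `y*_1` with `(alpha, beta)`.
#' @param rho,theta_eps,T,target_var as in [implied_moments_ar1()].
#' @return list `mu`, `Sigma`, `theta_eps`, `admissible`.
#' @export
implied_moments_alt <- function(nu1, mu_eta, psi_eta, psi_1eta, rho,
                                theta_eps, T,
                                target_var = rep(NA_real_, T)) {
  S <- matrix(0, T, T); m <- numeric(T)
  ca <- numeric(T); cb <- numeric(T)   # cov(y*_t, alpha), cov(y*_t, beta)
  if (is.na(theta_eps[1])) theta_eps[1] <- target_var[1]
  m[1] <- nu1; S[1, 1] <- theta_eps[1]
  ca[1] <- psi_1eta[1]; cb[1] <- psi_1eta[2]
  for (t in 2:T) {
    r <- rho[t - 1]; lam <- t - 1
    m[t] <- r * m[t - 1] + mu_eta[1] + lam * mu_eta[2]
    ca[t] <- r * ca[t - 1] + psi_eta[1, 1] + lam * psi_eta[1, 2]
    cb[t] <- r * cb[t - 1] + psi_eta[1, 2] + lam * psi_eta[2, 2]
    for (s in 1:(t - 1))
      S[t, s] <- S[s, t] <- r * S[t - 1, s] + ca[s] + lam * cb[s]
    prop <- r * S[t, t - 1] + ca[t] + lam * cb[t]
    if (is.na(theta_eps[t])) theta_eps[t] <- target_var[t] - prop
    S[t, t] <- prop + theta_eps[t]
  }
  # admissibility includes the joint covariance of the predetermined
  # variable with the growth factors (the process must be realizable)
  S3 <- rbind(c(theta_eps[1], psi_1eta), cbind(psi_1eta, psi_eta))
  list(mu = m, Sigma = S, theta_eps = theta_eps,
       admissible = all(theta_eps > 0) && is_psd(S3))
}

#' Implied moments of the multivariate autoregressive latent trajectory model
#'
#' Stacks `V` series sharing `T` occasions.  The lag-1 coefficient matrix
#' `B[, , t-1]` carries autoregressive (diagonal) and cross-lagged
#' (off-diagonal) effects of occasion `t-1` on occasion `t`; each series
#' has its own intercept/slope pair; errors of different series may
#' covary at the same occasion (concomitant effects, `conc`).
#'
#' @param nu1 length-`V` predetermined means.
#' @param mu_eta `V x 2` growth-factor means.
#' @param psi_g `2V x 2V` growth-factor covariance (order: alpha_1, beta_1,
#'   alpha_2, beta_2, ...).
#' @param psi_1g `V x 2V` covariances of the predetermined variables with
#'   the growth factors.
#' @param psi_11 `V x V` covariance of the predetermined variables
#'   (diagonal supplied through `theta_eps[, 1]`).
#' @param B `V x V x (T-1)` lag-1 coefficient array.
#' @param conc `V x V` same-occasion error covariance (zero diagonal).
#' @param theta_eps `V x T` error variances (`NA` = remainder).
#' @param T occasions; `target_var` `V x T` remainder targets.
#' @return list `mu`, `Sigma` (both over the `V*T` stacked vector,
#'   variable-block major), `theta_eps`, `admissible`.
#' @export
implied_moments_malt <- function(nu1, mu_eta, psi_g, psi_1g, psi_11, B,
                                 conc, theta_eps, T,
                                 target_var = matrix(NA_real_,
                                                     nrow(theta_eps), T)) {
  V <- length(nu1)
  p <- V * T
  idx <- function(v, t) (v - 1L) * T + t
  m <- numeric(p); S <- matrix(0, p, p)
  CG <- matrix(0, p, 2 * V)            # cov(y*_{v,t}, growth factors)
  gmu <- as.vector(t(mu_eta))          # (alpha_1, beta_1, alpha_2, ...)
  # occasion 1: predetermined block
  for (v in seq_len(V)) {
    if (is.na(theta_eps[v, 1])) theta_eps[v, 1] <- target_var[v, 1]
    m[idx(v, 1)] <- nu1[v]
    CG[idx(v, 1), ] <- psi_1g[v, ]
  }
  for (v in seq_len(V)) for (w in seq_len(V))
    S[idx(v, 1), idx(w, 1)] <- if (v == w) theta_eps[v, 1] else psi_11[v, w]
  for (t in 2:T) {
    lam <- t - 1
    Bt <- matrix(B[, , t - 1], V, V)
    prev <- idx(seq_len(V), t - 1L)
    cur <- idx(seq_len(V), t)
    L <- matrix(0, V, 2 * V)
    for (v in seq_len(V)) { L[v, 2 * v - 1] <- 1; L[v, 2 * v] <- lam }
    m[cur] <- drop(Bt %*% m[prev] + L %*% gmu)
    CG[cur, ] <- Bt %*% CG[prev, , drop = FALSE] + L %*% psi_g
    done <- as.vector(vapply(seq_len(V), function(v) idx(v, 1:(t - 1)),
                             integer(t - 1)))
    S[cur, done] <- Bt %*% S[prev, done, drop = FALSE] +
      L %*% t(CG[done, , drop = FALSE])
    S[done, cur] <- t(S[cur, done])
    # same-occasion block: propagated part + concomitant error covariance
    A <- CG[prev, , drop = FALSE]
    prop <- Bt %*% S[prev, prev, drop = FALSE] %*% t(Bt) +
      Bt %*% A %*% t(L) + L %*% t(A) %*% t(Bt) + L %*% psi_g %*% t(L)
    for (v in seq_len(V))
      if (is.na(theta_eps[v, t])) theta_eps[v, t] <-
        target_var[v, t] - prop[v, v]
    E <- conc; diag(E) <- theta_eps[, t]
    S[cur, cur] <- prop + E
  }
  # realizability: joint predetermined/growth covariance and the
  # same-occasion error covariance must both be PSD
  P11 <- psi_11; diag(P11) <- theta_eps[, 1]
  S0 <- rbind(cbind(P11, psi_1g), cbind(t(psi_1g), psi_g))
  Em <- conc; diag(Em) <- apply(theta_eps[, -1, drop = FALSE], 1, min)
  list(mu = m, Sigma = S, theta_eps = theta_eps,
       admissible = all(theta_eps > 0) && is_psd(S0) && is_psd(Em))
}

# ---------------------------------------------------------------------------
# generic reduced-form evaluator (independent oracle for the recursions)

#' Reduced-form moments of a linear structural system
#'
#' Evaluates `mu_eta = (I - B)^{-1} nu` and
#' `Sigma_eta = (I - B)^{-1} Psi (I - B)^{-T}` for the full latent vector
#' `eta` and returns the block belonging to its first `nsel` elements (the
#' underlying variables).  This generic evaluator is deliberately
#' independent of the family-specific recursions and serves as their
#' cross-check.
#'
#' @param nu intercept/mean vector.
#' @param B coefficient matrix (strictly lower block-triangular in time).
#' @param Psi disturbance covariance.
#' @param nsel how many leading elements of `eta` are observed-side
#'   underlying variables.
#' @return list `mu`, `Sigma` for the selected block (plus the full
#'   moments as `mu_eta`, `Sigma_eta`).
#' @export
reduced_form_moments <- function(nu, B, Psi, nsel = length(nu)) {
  IB <- diag(nrow(B)) - B
  mu_eta <- solve(IB, nu)
  Minv <- solve(IB)
  Sigma_eta <- Minv %*% Psi %*% t(Minv)
  list(mu = mu_eta[seq_len(nsel)],
       Sigma = Sigma_eta[seq_len(nsel), seq_len(nsel), drop = FALSE],
       mu_eta = mu_eta, Sigma_eta = Sigma_eta)
}

# assemble (nu, B, Psi) for a univariate family with resolved error
# variances; used by tests and check_identification as the oracle route
reduced_form_system <- function(family, T, nu = numeric(T),
                                rho = numeric(T - 1), theta_eps,
                                mu_eta = c(0, 0),
                                psi_eta = matrix(0, 2, 2),
                                psi_1eta = c(0, 0)) {
  if (family == "lgm") {
    q <- T + 2
    B <- matrix(0, q, q)
    B[1:T, T + 1] <- 1
    B[1:T, T + 2] <- 0:(T - 1)
    nuf <- c(rep(0, T), mu_eta)
    Psi <- matrix(0, q, q)
    diag(Psi)[1:T] <- theta_eps
    Psi[T + 1:2, T + 1:2] <- psi_eta
    return(list(nu = nuf, B = B, Psi = Psi, nsel = T))
  }
  if (family == "ar1") {
    B <- matrix(0, T, T)
    for (t in 2:T) B[t, t - 1] <- rho[t - 1]
    return(list(nu = nu, B = B, Psi = diag(theta_eps, T), nsel = T))
  }
  # alt: eta = (y*_1..y*_T, alpha, beta)
  q <- T + 2
  B <- matrix(0, q, q)
  for (t in 2:T) {
    B[t, t - 1] <- rho[t - 1]
    B[t, T + 1] <- 1
    B[t, T + 2] <- t - 1
  }
  nuf <- c(nu[1], rep(0, T - 1), mu_eta)
  Psi <- matrix(0, q, q)
  diag(Psi)[1:T] <- theta_eps
  Psi[T + 1:2, T + 1:2] <- psi_eta
  Psi[1, T + 1:2] <- Psi[T + 1:2, 1] <- psi_1eta
  list(nu = nuf, B = B, Psi = Psi, nsel = T)
}

# assemble the stacked (nu, B, Psi) system of a multivariate ALT spec with
# error variances already resolved; feeds reduced_form_moments as the
# independent oracle for implied_moments_malt
malt_system <- function(spec, theta) {
  ex <- expand_params(spec, theta)
  mom <- implied_moments(spec, theta)        # resolves remainder variances
  V <- spec$V; T <- spec$T
  p <- V * T; q <- p + 2 * V
  idx <- function(v, t) (v - 1L) * T + t
  B <- matrix(0, q, q)
  nu <- numeric(q)
  Psi <- matrix(0, q, q)
  th <- mom$theta_eps
  for (v in seq_len(V)) {
    nu[idx(v, 1)] <- ex$nu1[v]
    Psi[idx(v, 1), idx(v, 1)] <- th[v, 1]
    Psi[idx(v, 1), p + 1:(2 * V)] <- ex$psi_1g[v, ]
    Psi[p + 1:(2 * V), idx(v, 1)] <- ex$psi_1g[v, ]
    for (w in seq_len(V)) if (w != v)
      Psi[idx(v, 1), idx(w, 1)] <- ex$psi_11[v, w]
  }
  nu[p + 1:(2 * V)] <- as.vector(t(ex$mu_eta))
  Psi[p + 1:(2 * V), p + 1:(2 * V)] <- ex$psi_g
  for (t in 2:T) for (v in seq_len(V)) {
    i <- idx(v, t)
    for (w in seq_len(V)) B[i, idx(w, t - 1)] <- ex$B[v, w, t - 1]
    B[i, p + 2 * v - 1] <- 1
    B[i, p + 2 * v] <- t - 1
    Psi[i, i] <- th[v, t]
    for (w in seq_len(V)) if (w != v)
      Psi[i, idx(w, t)] <- ex$conc[v, w]
  }
  list(nu = nu, B = B, Psi = Psi, nsel = p)
}

# ---------------------------------------------------------------------------
# implied statistics in the standard metric

# expand free parameters into family structures
expand_params <- function(spec, theta) {
  v <- full_params(spec, theta)
  ix <- spec$ix
  fam <- spec$family
  T <- spec$T; V <- spec$V
  tau_model <- vector("list", V * T)
  for (vv in seq_len(V)) {
    M <- ix$tau[[vv]]
    for (t in seq_len(T))
      tau_model[[(vv - 1) * T + t]] <- v[M[, t]]
  }
  out <- list(tau_model = tau_model)
  if (fam == "aux") {
    out$mustar <- as.vector(vapply(seq_len(V), function(vv)
      v[ix$mustar[[vv]]], numeric(T)))
    out$sigstar <- as.vector(vapply(seq_len(V), function(vv)
      v[ix$sigstar[[vv]]], numeric(T)))
    p <- V * T
    R <- diag(p)
    pr <- spec$pairs
    for (k in seq_len(nrow(pr)))
      R[pr[k, 1], pr[k, 2]] <- R[pr[k, 2], pr[k, 1]] <- v[ix$r[k]]
    out$R <- R
  } else if (fam %in% c("lgm", "ar1", "alt")) {
    th <- v[ix$theta]
    out$theta_eps <- unname(th)
    out$target_var <- spec$target_var
    out$theta_eps[ix$remainder] <- NA_real_
    if (fam != "lgm") out$rho <- unname(v[ix$rho])
    if (fam == "ar1") out$nu <- unname(v[ix$nu])
    if (fam %in% c("lgm", "alt")) {
      out$mu_eta <- unname(v[ix$mu_eta])
      psi <- v[ix$psi]
      out$psi_eta <- matrix(c(psi[1], psi[2], psi[2], psi[3]), 2, 2)
    }
    if (fam == "alt") {
      out$nu1 <- unname(v[ix$nu1])
      out$psi_1eta <- unname(v[ix$psi1])
    }
  } else { # malt
    out$theta_eps <- matrix(v[ix$theta], V, spec$T)
    out$target_var <- spec$target_var
    out$theta_eps[ix$remainder] <- NA_real_
    out$B <- array(v[ix$B], dim(ix$B))
    out$nu1 <- unname(v[ix$nu1])
    out$mu_eta <- matrix(v[ix$mu_eta], V, 2)
    out$psi_g <- matrix(v[ix$psi_g], 2 * V, 2 * V)
    out$psi_1g <- matrix(v[ix$psi_1g], V, 2 * V)
    P11 <- matrix(0, V, V)
    if (V > 1) { P11[ix$psi_11 != 0] <- v[ix$psi_11[ix$psi_11 != 0]] }
    out$psi_11 <- P11
    conc <- matrix(0, V, V)
    if (spec$concomitant && V > 1)
      conc[ix$conc != 0] <- v[ix$conc[ix$conc != 0]]
    out$conc <- conc
  }
  out
}

# model-implied moments of the underlying variables for any family
implied_moments <- function(spec, theta) {
  ex <- expand_params(spec, theta)
  T <- spec$T
  switch(spec$family,
    lgm = implied_moments_lgm(ex$mu_eta, ex$psi_eta, ex$theta_eps, T,
                              ex$target_var),
    ar1 = implied_moments_ar1(ex$nu, ex$rho, ex$theta_eps, T,
                              ex$target_var),
    alt = implied_moments_alt(ex$nu1, ex$mu_eta, ex$psi_eta, ex$psi_1eta,
                              ex$rho, ex$theta_eps, T, ex$target_var),
    malt = implied_moments_malt(ex$nu1, ex$mu_eta, ex$psi_g, ex$psi_1g,
                                ex$psi_11, ex$B, ex$conc, ex$theta_eps, T,
                                ex$target_var),
    aux = {
      D <- diag(ex$sigstar, length(ex$sigstar))
      list(mu = ex$mustar, Sigma = D %*% ex$R %*% D,
           theta_eps = NULL, admissible = TRUE)
    })
}

#' Model-implied statistics in the standard metric
#'
#' Maps a specification's free-parameter vector to the statistics the
#' DWLS fit targets: standardized thresholds
#' `(tau_model - mu*) / sd*` for every variable-occasion column, followed
#' by the implied correlations of the underlying variables
#' (lower-triangle, pair order `(1,2), (1,3), ...`).  All
#' parameterizations imply this common vector, which is what makes their
#' chi-squares comparable.
#'
#' @param spec a [model_spec()].
#' @param theta free-parameter vector.
#' @param detail logical; return the components (`tau_std`, `R`,
#'   `mu_star`, `sigma_star`, `tau_model`, `admissible`) instead of the
#'   stacked vector.
#' @return numeric vector (or a list when `detail = TRUE`).
#' @export
implied_stats <- function(spec, theta, detail = FALSE) {
  ex <- expand_params(spec, theta)
  mom <- implied_moments(spec, theta)
  p <- spec$V * spec$T
  sdv <- sqrt(pmax(diag(mom$Sigma), 1e-12))
  R <- mom$Sigma / tcrossprod(sdv)
  tau_std <- lapply(seq_len(p), function(j)
    (ex$tau_model[[j]] - mom$mu[j]) / sdv[j])
  pr <- spec$pairs
  svec <- c(unlist(tau_std), R[pr])
  if (!detail) return(svec)
  list(s = svec, tau_std = tau_std, R = R, mu_star = mom$mu,
       sigma_star = sdv, tau_model = ex$tau_model,
       admissible = mom$admissible)
}

# ---------------------------------------------------------------------------
# degrees of freedom and identification

#' Degrees of freedom of a specification
#'
#' Sample information is the count of univariate threshold statistics,
#' `sum_v T (C_v - 1)`, plus the `p(p-1)/2` polychoric correlations of the
#' stacked underlying vector; the degrees of freedom subtract the number
#' of free parameters.
#'
#' @param spec a [model_spec()].
#' @return integer degrees of freedom.
#' @export
count_df <- function(spec) {
  p <- spec$V * spec$T
  nstat <- sum((rep(spec$C, each = spec$T)) - 1) + p * (p - 1) / 2
  as.integer(nstat - sum(spec$pt$free))
}

# draw an admissible random parameter vector near the table starts
random_admissible <- function(spec, scale = 0.4, max_tries = 200) {
  pt <- spec$pt
  st <- pt$start[pt$free]
  lo <- pt$lower[pt$free]; hi <- pt$upper[pt$free]
  for (k in seq_len(max_tries)) {
    th <- st + runif(length(st), -scale, scale)
    # keep variance-like parameters safely positive
    th <- pmin(pmax(th, ifelse(is.finite(lo), lo + 0.05, -Inf)),
               ifelse(is.finite(hi), hi - 0.05, Inf))
    ok <- tryCatch({
      det <- implied_stats(spec, th, detail = TRUE)
      all(is.finite(det$s)) && det$admissible &&
        all(vapply(det$tau_std, function(x)
          length(x) < 2 || all(diff(x) > 1e-3), logical(1)))
    }, error = function(e) FALSE)
    if (ok) return(th)
  }
  stop("could not find an admissible random parameter vector")
}

#' Local identification check by Jacobian rank
#'
#' Evaluates the Jacobian of the implied-statistics map at random
#' admissible parameter vectors and inspects its singular values.  Full
#' column rank at every probe point indicates local identification; a
#' deficient rank reports the null-space direction (which parameters trade
#' off).
#'
#' @param spec a [model_spec()].
#' @param n_draws number of random probe points.
#' @param tol relative singular-value tolerance.
#' @param seed RNG seed for the probe draws.
#' @return list with `identified` (`"yes"`/`"no"`), `rank`, `n_free`,
#'   `min_sv_ratio`, and (when deficient) `null_direction`, a named vector
#'   over the free parameters.
#' @export
check_identification <- function(spec, n_draws = 10, tol = 1e-8,
                                 seed = 1) {
  set.seed(seed)
  nf <- sum(spec$pt$free)
  worst <- Inf; worst_sv <- NULL; ranks <- integer(0)
  for (d in seq_len(n_draws)) {
    th <- random_admissible(spec)
    J <- num_jacobian(function(x) implied_stats(spec, x), th)
    sv <- svd(J, nu = 0)
    ratio <- sv$d[nf] / sv$d[1]
    ranks <- c(ranks, sum(sv$d > tol * sv$d[1]))
    if (ratio < worst) { worst <- ratio; worst_sv <- sv }
  }
  rank <- min(ranks)
  out <- list(identified = if (rank == nf) "yes" else "no",
              rank = rank, n_free = nf, min_sv_ratio = worst,
              ranks = ranks)
  if (rank < nf) {
    nd <- worst_sv$v[, nf]
    names(nd) <- free_params(spec)
    out$null_direction <- nd
  }
  out
}
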