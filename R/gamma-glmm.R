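# Gamma log-link mixed model with a single random intercept (group) and an
# optional log-linear submodel for the Gamma dispersion parameter.
#
# Marginal likelihood is obtained by the Laplace approximation: the random
# intercepts enter the linear predictor additively, so the inner mode is a
# one-dimensional Newton problem per group with closed-form first and second
# derivatives, vectorized over groups. The outer problem (fixed effects,
# dispersion coefficients, log random-effect SD) is solved with BFGS.

# Conditional Gamma log-density pieces. eta = linear predictor (log mean),
# lphi = log dispersion; shape k = exp(-lphi).
.gamma_ll <- function(y, eta, lphi) {
  k <- exp(-lphi)
  sum(k * (-lphi - eta) + (k - 1) * log(y) - k * y * exp(-eta) - lgamma(k))
}

# Laplace marginal negative log-likelihood.
# par = c(beta, gamma, log_sigma?); X (n x p), Zd (n x q) dispersion design,
# gi = integer group index (or NULL for fixed-effects-only).
.ggmm_nll <- function(par, y, X, Zd, gi, n_groups, random, cache = NULL) {
  p <- ncol(X); q <- ncol(Zd)
  beta <- par[seq_len(p)]
  gam <- par[p + seq_len(q)]
  eta0 <- drop(X %*% beta)
  lphi <- drop(Zd %*% gam)
  if (any(!is.finite(eta0)) || any(!is.finite(lphi)) || any(abs(lphi) > 30))
    return(1e10)
  if (!random) {
    ll <- .gamma_ll(y, eta0, lphi)
    return(if (is.finite(ll)) -ll else 1e10)
  }
  lsig <- par[p + q + 1]
  if (!is.finite(lsig) || abs(lsig) > 20) return(1e10)
  sigma <- exp(lsig)
  k <- exp(-lphi)
  # warm-start the inner modes from the previous outer evaluation
  b <- if (!is.null(cache) && length(cache$b) == n_groups) cache$b
       else numeric(n_groups)
  # damped Newton for the per-group conditional modes, all groups at once
  for (iter in 1:100) {
    eta <- eta0 + b[gi]
    w <- k * y * exp(-eta)                       # -d2/db2 contributions
    g1 <- rowsum(w - k, gi, reorder = TRUE)[, 1] - b / sigma^2
    g2 <- -rowsum(w, gi, reorder = TRUE)[, 1] - 1 / sigma^2
    step <- g1 / g2
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 1), -1)              # trust region vs exp overflow
    b <- b - step
    if (any(!is.finite(b))) return(1e10)
    if (max(abs(g1)) < 1e-10 || max(abs(step)) < 1e-12) break
  }
  eta <- eta0 + b[gi]
  ll_cond <- .gamma_ll(y, eta, lphi)
  w <- k * y * exp(-eta)
  neg_g2 <- rowsum(w, gi, reorder = TRUE)[, 1] + 1 / sigma^2
  ll <- ll_cond - sum(b^2) / (2 * sigma^2) - n_groups * log(sigma) -
    0.5 * sum(log(neg_g2))
  if (!is.finite(ll)) return(1e10)
  if (!is.null(cache)) cache$b <- b
  -ll
}

#' Fit a Gamma log-link (mixed) model with optional dispersion submodel
#'
#' Workhorse behind [fit_seasonal_glmm()] and [fit_dispersion_model()].
#' The mean model is `log mu = X beta + b[group]`, `b ~ N(0, sigma^2)`; the
#' dispersion model is `log phi = Zd gamma` (constant when `Zd` is a column
#' of ones). Estimation maximizes the Laplace-approximate marginal
#' likelihood. A fitted random-effect SD below `singular_tol` raises the
#' `singular` flag and the model is refitted without the random term
#' (fixed-effects maximum likelihood), mirroring the usual fallback when a
#' random intercept is unsupported by the data.
#'
#' @param y Positive response vector.
#' @param X Fixed-effects design matrix (with intercept column).
#' @param group Factor (or NULL for a fixed-effects model).
#' @param Zd Dispersion design matrix; default a constant column.
#' @param singular_tol Random-SD threshold below which the fit is declared
#'   singular (default 1e-4).
#' @param se Compute Wald standard errors from the numerical Hessian
#'   (default TRUE); `FALSE` skips the Hessian, roughly halving the cost when
#'   only the likelihood is needed (e.g. simulation-based calibration of
#'   likelihood-ratio tests).
#' @return Object of class `gamma_glmm_fit`: `coefficients` (fixed), `se`,
#'   `zval`, `pval`, `disp_coefficients` (+ `disp_se`), `sigma` (random-int.
#'   SD), `loglik`, `aic`, `bic`, `n`, `convergence`, `singular`, `random`.
#' @export
gamma_glmm <- function(y, X, group = NULL, Zd = NULL, singular_tol = 1e-4,
                       se = TRUE) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Gamma response must be strictly positive and finite", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(Zd)) Zd <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Zd <- as.matrix(Zd)
  random <- !is.null(group)
  gi <- NULL; n_groups <- 0L
  if (random) {
    group <- droplevels(factor(group))
    gi <- as.integer(group)
    n_groups <- nlevels(group)
  }
  p <- ncol(X); q <- ncol(Zd)

  # starting values from the fixed-effects Gamma GLM
  st <- stats::glm.fit(X, y, family = stats::Gamma(link = "log"))
  beta0 <- st$coefficients
  phi0 <- sum((y / st$fitted.values - 1)^2) / max(1, length(y) - p)
  gam0 <- c(log(max(phi0, 1e-4)), rep(0, q - 1))
  par0 <- c(beta0, gam0, if (random) log(0.3))

  cache <- new.env(parent = emptyenv())
  fitted_opt <- stats::optim(par0, .ggmm_nll, y = y, X = X, Zd = Zd, gi = gi,
                             n_groups = n_groups, random = random,
                             cache = cache,
                             method = "BFGS", hessian = se,
                             control = list(maxit = 500, reltol = 1e-10))
  singular <- FALSE
  if (random) {
    sigma_hat <- exp(fitted_opt$par[p + q + 1])
    # a variance estimated at, or numerically indistinguishable from, zero:
    # either the SD collapses outright, or it is small (log scale, i.e. CV
    # units) and removing the random term costs essentially no likelihood
    near_zero <- sigma_hat < singular_tol
    if (!near_zero && sigma_hat < 0.1) {
      fixed_fit <- gamma_glmm(y, X, group = NULL, Zd = Zd, se = FALSE)
      near_zero <- 2 * (-fitted_opt$value - fixed_fit$loglik) < 1e-3
    }
    if (near_zero) {
      refit <- gamma_glmm(y, X, group = NULL, Zd = Zd, se = se)
      refit$singular <- TRUE
      refit$sigma <- 0
      return(refit)
    }
  }
  par <- fitted_opt$par
  se_all <- if (se) {
    V <- tryCatch(solve(fitted_opt$hessian),
                  error = function(e) matrix(NA_real_, length(par), length(par)))
    suppressWarnings(sqrt(diag(V)))
  } else rep(NA_real_, length(par))
  beta <- par[seq_len(p)]; names(beta) <- colnames(X)
  se <- se_all[seq_len(p)]; names(se) <- colnames(X)
  gam <- par[p + seq_len(q)]; names(gam) <- colnames(Zd)
  gam_se <- se_all[p + seq_len(q)]; names(gam_se) <- colnames(Zd)
  k <- length(par)
  ll <- -fitted_opt$value
  zval <- beta / se
  structure(list(
    coefficients = beta, se = se, zval = zval,
    pval = 2 * stats::pnorm(-abs(zval)),
    disp_coefficients = gam, disp_se = gam_se,
    sigma = if (random) unname(exp(par[p + q + 1])) else 0,
    loglik = ll, aic = -2 * ll + 2 * k,
    bic = -2 * ll + log(length(y)) * k,
    n = length(y), n_groups = n_groups, n_par = k,
    convergence = fitted_opt$convergence == 0,
    singular = singular, random = random,
    X = X, Zd = Zd), class = "gamma_glmm_fit")
}

#' @export
print.gamma_glmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<gamma_glmm_fit: n = %d, logLik = %.4g, AIC = %.4g%s%s>\n",
              x$n, x$loglik, x$aic,
              if (x$random || x$sigma > 0) sprintf(", group SD = %.4g", x$sigma) else " (no random effect)",
              if (x$singular) " [singular]" else ""))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$zval, p = x$pval)
  print(format(tab, digits = digits))
  if (length(x$disp_coefficients) > 1) {
    cat("dispersion submodel (log scale):\n")
    print(format(data.frame(estimate = x$disp_coefficients, se = x$disp_se),
                 digits = digits))
  }
  invisible(x)
}

#' @export
logLik.gamma_glmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n, class = "logLik")
}
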