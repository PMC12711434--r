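# Census-scale inference: rural/urban rank contrasts, the resource x
# settlement Gamma GLM with rate ratios, and the sensitivity analysis
# (two-sample power and its Mann-Whitney AUC / Cliff's delta equivalents).

#' Two-sided Mann-Whitney U / Wilcoxon rank-sum test
#'
#' Reports both statistic conventions: `U` (number of (x, y) pairs with
#' x > y, counting ties as 1/2) and `W` (rank sum of the first sample). The
#' p-value is exact when `min(n1, n2) <= 8` and there are no ties, otherwise
#' a normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return An object of class `rank_test` with fields `U`, `W`, `p.value`,
#'   `exact` (logical), `continuity`, `n1`, `n2`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
rank_sum_test <- function(x, y, continuity = TRUE) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(n1, n2) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = continuity,
                       alternative = "two.sided"))
  U <- unname(ht$statistic)            # wilcox.test's W is the Mann-Whitney U for x
  structure(list(U = U, W = U + n1 * (n1 + 1) / 2, p.value = ht$p.value,
                 exact = exact, continuity = continuity && !exact,
                 n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (rank-sum W = %g), p = %.4g [%s%s]\n",
              x$U, x$W, x$p.value,
              if (x$exact) "exact" else "normal approximation",
              if (x$continuity) ", continuity corrected" else ""))
  invisible(x)
}

# --- Gamma GLM on census sites ----------------------------------------------

#' Build the census model frame from a list of sites
#'
#' @param sites List of [census_site()] objects.
#' @return data.frame with `site_id`, `settlement` (factor, reference rural),
#'   `resource_density`, `dog_density`, and sex-restricted densities.
#' @export
census_frame <- function(sites) {
  out <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$id,
               settlement = s$settlement,
               area_ha = s$area_ha,
               resource_density = resource_density(s),
               dog_density = dog_density(s),
               male_density = dog_density(s, "M"),
               female_density = dog_density(s, "F"),
               stringsAsFactors = FALSE)
  }))
  out$settlement <- factor(out$settlement, levels = c("rural", "urban"))
  out
}

#' Fit the census Gamma GLM: dog density ~ resource density x settlement
#'
#' Log-link Gamma GLM of dogs per hectare on resource score per hectare,
#' settlement type (reference: rural) and their interaction. Mean structure
#' `mu = exp(b0 + b1 resource + b2 urban + b3 resource:urban)`, variance
#' `phi mu^2`. Wald t statistics use the dispersion-adjusted covariance.
#' Sites with zero dog density violate the Gamma support and are dropped
#' (logged in `n_dropped`); alternatively a small positive `zero_offset` can
#' be added to every response.
#'
#' @param sites List of [census_site()] objects, or a [census_frame()]-style
#'   data.frame.
#' @param zero_offset Constant added to the response (default 0; when 0,
#'   zero-density sites are dropped instead).
#' @return A `model_fit` object; see [model_fit_table()].
#' @export
fit_census_glm <- function(sites, zero_offset = 0) {
  df <- if (is.data.frame(sites)) sites else census_frame(sites)
  stopifnot(all(c("dog_density", "resource_density", "settlement") %in% names(df)))
  df$settlement <- factor(df$settlement, levels = c("rural", "urban"))
  n0 <- nrow(df)
  if (zero_offset > 0) df$dog_density <- df$dog_density + zero_offset
  keep <- is.finite(df$dog_density) & df$dog_density > 0 &
    is.finite(df$resource_density)
  df <- df[keep, , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0)
    message(sprintf("fit_census_glm: dropped %d site(s) with non-positive dog density", n_dropped))
  for (lev in c("rural", "urban"))
    if (sum(df$settlement == lev) < 2)
      stop(sprintf("need >= 2 usable sites in the %s stratum", lev), call. = FALSE)
  fit <- stats::glm(dog_density ~ resource_density * settlement,
                    family = stats::Gamma(link = "log"), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  .as_model_fit(fit, n_dropped = n_dropped, rate_ratios = TRUE)
}

# Wrap a glm/lm into the package's fit container.
.as_model_fit <- function(fit, n_dropped = 0, rate_ratios = FALSE) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  tab <- data.frame(term = rownames(co),
                    estimate = co[, 1], std.error = co[, 2],
                    statistic = co[, 3], p.value = co[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (rate_ratios) {
    tab$rate_ratio <- exp(tab$estimate)
    z <- stats::qnorm(0.975)
    tab$rr_ci_low <- exp(tab$estimate - z * tab$std.error)
    tab$rr_ci_high <- exp(tab$estimate + z * tab$std.error)
  }
  disp <- if (inherits(fit, "glm")) sm$dispersion else sm$sigma^2
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    table = tab,
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    deviance = stats::deviance(fit),
    null_deviance = if (inherits(fit, "glm")) fit$null.deviance else NA_real_,
    df_residual = stats::df.residual(fit),
    aic = stats::AIC(fit),
    loglik = ll,
    dispersion = disp,
    n = stats::nobs(fit),
    n_dropped = n_dropped,
    fit = fit), class = "model_fit")
}

#' Coefficient table of a fitted model
#'
#' @param x A `model_fit`.
#' @return data.frame with term, estimate, SE, statistic, p-value and (for
#'   log-link fits) rate ratios with 95% Wald CIs.
#' @export
model_fit_table <- function(x) {
  stopifnot(inherits(x, "model_fit"))
  x$table
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<model_fit: n = %d (%d dropped), deviance = %.4g, AIC = %.4g, dispersion = %.4g>\n",
              x$n, x$n_dropped, x$deviance, x$aic, x$dispersion))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Combined (urban) resource slope of the census GLM
#'
#' The resource-density slope within a settlement stratum: the rural slope is
#' `b1`; the urban slope is `b1 + b3` with standard error
#' `sqrt(var1 + var3 + 2 cov13)` from the fitted covariance.
#'
#' @param fit A `model_fit` from [fit_census_glm()].
#' @param level `"urban"` (default) or `"rural"`.
#' @return Named list with `slope`, `se`, `statistic`, `p.value` (Wald t with
#'   the fit's residual df).
#' @export
combined_slope <- function(fit, level = c("urban", "rural")) {
  stopifnot(inherits(fit, "model_fit"))
  level <- match.arg(level)
  b <- fit$coefficients
  V <- fit$vcov
  i1 <- "resource_density"
  i3 <- grep(":", names(b), value = TRUE)
  if (!(i1 %in% names(b)) || length(i3) != 1)
    stop("fit does not contain resource and interaction terms", call. = FALSE)
  if (level == "rural") {
    slope <- b[[i1]]; se <- sqrt(V[i1, i1])
  } else {
    slope <- b[[i1]] + b[[i3]]
    se <- sqrt(V[i1, i1] + V[i3, i3] + 2 * V[i1, i3])
  }
  stat <- slope / se
  list(slope = unname(slope), se = unname(se), statistic = unname(stat),
       p.value = 2 * stats::pt(-abs(stat), df = fit$df_residual))
}

# --- Sensitivity analysis ----------------------------------------------------

#' Power of the two-sided two-sample t test
#'
#' Noncentral-t formulation: with `df = n1 + n2 - 2` and noncentrality
#' `ncp = d / sqrt(1/n1 + 1/n2)`, power is the probability that |T| exceeds
#' the two-sided critical value.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param d Cohen's standardized mean difference (>= 0).
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return Power as a probability.
#' @export
#' @examples
#' two_sample_power(52, 41, d = 0.6)  # ~0.81
two_sample_power <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, d >= 0)
  df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  q <- stats::qt(1 - alpha / 2, df)
  stats::pt(q, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp = ncp)
}

#' Effect size achieving a target power
#'
#' Inverts [two_sample_power()] in `d` by bisection on (0, 10) to an absolute
#' power tolerance of 1e-8.
#'
#' @inheritParams two_sample_power
#' @param target_power Desired power, in (alpha, 1).
#' @return Cohen's d.
#' @export
d_for_power <- function(target_power, n1, n2, alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  lo <- 0; hi <- 10
  if (two_sample_power(n1, n2, hi, alpha) < target_power)
    stop("target power unattainable for d < 10", call. = FALSE)
  repeat {
    mid <- (lo + hi) / 2
    p <- two_sample_power(n1, n2, mid, alpha)
    if (abs(p - target_power) < 1e-8 || (hi - lo) < 1e-12) return(mid)
    if (p < target_power) lo <- mid else hi <- mid
  }
}

#' Normal-shift equivalences: Cohen's d, Mann-Whitney AUC, Cliff's delta
#'
#' Under a normal shift of size d between two populations, the probability
#' that a random draw from the shifted population exceeds one from the
#' reference population is `AUC = pnorm(d / sqrt(2))`; Cliff's delta is
#' `2 AUC - 1`.
#'
#' @param d Cohen's d.
#' @return AUC in (0, 1).
#' @export
#' @examples
#' d_to_auc(0)  # 0.5
d_to_auc <- function(d) {
  stopifnot(all(is.finite(d)))
  stats::pnorm(d / sqrt(2))
}

#' @rdname d_to_auc
#' @param auc Mann-Whitney AUC in [0, 1].
#' @return Cliff's delta in [-1, 1].
#' @export
auc_to_cliffs <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  2 * auc - 1
}
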