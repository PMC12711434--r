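# Territory-scale inference: Gamma GLMs for territory size and adult count,
# likelihood-ratio tests against intercept-only models, seasonal Gamma GLMMs
# with a group random intercept, the heterogeneity model with season-specific
# dispersion, and the log inter-patch-distance linear model.

.ts_predictors <- c("n_adults", "heterogeneity", "patch_richness",
                    "mf_ratio", "dispersion")
.gs_predictors <- c("heterogeneity", "patch_richness", "dispersion",
                    "mf_ratio", "territory_area")

# Shared GLM machinery: listwise deletion, constant-predictor handling,
# collinearity check, Gamma log-link fit.
.fit_gamma_glm <- function(rows, response, predictors) {
  stopifnot(is.data.frame(rows), response %in% names(rows))
  need <- c(response, predictors)
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  n0 <- nrow(rows)
  keep <- stats::complete.cases(rows[, need]) & is.finite(rows[[response]]) &
    rows[[response]] > 0
  df <- rows[keep, need, drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0)
    message(sprintf("dropped %d incomplete/non-positive row(s)", n_dropped))
  if (nrow(df) < 10)
    stop("need at least 10 complete rows with positive response", call. = FALSE)
  constant <- predictors[vapply(predictors, function(p) stats::var(df[[p]]) == 0, logical(1))]
  active <- setdiff(predictors, constant)
  fml <- if (length(active))
    stats::reformulate(active, response = response)
  else stats::as.formula(paste(response, "~ 1"))
  if (length(active)) {
    Xchk <- stats::model.matrix(fml, df)
    if (kappa(Xchk, exact = TRUE) > 1e8)
      stop("singular design: predictors are collinear", call. = FALSE)
  }
  fit <- stats::glm(fml, family = stats::Gamma(link = "log"), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  out <- .as_model_fit(fit, n_dropped = n_dropped, rate_ratios = TRUE)
  if (length(constant)) {
    # constant predictors carry no information; report a zero slope
    add <- data.frame(term = constant, estimate = 0, std.error = NA_real_,
                      statistic = NA_real_, p.value = NA_real_,
                      rate_ratio = 1, rr_ci_low = NA_real_, rr_ci_high = NA_real_)
    out$table <- rbind(out$table, add)
    out$constant_terms <- constant
  }
  out
}

#' Territory-size Gamma GLM
#'
#' Gamma log-link fit of territory area (ha) on adult count, resource
#' heterogeneity, patch richness, male:female ratio and resource dispersion.
#' Rows with undefined metrics (dispersion with < 2 resource points, ratio in
#' an all-male/female group) are dropped listwise and counted.
#'
#' @param rows A [metrics_table()]-style data.frame.
#' @return A `model_fit`.
#' @export
fit_territory_glm <- function(rows) {
  .fit_gamma_glm(rows, "territory_area", .ts_predictors)
}

#' Group-size Gamma GLM
#'
#' Gamma log-link fit of resident adult count on resource heterogeneity,
#' patch richness, resource dispersion, male:female ratio and territory area.
#'
#' @inheritParams fit_territory_glm
#' @return A `model_fit`.
#' @export
fit_group_glm <- function(rows) {
  .fit_gamma_glm(rows, "n_adults", .gs_predictors)
}

#' Likelihood-ratio test of nested fits
#'
#' For Gamma GLMs the reported statistic is the deviance difference (null
#' minus full), as conventionally printed alongside these models; the
#' p-value uses the dispersion-scaled difference (deviance change divided by
#' the full model's estimated Gamma dispersion), which is the quantity with
#' an approximate chi-squared reference. For mixed fits the statistic is
#' `2 (logLik_full - logLik_null)` and is referred to chi-squared directly.
#'
#' @param full,null Nested `model_fit` or `gamma_glmm_fit` objects fitted to
#'   the same rows.
#' @return List of class `lrt_result`: `statistic`, `df`, `p.value`,
#'   `aic_full`, `aic_null`, plus `scaled_statistic` for GLMs and `bic_*`
#'   for mixed fits.
#' @export
lr_test <- function(full, null) {
  if (inherits(full, "model_fit") && inherits(null, "model_fit")) {
    if (full$n != null$n) stop("fits use different row sets", call. = FALSE)
    stat <- max(null$deviance - full$deviance, 0)
    df <- null$df_residual - full$df_residual
    scaled <- stat / full$dispersion
    out <- list(statistic = stat, df = df,
                scaled_statistic = scaled,
                p.value = if (df > 0) stats::pchisq(scaled, df, lower.tail = FALSE) else 1,
                aic_full = full$aic, aic_null = null$aic)
  } else if (inherits(full, "gamma_glmm_fit") && inherits(null, "gamma_glmm_fit")) {
    if (full$n != null$n) stop("fits use different row sets", call. = FALSE)
    stat <- 2 * (full$loglik - null$loglik)
    df <- full$n_par - null$n_par
    out <- list(statistic = max(stat, 0), df = df,
                p.value = if (df > 0) stats::pchisq(max(stat, 0), df, lower.tail = FALSE) else 1,
                aic_full = full$aic, aic_null = null$aic,
                bic_full = full$bic, bic_null = null$bic)
  } else stop("full and null must both be model_fit or gamma_glmm_fit", call. = FALSE)
  structure(out, class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LR test: statistic = %.4g on %d df, p = %.4g (AIC full %.4g vs null %.4g)\n",
              x$statistic, x$df, x$p.value, x$aic_full, x$aic_null))
  invisible(x)
}

#' Intercept-only counterpart of a territory/group GLM
#'
#' @param rows Data used for the full fit (the same listwise deletion is
#'   applied so both fits share rows).
#' @param response Response column name.
#' @param predictors Predictors of the full model (used only to reproduce the
#'   row set).
#' @return A `model_fit` of the intercept-only Gamma GLM.
#' @export
fit_null_glm <- function(rows, response, predictors) {
  keep <- stats::complete.cases(rows[, c(response, predictors)]) &
    is.finite(rows[[response]]) & rows[[response]] > 0
  df <- rows[keep, , drop = FALSE]
  fit <- stats::glm(stats::reformulate("1", response = response),
                    family = stats::Gamma(link = "log"), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  .as_model_fit(fit, n_dropped = nrow(rows) - nrow(df), rate_ratios = TRUE)
}

# Build season fixed-effect design (reference = mating) from a data.frame.
.season_design <- function(rows) {
  season <- factor(as.character(rows$season),
                   levels = c("mating", "post_mating", "pre_mating"))
  if (any(is.na(season))) stop("unknown season labels", call. = FALSE)
  stats::model.matrix(~season, data.frame(season = season))
}

#' Seasonal Gamma GLMM for territory size or adult count
#'
#' Gamma log-link mixed model with season as the fixed effect (reference
#' level: mating, so the reported contrasts are post-mating vs mating and
#' pre-mating vs mating) and a random intercept per dog group, estimated by
#' Laplace-approximate maximum likelihood. Near-singular random effects
#' (fitted SD below 1e-4) are flagged and the model falls back to the
#' fixed-effects fit.
#'
#' @param rows A [metrics_table()]-style data.frame with `group_id`, `season`
#'   and the response column.
#' @param response `"territory_area"` or `"n_adults"`.
#' @return A [gamma_glmm()] fit.
#' @export
fit_seasonal_glmm <- function(rows, response = c("territory_area", "n_adults")) {
  response <- match.arg(response)
  keep <- is.finite(rows[[response]]) & rows[[response]] > 0
  rows <- rows[keep, , drop = FALSE]
  X <- .season_design(rows)
  gamma_glmm(rows[[response]], X, group = rows$group_id)
}

#' Season-specific dispersion model for resource heterogeneity
#'
#' Fits two Gamma log-link mixed models sharing the mean structure (season
#' fixed effect, group random intercept): one with constant dispersion and
#' one whose log dispersion is a linear function of season (two extra
#' parameters), and compares them by a likelihood-ratio test on 2 df plus
#' AIC/BIC.
#'
#' @param rows A [metrics_table()]-style data.frame.
#' @param response Response column, default `"heterogeneity"` (must be
#'   strictly positive; zero-heterogeneity territories are dropped).
#' @param random Include the group random intercept (default TRUE). With
#'   `FALSE` both models are fixed-effects maximum-likelihood fits (the
#'   fallback used when the random intercept is unsupported).
#' @param se Compute Wald standard errors (see [gamma_glmm()]); `FALSE`
#'   speeds up likelihood-only uses such as LRT calibration by simulation.
#' @return List of class `dispersion_model`: `constant`, `seasonal`
#'   ([gamma_glmm()] fits) and `lrt` ([lr_test()]).
#' @export
fit_dispersion_model <- function(rows, response = "heterogeneity", random = TRUE,
                                 se = TRUE) {
  keep <- is.finite(rows[[response]]) & rows[[response]] > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropped %d row(s) with non-positive %s", n_dropped, response))
  rows <- rows[keep, , drop = FALSE]
  X <- .season_design(rows)
  grp <- if (random) rows$group_id else NULL
  m_const <- gamma_glmm(rows[[response]], X, group = grp, se = se)
  m_seas <- gamma_glmm(rows[[response]], X, group = grp, Zd = X, se = se)
  # if one arm went singular, refit the other without the random term too so
  # the LRT compares like with like
  if (m_const$singular != m_seas$singular &&
      (m_const$singular || m_seas$singular)) {
    m_const <- gamma_glmm(rows[[response]], X, group = NULL, se = se)
    m_seas <- gamma_glmm(rows[[response]], X, group = NULL, Zd = X, se = se)
  }
  structure(list(constant = m_const, seasonal = m_seas,
                 lrt = lr_test(m_seas, m_const), n_dropped = n_dropped),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("Constant-dispersion model:\n"); print(x$constant)
  cat("Season-specific dispersion model:\n"); print(x$seasonal)
  print(x$lrt)
  invisible(x)
}

#' Linear model for log inter-patch distance
#'
#' Ordinary least squares on the log of resource dispersion with season as
#' the only predictor: the fallback used when random-intercept variants are
#' near-singular.
#'
#' @param rows A [metrics_table()]-style data.frame with a positive
#'   `dispersion` column.
#' @return A `model_fit` with extra fields `fstatistic` (value, df1, df2),
#'   `f_p.value` and `r.squared`.
#' @export
fit_logdistance_lm <- function(rows) {
  keep <- is.finite(rows$dispersion) & rows$dispersion > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropped %d row(s) with undefined dispersion", n_dropped))
  df <- rows[keep, , drop = FALSE]
  df$season <- droplevels(factor(as.character(df$season),
                                 levels = c("mating", "post_mating", "pre_mating")))
  fml <- if (nlevels(df$season) >= 2) log(dispersion) ~ season else log(dispersion) ~ 1
  fit <- stats::lm(fml, data = df)
  out <- .as_model_fit(fit, n_dropped = n_dropped)
  sm <- summary(fit)
  fs <- sm$fstatistic
  out$r.squared <- sm$r.squared
  if (!is.null(fs)) {
    out$fstatistic <- fs
    out$f_p.value <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  } else {
    out$fstatistic <- c(value = NA_real_, numdf = 0, dendf = stats::df.residual(fit))
    out$f_p.value <- NA_real_
    out$r.squared <- 0
  }
  out
}
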