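make_rows <- function(n = 40, seed = 61, beta = c(-2.788, -0.0006, 0.102,
                                                  0.041, 0.391, 0.0206),
                      phi = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  rows <- data.frame(
    group_id = sprintf("g%02d", seq_len(n)),
    season = sample(territory_seasons(), n, replace = TRUE),
    n_adults = pmax(2, rpois(n, 6)),
    heterogeneity = sample(2:8, n, replace = TRUE),
    patch_richness = pmax(2, rpois(n, 15)),
    mf_ratio = round(runif(n, 0.3, 2.5), 2),
    dispersion = runif(n, 20, 120))
  eta <- beta[1] + beta[2] * rows$n_adults + beta[3] * rows$heterogeneity +
    beta[4] * rows$patch_richness + beta[5] * rows$mf_ratio +
    beta[6] * rows$dispersion
  rows$territory_area <- rgamma(n, shape = 1 / phi, scale = exp(eta) * phi)
  rows
}

test_that("territory GLM drops incomplete rows and reports them", {
  rows <- make_rows(40)
  rows$dispersion[3] <- NA
  rows$mf_ratio[c(10, 11)] <- NA
  expect_message(fit <- fit_territory_glm(rows), "dropped 3")
  expect_equal(fit$n, 37)
  expect_equal(fit$n_dropped, 3)
  expect_equal(sort(fit$table$term),
               sort(c("(Intercept)", "n_adults", "heterogeneity",
                      "patch_richness", "mf_ratio", "dispersion")))
})

test_that("constant predictors degrade to an intercept-only fit with zero slopes", {
  rows <- make_rows(20)
  rows[c("n_adults", "heterogeneity", "patch_richness", "mf_ratio",
         "dispersion")] <- list(4, 5, 10, 1, 50)
  fit <- fit_territory_glm(rows)
  expect_equal(fit$coefficients[["(Intercept)"]],
               log(mean(rows$territory_area)), tolerance = 1e-9)
  slopes <- fit$table[fit$table$term != "(Intercept)", ]
  expect_true(all(slopes$estimate == 0))
})

test_that("deviance never increases as predictors are added", {
  rows <- make_rows(50)
  fit_full <- quietly(fit_territory_glm(rows))
  fit_null <- fit_null_glm(rows, "territory_area", c("n_adults", "heterogeneity",
                                                     "patch_richness", "mf_ratio",
                                                     "dispersion"))
  expect_lte(fit_full$deviance, fit_null$deviance)
  # intermediate model
  mid <- glm(territory_area ~ dispersion, family = Gamma(link = "log"),
             data = rows)
  expect_lte(fit_full$deviance, deviance(mid))
  expect_lte(deviance(mid), fit_null$deviance)
})

test_that("collinear designs are refused", {
  rows <- make_rows(30)
  rows$patch_richness <- 2 * rows$heterogeneity
  expect_error(quietly(fit_territory_glm(rows)), "collinear")
})

test_that("group-size GLM obeys log-link equivariance and positive fitted means", {
  rows <- make_rows(40)
  rows$n_adults <- rows$n_adults + runif(40, 0, 0.5)  # continuous response
  f1 <- fit_group_glm(rows)
  rows2 <- rows
  rows2$n_adults <- rows2$n_adults * 3
  f2 <- fit_group_glm(rows2)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] + log(3), tolerance = 1e-7)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-7)
  expect_true(all(fitted(f1$fit) > 0))
})

test_that("group-size LR test is calibrated under an intercept-only truth", {
  set.seed(62)
  gs_pred <- c("heterogeneity", "patch_richness", "dispersion", "mf_ratio",
               "territory_area")
  rej <- replicate(1000, {
    rows <- make_rows(seed = NULL, n = 84)
    # intercept-only truth for the adult count (log mean 1.776)
    rows$n_adults <- rgamma(84, shape = 4, scale = exp(1.776) / 4)
    full <- quietly(fit_group_glm(rows))
    null <- fit_null_glm(rows, "n_adults", gs_pred)
    lr_test(full, null)$p.value < 0.05
  })
  # binomial 95% band around 0.05 at 1000 replicates
  expect_gt(mean(rej), 0.0365)
  expect_lt(mean(rej), 0.0635)
})

test_that("lr_test handles identity, density oracle, and monotonicity", {
  rows <- make_rows(30)
  fit <- quietly(fit_territory_glm(rows))
  self <- lr_test(fit, fit)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)

  # density oracle on n <= 10 rows: at shape 1 the deviance difference equals
  # twice the log-density difference
  small <- make_rows(10)
  f <- glm(territory_area ~ dispersion, family = Gamma(link = "log"), data = small)
  n0 <- glm(territory_area ~ 1, family = Gamma(link = "log"), data = small)
  ff <- rdhtools:::.as_model_fit(f); nn <- rdhtools:::.as_model_fit(n0)
  lrt <- lr_test(ff, nn)
  oracle <- 2 * (sum(dgamma(small$territory_area, shape = 1,
                            scale = fitted(f), log = TRUE)) -
                 sum(dgamma(small$territory_area, shape = 1,
                            scale = fitted(n0), log = TRUE)))
  expect_equal(lrt$statistic, oracle, tolerance = 1e-9)

  # p monotone decreasing in the statistic at fixed df
  p <- pchisq(c(1, 5, 10, 20), df = 5, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("GLM fits agree with a direct numerical-ML oracle on small samples", {
  set.seed(63)
  for (n in c(20, 50)) {
    rows <- make_rows(n, seed = NULL)
    fit <- quietly(fit_territory_glm(rows))
    X <- model.matrix(~n_adults + heterogeneity + patch_richness + mf_ratio +
                        dispersion, rows)
    oracle <- direct_gamma_ml(rows$territory_area, X)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-5)
  }
})

test_that("dispersion-model likelihoods nest and AIC ordering is antisymmetric", {
  set.seed(64)
  dat <- sim_glmm_panel(group_sd = 0.4, intercept = 1.6,
                        phi = c(mating = 0.6, post_mating = 0.06,
                                pre_mating = 0.6), n_keep = 84)
  names(dat)[names(dat) == "territory_area"] <- "heterogeneity"
  dm <- fit_dispersion_model(dat)
  expect_gte(dm$seasonal$loglik, dm$constant$loglik)
  expect_equal(dm$lrt$df, 2)
  expect_equal(dm$lrt$statistic,
               2 * (dm$seasonal$loglik - dm$constant$loglik))
  # swapping the roles reverses the AIC comparison
  swapped <- lr_test(dm$seasonal, dm$constant)
  expect_equal(sign(dm$lrt$aic_full - dm$lrt$aic_null),
               -sign(swapped$aic_null - swapped$aic_full))
})

test_that("log-distance LM: scale shifts the intercept, F and R2 are reported", {
  set.seed(65)
  rows <- data.frame(group_id = sprintf("g%02d", 1:60),
                     season = sample(territory_seasons(), 60, replace = TRUE),
                     dispersion = rlnorm(60, log(60), 0.4))
  f1 <- fit_logdistance_lm(rows)
  expect_equal(unname(f1$fstatistic["numdf"]), 2)
  expect_equal(unname(f1$fstatistic["dendf"]), 57)
  expect_true(f1$r.squared >= 0 && f1$r.squared <= 1)

  rows2 <- rows; rows2$dispersion <- rows2$dispersion * 5
  f2 <- fit_logdistance_lm(rows2)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] + log(5), tolerance = 1e-9)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-9)

  # intercept-only fit has R2 = 0
  rows3 <- rows; rows3$season <- "mating"
  f3 <- fit_logdistance_lm(rows3)
  expect_equal(f3$r.squared, 0)

  # under equal season means the F-test p-value is well behaved
  set.seed(66)
  ps <- replicate(200, {
    r <- data.frame(season = sample(territory_seasons(), 45, replace = TRUE),
                    dispersion = rlnorm(45, log(60), 0.3))
    fit_logdistance_lm(r)$f_p.value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
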