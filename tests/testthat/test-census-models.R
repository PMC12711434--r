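test_that("rank-sum test reproduces the exact enumeration for separated samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_true(r$exact)
  expect_equal(r$p.value, 0.1)  # 2/20 orderings as extreme
  expect_equal(r$W, 0 + 3 * 4 / 2)
})

test_that("rank-sum test is symmetric under sample swap and identity", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.8, 4.4, 2.9)
  a <- rank_sum_test(x, y); b <- rank_sum_test(y, x)
  expect_equal(b$U, length(x) * length(y) - a$U)
  expect_equal(a$p.value, b$p.value)
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("census GLM recovers group means in the saturated two-group case", {
  # no resource effect in truth: responses exactly at group means a and b
  df <- data.frame(settlement = rep(c("rural", "urban"), each = 4),
                   resource_density = 0,
                   dog_density = rep(c(2.5, 4.0), each = 4))
  fit <- quietly(fit_census_glm(df))
  co <- fit$coefficients
  expect_equal(unname(co["(Intercept)"]), log(2.5), tolerance = 1e-9)
  expect_equal(unname(co["settlementurban"]), log(4.0 / 2.5), tolerance = 1e-9)
})

test_that("census GLM drops zero-density sites and reports rate ratios as exact transforms", {
  set.seed(41)
  n <- 60
  df <- data.frame(settlement = rep(c("rural", "urban"), each = n / 2),
                   resource_density = rexp(n, 1 / 5))
  mu <- exp(-0.3 + 0.1 * df$resource_density + (df$settlement == "urban") * 1.0)
  df$dog_density <- rgamma(n, shape = 2, scale = mu / 2)
  df$dog_density[c(3, 17)] <- 0
  expect_message(fit <- fit_census_glm(df), "dropped 2")
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n, n - 2)
  tab <- fit$table
  expect_equal(tab$rate_ratio, exp(tab$estimate), tolerance = 1e-12)
  expect_true(all(tab$rr_ci_low < tab$rate_ratio & tab$rate_ratio < tab$rr_ci_high))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (length(fit$coefficients) + 1))
})

test_that("published point estimates exponentiate to their rate ratios", {
  expect_equal(round(exp(0.110), 3), 1.116)
  expect_equal(round(exp(1.169), 3), 3.219)
})

test_that("combined slope adds the interaction and propagates covariance", {
  set.seed(42)
  n <- 400
  df <- data.frame(settlement = rep(c("rural", "urban"), each = n / 2),
                   resource_density = rexp(n, 1 / 5))
  mu <- exp(-0.3 + 0.11 * df$resource_density + (df$settlement == "urban") *
              (1.0 - 0.11 * df$resource_density))
  df$dog_density <- rgamma(n, shape = 2, scale = mu / 2)
  fit <- quietly(fit_census_glm(df))
  cs <- combined_slope(fit, "urban")
  b <- fit$coefficients
  expect_equal(cs$slope, unname(b["resource_density"] +
                                b["resource_density:settlementurban"]))
  # delta-method oracle via parametric resampling of the coefficient vector
  L <- chol(fit$vcov)
  sims <- matrix(rnorm(4000 * 4), ncol = 4) %*% L
  sim_slope <- b["resource_density"] + sims[, 2] +
    b["resource_density:settlementurban"] + sims[, 4]
  expect_equal(cs$se, sd(sim_slope), tolerance = 0.05)
  # rural slope is the raw coefficient
  expect_equal(combined_slope(fit, "rural")$slope, unname(b["resource_density"]))
  # the published arithmetic: 0.109 + (-0.106) = 0.003
  expect_equal(0.109 - 0.106, 0.003)
})

test_that("under a true null the resource-term Wald p-values are uniform", {
  set.seed(43)
  pvals <- replicate(1000, {
    n <- 93
    df <- data.frame(settlement = rep(c("rural", "urban"), c(52, 41)),
                     resource_density = rexp(n, 1 / 5))
    mu <- exp(0.2 + (df$settlement == "urban") * 0.8)  # no resource effect
    df$dog_density <- rgamma(n, shape = 2, scale = mu / 2)
    quietly(fit_census_glm(df))$table$p.value[2]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("two-sample power matches the published sensitivity analysis", {
  expect_equal(two_sample_power(52, 41, d = 0), 0.05)
  expect_equal(two_sample_power(52, 41, d = 0.6), 0.81, tolerance = 0.01 / 0.81)
  # monotone in d and in group size
  d <- seq(0, 2, by = 0.25)
  p <- vapply(d, function(dd) two_sample_power(52, 41, dd), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_gt(two_sample_power(80, 41, 0.5), two_sample_power(52, 41, 0.5))
})

test_that("d_for_power inverts the power function", {
  expect_equal(d_for_power(0.05 + 1e-6, 52, 41), 0, tolerance = 1e-2)
  d80 <- d_for_power(0.80, 52, 41)
  expect_equal(two_sample_power(52, 41, d80), 0.80, tolerance = 1e-7)
  expect_equal(d80, 0.59, tolerance = 0.01)
  for (d in c(0.2, 0.6, 1.1)) {
    expect_equal(d_for_power(two_sample_power(52, 41, d), 52, 41), d,
                 tolerance = 1e-6)
  }
})

test_that("normal-shift equivalences reproduce the AUC and Cliff's delta chain", {
  expect_equal(d_to_auc(0), 0.5)
  expect_equal(auc_to_cliffs(0.5), 0)
  d80 <- d_for_power(0.80, 52, 41)
  auc <- d_to_auc(d80)
  expect_equal(auc, 0.662, tolerance = 0.002 / 0.662)
  expect_equal(auc_to_cliffs(round(auc, 3)), 0.324)
})
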