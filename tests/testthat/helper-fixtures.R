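# Shared fixtures and small oracles, all built in code.

quietly <- function(expr) {
  withCallingHandlers(suppressWarnings(expr),
                      message = function(m) invokeRestart("muffleMessage"))
}

square_poly <- function(side = 100, origin = c(0, 0)) {
  polygon2d(rbind(origin,
                  origin + c(side, 0),
                  origin + c(side, side),
                  origin + c(0, side)))
}

# territory with explicit geometry and resource layout
make_territory <- function(xy, cats, n_male = 2, n_female = 2,
                           season = "mating", poly = square_poly(),
                           group_id = "g1", n_pups = 0) {
  territory_record(group_id, season, territory = poly,
                   resources = resource_points(xy, cats),
                   n_male = n_male, n_female = n_female, n_pups = n_pups)
}

# brute-force mean over per-point average distances (double loop)
brute_dispersion <- function(xy, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  n <- nrow(xy)
  per_point <- vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i)
      s <- s + sqrt(sum((xy[i, ] - xy[j, ])^2))
    s / (if (divisor == "n-1") n - 1 else n)
  }, numeric(1))
  mean(per_point)
}

# simulate a balanced group x season panel directly from the Gamma GLMM
# (used for fitter-level harnesses; the landscape generator is tested
# separately)
sim_glmm_panel <- function(n_groups = 36, group_sd = 0.4, intercept = 0.6,
                           post_effect = 0, pre_effect = 0,
                           phi = c(mating = 0.02, post_mating = 0.02,
                                   pre_mating = 0.02),
                           n_keep = NULL, response = "territory_area") {
  dat <- data.frame(group_id = rep(sprintf("g%02d", seq_len(n_groups)), each = 3),
                    season = rep(territory_seasons(), n_groups),
                    stringsAsFactors = FALSE)
  b <- stats::rnorm(n_groups, 0, group_sd)
  eta <- intercept + b[as.integer(factor(dat$group_id))] +
    ifelse(dat$season == "post_mating", post_effect,
           ifelse(dat$season == "pre_mating", pre_effect, 0))
  ph <- phi[dat$season]
  dat[[response]] <- stats::rgamma(nrow(dat), shape = 1 / ph,
                                   scale = exp(eta) * ph)
  if (!is.null(n_keep) && n_keep < nrow(dat))
    dat <- dat[sort(sample.int(nrow(dat), n_keep)), ]
  dat
}

# direct ML fit of a fixed-effects Gamma log-link model by log-density
# maximization (independent of glm's IRLS and of gamma_glmm)
direct_gamma_ml <- function(y, X) {
  nll <- function(par) {
    beta <- par[-length(par)]
    k <- exp(par[length(par)])
    mu <- exp(drop(X %*% beta))
    -sum(stats::dgamma(y, shape = k, scale = mu / k, log = TRUE))
  }
  gr <- function(par) {
    beta <- par[-length(par)]
    k <- exp(par[length(par)])
    mu <- exp(drop(X %*% beta))
    dbeta <- -drop(crossprod(X, k * (y / mu - 1)))
    dlogk <- -k * sum(log(k) + 1 - digamma(k) + log(y) - log(mu) - y / mu)
    c(dbeta, dlogk)
  }
  start <- c(stats::glm.fit(X, y, family = stats::Gamma(link = "log"))$coefficients, 0)
  # perturb the start so agreement is not an artifact of initialization
  opt <- suppressWarnings(
    stats::optim(start + 0.05, nll, gr, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15)))
  list(coefficients = opt$par[-length(opt$par)], shape = exp(opt$par[length(opt$par)]),
       loglik = -opt$value)
}
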