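# Synthetic landscape, census and territory-panel generator.
#
# The generator emulates the statistical structure the analyses assume: survey
# polygons with settlement strata and scored resource points; dog densities
# following the census Gamma log-link truth; and a group x season territory
# panel whose areas follow the territory-model truth with a group random
# intercept and seasonal effects. All draws are governed by the R RNG, so a
# single set.seed() call makes every output reproducible.

#' Simulation configuration
#'
#' Bundles every generator parameter with defaults that mirror the study
#' design: 93 census polygons (52 rural, 41 urban) of 1.29-161 ha; eight-way
#' category weights and resource intensities chosen so that mean score
#' densities sit near the field values (about 4 score/ha rural, 10 urban);
#' census Gamma truth (intercept, resource slope, urban shift, interaction) =
#' (-0.346, 0.110, 1.169, -0.106); 36 territory groups x 3 seasons thinned to
#' an 84-row panel; territory-size truth (intercept, adults, heterogeneity,
#' richness, male:female ratio, dispersion) =
#' (-2.788, -0.0006, 0.102, 0.041, 0.391, 0.0206); adult-count truth
#' intercept-only at 1.776 (log scale); season log-effects (post-mating
#' -0.075, pre-mating -0.021) and group intercept SD 0.4.
#'
#' @param n_rural,n_urban Census site counts per stratum.
#' @param area_range_ha Polygon area range (uniform draw).
#' @param resource_intensity Named vector, mean points per hectare by
#'   stratum.
#' @param intensity_sdlog Site-to-site lognormal spread (sdlog) of resource
#'   intensity around the stratum mean; gives the resource-density
#'   coefficient of variation (~1.3 at the default 1.0) seen in field
#'   censuses.
#' @param category_weights List of two 8-vectors (rural, urban) summing to 1.
#' @param census_beta Census truth coefficients (length 4).
#' @param census_phi Census Gamma dispersion.
#' @param n_groups,panel_n Territory groups and target panel size after
#'   missingness (108 rows thinned to `panel_n`).
#' @param ts_beta Territory-size truth (length 6, order: intercept, n_adults,
#'   heterogeneity, patch_richness, mf_ratio, dispersion).
#' @param ts_phi Territory-size residual Gamma dispersion.
#' @param gs_log_mean Log mean adult count (group-size truth intercept).
#' @param gs_phi Adult-count Gamma dispersion.
#' @param season_effects Named log-scale effects relative to the mating
#'   season.
#' @param group_sd Group random-intercept SD (log scale).
#' @param process Resource point process for territories: `"poisson"`,
#'   `"clustered"` or `"regular"`.
#' @param cluster_radius,cluster_mu Matern-style cluster parameters (m,
#'   offspring per parent).
#' @param inhibition Hard-core minimum spacing for the regular process (m).
#' @param richness_meanlog,richness_sdlog Between-group spread of expected
#'   points per territory (lognormal).
#' @param radius_meanlog,radius_sdlog Between-group spread of territory
#'   resource-cloud radius in metres (lognormal).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_rural = 52, n_urban = 41,
                       area_range_ha = c(1.29, 161),
                       resource_intensity = c(rural = 1.2, urban = 2.9),
                       intensity_sdlog = 1.0,
                       category_weights = list(
                         rural = c(0.04, 0.05, 0.08, 0.14, 0.12, 0.17, 0.12, 0.28),
                         urban = c(0.08, 0.12, 0.10, 0.12, 0.12, 0.12, 0.12, 0.22)),
                       census_beta = c(-0.346, 0.110, 1.169, -0.106),
                       census_phi = 0.5,
                       n_groups = 36, panel_n = 84,
                       ts_beta = c(-2.788, -0.0006, 0.102, 0.041, 0.391, 0.0206),
                       ts_phi = 0.02,
                       gs_log_mean = 1.776, gs_phi = 0.25,
                       season_effects = c(post_mating = -0.075, pre_mating = -0.021),
                       group_sd = 0.4,
                       process = c("poisson", "clustered", "regular"),
                       cluster_radius = 25, cluster_mu = 4,
                       inhibition = 15,
                       richness_meanlog = log(15), richness_sdlog = 0.45,
                       radius_meanlog = log(65), radius_sdlog = 0.35) {
  process <- match.arg(process)
  stopifnot(all(resource_intensity >= 0),
            abs(sum(category_weights$rural) - 1) < 1e-8,
            abs(sum(category_weights$urban) - 1) < 1e-8,
            length(census_beta) == 4, length(ts_beta) == 6,
            census_phi > 0, ts_phi > 0, gs_phi > 0, group_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random simple polygon of given area
#'
#' Star-shaped polygon: vertices at sorted random angles with lognormal
#' radius perturbation, rescaled so the shoelace area matches the request
#' exactly.
#'
#' @param area_ha Target area (> 0), hectares.
#' @param n_vertices Number of vertices (default 12).
#' @param centre Length-2 centre coordinates in metres.
#' @return A [polygon2d()] with area equal to `area_ha`.
#' @export
gen_polygon <- function(area_ha, n_vertices = 12, centre = c(0, 0)) {
  stopifnot(area_ha > 0, n_vertices >= 3)
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- exp(stats::rnorm(n_vertices, 0, 0.25))
  v <- cbind(r * cos(theta), r * sin(theta))
  a0 <- abs(.shoelace(v))
  s <- sqrt(area_ha * 1e4 / a0)
  polygon2d(sweep(v * s, 2, centre, "+"), check_simple = FALSE)
}

# uniform points in a polygon by rejection from the bounding box
.runif_in_polygon <- function(n, poly) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  v <- poly$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    keep <- .in_poly(cand, poly$vertices)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate resource points inside a polygon
#'
#' Expected count is `intensity x area` for all three processes. `"poisson"`
#' scatters points uniformly; `"clustered"` is a Matern-style parent-offspring
#' process (lower mean inter-point distance at equal intensity);
#' `"regular"` applies sequential hard-core inhibition (higher mean
#' inter-point distance).
#'
#' @param poly A [polygon2d()].
#' @param intensity Points per hectare (>= 0).
#' @param process `"poisson"`, `"clustered"` or `"regular"`.
#' @param category_weights 8-vector of category sampling weights.
#' @param cluster_radius,cluster_mu,inhibition Process parameters (metres,
#'   offspring per parent, metres).
#' @return A [resource_points()] data.frame.
#' @export
gen_resources <- function(poly, intensity,
                          process = c("poisson", "clustered", "regular"),
                          category_weights = rep(1 / 8, 8),
                          cluster_radius = 25, cluster_mu = 4,
                          inhibition = 15) {
  process <- match.arg(process)
  stopifnot(intensity >= 0, length(category_weights) == 8)
  area <- polygon_area_ha(poly)
  n <- stats::rpois(1, intensity * area)
  if (n == 0) return(resource_points(matrix(numeric(0), 0, 2), integer(0)))
  xy <- switch(process,
    poisson = .runif_in_polygon(n, poly),
    clustered = {
      n_parents <- max(1L, round(n / cluster_mu))
      parents <- .runif_in_polygon(n_parents, poly)
      pts <- matrix(numeric(0), 0, 2)
      while (nrow(pts) < n) {
        idx <- sample.int(n_parents, n - nrow(pts), replace = TRUE)
        ang <- stats::runif(length(idx), 0, 2 * pi)
        rad <- cluster_radius * sqrt(stats::runif(length(idx)))
        cand <- parents[idx, , drop = FALSE] +
          cbind(rad * cos(ang), rad * sin(ang))
        keep <- .in_poly(cand, poly$vertices)
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts[seq_len(n), , drop = FALSE]
    },
    regular = {
      pts <- matrix(numeric(0), 0, 2)
      h <- inhibition
      tries <- 0L
      while (nrow(pts) < n) {
        cand <- .runif_in_polygon(1, poly)
        ok <- nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= h
        if (ok) { pts <- rbind(pts, cand); tries <- 0L } else tries <- tries + 1L
        if (tries > 200L) { h <- h * 0.7; tries <- 0L }  # relax if saturated
      }
      pts
    })
  resource_points(xy, sample.int(8, n, replace = TRUE, prob = category_weights))
}

#' Generate a synthetic census
#'
#' Draws the configured number of rural and urban survey polygons, populates
#' them with scored resource points, and draws dog densities from a Gamma
#' distribution with mean `exp(b0 + b1 resource + b2 urban + b3
#' resource:urban)` and dispersion `census_phi`. The continuous density is
#' discretized to a whole-dog count and the stored density recomputed as
#' count/area, so the pair is self-consistent. Sexes are assigned 1:1 and
#' ages pup/juvenile/adult at 15/15/70%.
#'
#' @param config A [sim_config()].
#' @return List of [census_site()] objects.
#' @export
gen_census <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  strata <- c(rep("rural", config$n_rural), rep("urban", config$n_urban))
  b <- config$census_beta
  lapply(seq_along(strata), function(i) {
    settlement <- strata[i]
    area <- stats::runif(1, config$area_range_ha[1], config$area_range_ha[2])
    poly <- gen_polygon(area)
    # mean-preserving lognormal site effect on resource intensity
    site_intensity <- config$resource_intensity[[settlement]] *
      stats::rlnorm(1, -config$intensity_sdlog^2 / 2, config$intensity_sdlog)
    res <- gen_resources(poly, site_intensity,
                         process = "poisson",
                         category_weights = config$category_weights[[settlement]])
    rdens <- score_sum(res) / area
    urban <- as.numeric(settlement == "urban")
    mu <- exp(b[1] + b[2] * rdens + b[3] * urban + b[4] * rdens * urban)
    dens <- stats::rgamma(1, shape = 1 / config$census_phi,
                          scale = mu * config$census_phi)
    n_dogs <- round(dens * area)
    sex <- sample(c("M", "F"), n_dogs, replace = TRUE)
    age <- sample(c("pup", "juvenile", "adult"), n_dogs, replace = TRUE,
                  prob = c(0.15, 0.15, 0.70))
    suppressWarnings(census_site(
      id = sprintf("site_%03d", i), polygon = poly, settlement = settlement,
      resources = res,
      dogs = data.frame(sex = sex, age = age, stringsAsFactors = FALSE)))
  })
}

#' Generate a synthetic territory panel
#'
#' For each of `n_groups` dog groups, draws group-level resource parameters
#' (cloud radius and expected patch count, lognormal across groups, creating
#' between-group spread in richness, heterogeneity and dispersion), then for
#' each of the three seasons lays out resource points, draws the resident
#' adult count (intercept-only Gamma truth, sexes binomial), and draws
#' territory area from a Gamma distribution whose log mean is the linear
#' combination of the territory-size truth coefficients with the realized
#' metrics, plus the group random intercept and the season effect. A convex
#' territory polygon of that area is generated around the resource centroid.
#' Finally group x season rows are thinned at random to `panel_n` rows.
#'
#' @param config A [sim_config()].
#' @return List of [territory_record()] objects (length `panel_n`).
#' @export
gen_territory_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_groups
  bt <- config$ts_beta
  g_radius <- stats::rlnorm(G, config$radius_meanlog, config$radius_sdlog)
  g_lambda <- stats::rlnorm(G, config$richness_meanlog, config$richness_sdlog)
  g_int <- stats::rnorm(G, 0, config$group_sd)
  seasons <- territory_seasons()
  recs <- list()
  for (g in seq_len(G)) {
    # skew category weights differently per group for heterogeneity spread
    w <- stats::rgamma(8, shape = 0.8)
    w <- w / sum(w)
    for (s in seasons) {
      # resource cloud: disc of group radius, so dispersion scales with radius
      disc_area_ha <- pi * g_radius[g]^2 / 1e4
      disc <- gen_polygon(disc_area_ha, n_vertices = 24)
      n_target <- max(2L, stats::rpois(1, g_lambda[g]))
      res <- gen_resources(disc, n_target / disc_area_ha,
                           process = config$process,
                           category_weights = w,
                           cluster_radius = config$cluster_radius,
                           cluster_mu = config$cluster_mu,
                           inhibition = config$inhibition)
      while (nrow(res) < 2) {
        res <- gen_resources(disc, n_target / disc_area_ha, process = config$process,
                             category_weights = w,
                             cluster_radius = config$cluster_radius,
                             cluster_mu = config$cluster_mu,
                             inhibition = config$inhibition)
      }
      n_adults <- max(2L, round(stats::rgamma(1, shape = 1 / config$gs_phi,
                                              scale = exp(config$gs_log_mean) * config$gs_phi)))
      n_male <- stats::rbinom(1, n_adults, 0.5)
      n_female <- n_adults - n_male
      mfr <- if (n_female > 0) n_male / n_female else NA_real_
      disp <- resource_dispersion(cbind(res$x, res$y))
      het <- length(unique(res$category))
      seff <- if (s == "mating") 0 else config$season_effects[[s]]
      eta <- bt[1] + bt[2] * n_adults + bt[3] * het + bt[4] * nrow(res) +
        bt[5] * (if (is.na(mfr)) 1 else mfr) + bt[6] * disp +
        g_int[g] + seff
      area <- stats::rgamma(1, shape = 1 / config$ts_phi,
                            scale = exp(eta) * config$ts_phi)
      cen <- colMeans(cbind(res$x, res$y))
      terr <- gen_polygon(area, n_vertices = 16, centre = cen)
      if (!any(points_in_polygon(cbind(res$x, res$y), terr))) {
        # recentre on the nearest resource point so the territory holds >= 1
        d2 <- (res$x - cen[1])^2 + (res$y - cen[2])^2
        k <- which.min(d2)
        terr <- gen_polygon(area, n_vertices = 16, centre = c(res$x[k], res$y[k]))
      }
      recs[[length(recs) + 1L]] <- territory_record(
        group_id = sprintf("group_%02d", g), season = s,
        territory = terr, resources = res,
        n_male = n_male, n_female = n_female,
        n_pups = if (s == "post_mating") stats::rpois(1, 3) else 0L)
    }
  }
  if (config$panel_n < length(recs))
    recs <- recs[sort(sample.int(length(recs), config$panel_n))]
  recs
}
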