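# Territory-level resource statistics: patch richness, heterogeneity,
# dispersion (mean pairwise inter-point distance), and group composition.

.seasons <- c("pre_mating", "mating", "post_mating")

#' Seasons of the territory study
#'
#' @return Character vector of the three season labels, in calendar order:
#'   pre-mating (April-early July), mating (mid July-mid October), and the
#'   post-mating pup-emergence season (late October-March).
#' @export
territory_seasons <- function() .seasons

#' Construct a territory record
#'
#' One group x season observation unit: the territory polygon (built as the
#' convex hull of recorded marking/defence points unless a polygon is given),
#' the mapped resource points, and the resident group composition.
#'
#' @param group_id Group identifier.
#' @param season One of [territory_seasons()].
#' @param boundary_points Two-column matrix of planar metre coordinates of
#'   marking/defence points (>= 3, not all collinear), or `NULL` if
#'   `territory` is supplied directly.
#' @param resources A [resource_points()] data.frame.
#' @param n_male,n_female Resident adult counts by sex (unsexed adults are not
#'   allowed in the territory study).
#' @param n_pups Pup count (excluded from adult-count models).
#' @param territory Optional [polygon2d()]; overrides the hull construction.
#' @return An object of class `territory_record`.
#' @export
territory_record <- function(group_id, season, boundary_points = NULL,
                             resources = resource_points(matrix(numeric(0), 0, 2), integer(0)),
                             n_male = 0L, n_female = 0L, n_pups = 0L,
                             territory = NULL) {
  season <- match.arg(season, .seasons)
  if (is.null(territory)) {
    if (is.null(boundary_points)) stop("boundary_points or territory required", call. = FALSE)
    territory <- convex_hull(boundary_points)
  }
  stopifnot(inherits(territory, "polygon2d"))
  n_male <- as.integer(n_male); n_female <- as.integer(n_female)
  if (n_male < 0 || n_female < 0 || n_pups < 0)
    stop("composition counts must be non-negative", call. = FALSE)
  structure(list(group_id = group_id, season = season, territory = territory,
                 resources = resources, n_male = n_male, n_female = n_female,
                 n_adults = n_male + n_female, n_pups = as.integer(n_pups)),
            class = "territory_record")
}

#' @export
print.territory_record <- function(x, ...) {
  cat(sprintf("<territory_record %s/%s: %.3g ha, %d resource points, %d adults (%dM %dF), %d pups>\n",
              x$group_id, x$season, polygon_area_ha(x$territory),
              nrow(x$resources), x$n_adults, x$n_male, x$n_female, x$n_pups))
  invisible(x)
}

#' Patch richness
#'
#' Count of food-resource points inside a territory in a season. Points with
#' identical coordinates still count separately: two bins at one corner are
#' two patches.
#'
#' @param t A [territory_record()].
#' @return Integer count.
#' @export
patch_richness <- function(t) {
  stopifnot(inherits(t, "territory_record"))
  nrow(t$resources)
}

#' Resource heterogeneity
#'
#' Number of distinct food-source categories (of the eight in
#' [resource_categories()]) present in the territory; 0 for an empty
#' territory, at most 8.
#'
#' @param t A [territory_record()].
#' @return Integer in 0..8.
#' @export
heterogeneity <- function(t) {
  stopifnot(inherits(t, "territory_record"))
  length(unique(t$resources$category))
}

#' Resource dispersion
#'
#' Mean, over resource points, of each point's average distance to the other
#' points in the territory. With the default divisor `N - 1` (self-distance
#' excluded) this equals the mean pairwise inter-point distance:
#' `2 / (N (N - 1)) * sum_{i<j} d_ij`. The alternative divisor `N` includes
#' each point's zero self-distance and shrinks every per-point average by
#' `(N-1)/N`.
#'
#' @param t A [territory_record()], or a two-column coordinate matrix.
#' @param divisor `"n-1"` (default) or `"n"`.
#' @return Mean distance in metres; `NA` (with a warning) when fewer than two
#'   resource points are present, since the statistic is then undefined.
#' @export
#' @examples
#' resource_dispersion(rbind(c(0, 0), c(10, 0)))  # 10
resource_dispersion <- function(t, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  xy <- if (inherits(t, "territory_record")) cbind(t$resources$x, t$resources$y)
        else as.matrix(t)
  n <- nrow(xy)
  if (is.null(n) || n < 2) {
    warning("resource dispersion undefined with fewer than 2 points; returning NA")
    return(NA_real_)
  }
  d <- stats::dist(xy)
  per_point_sum <- 2 * sum(d) / n          # mean over points of row sums = 2*total/n
  if (divisor == "n-1") per_point_sum / (n - 1) else per_point_sum / n
}

#' Male:female ratio of resident adults
#'
#' @param t A [territory_record()].
#' @return `n_male / n_female`; `NA` (with a warning) when the group has no
#'   females, in which case the row is excluded from ratio-dependent models.
#' @export
mf_ratio <- function(t) {
  stopifnot(inherits(t, "territory_record"))
  if (t$n_female == 0) {
    warning(sprintf("group %s/%s has no females: male:female ratio undefined",
                    t$group_id, t$season))
    return(NA_real_)
  }
  t$n_male / t$n_female
}

#' Compute all territory metrics
#'
#' @param t A [territory_record()].
#' @param divisor Dispersion divisor convention, see [resource_dispersion()].
#' @return A one-row data.frame: `group_id`, `season`, `territory_area`
#'   (ha), `patch_richness`, `heterogeneity`, `dispersion` (m), `mf_ratio`,
#'   `n_adults`, `n_male`, `n_female`, `n_pups`. Undefined metrics are `NA`.
#' @export
compute_metrics <- function(t, divisor = c("n-1", "n")) {
  stopifnot(inherits(t, "territory_record"))
  divisor <- match.arg(divisor)
  disp <- if (patch_richness(t) >= 2) resource_dispersion(t, divisor) else {
    warning(sprintf("group %s/%s: <2 resource points, dispersion set to NA",
                    t$group_id, t$season))
    NA_real_
  }
  ratio <- if (t$n_female >= 1) t$n_male / t$n_female else {
    warning(sprintf("group %s/%s has no females: male:female ratio undefined",
                    t$group_id, t$season))
    NA_real_
  }
  data.frame(group_id = t$group_id, season = t$season,
             territory_area = polygon_area_ha(t$territory),
             patch_richness = patch_richness(t),
             heterogeneity = heterogeneity(t),
             dispersion = disp, mf_ratio = ratio,
             n_adults = t$n_adults, n_male = t$n_male,
             n_female = t$n_female, n_pups = t$n_pups,
             stringsAsFactors = FALSE)
}

#' Metrics table for a list of territory records
#'
#' @param records List of [territory_record()] objects.
#' @inheritParams compute_metrics
#' @return Row-bound data.frame of [compute_metrics()] results with `season`
#'   as a factor whose reference level is `mating`, so model contrasts are
#'   post-vs-mating and pre-vs-mating.
#' @export
metrics_table <- function(records, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  out <- do.call(rbind, lapply(records, compute_metrics, divisor = divisor))
  out$season <- factor(out$season, levels = c("mating", "post_mating", "pre_mating"))
  out
}
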