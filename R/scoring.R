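# Food-source scoring scheme and area-standardized census densities.

#' Food-source category table
#'
#' The eight anthropogenic food-source categories available to free-ranging
#' dogs, with the ordinal quality/quantity score attached to each. Higher
#' scores indicate richer, more reliable access (a meat/fish shop scores 8, an
#' uncovered household dustbin scores 1).
#'
#' @return A data.frame with columns `code` (integer 1-8), `label`, and
#'   `score` (integer 8..1).
#' @export
#' @examples
#' resource_categories()
resource_categories <- function() {
  data.frame(
    code = 1:8,
    label = c("meat/fish shop",
              "eatery/restaurant/hostel",
              "direct feeding by human or NGO",
              "open garbage dump/occasional carcass",
              "tea shop or temple",
              "direct feeding by begging",
              "grocery/sweet shop/bakery",
              "household/eatery dustbin"),
    score = c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Look up scores for category codes
#'
#' @param code Integer vector of category codes in 1..8.
#' @return Integer vector of scores.
#' @export
category_score <- function(code) {
  if (length(code) == 0) return(integer(0))
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 1L | code > 8L))
    stop("category codes must be integers in 1..8", call. = FALSE)
  resource_categories()$score[code]
}

#' Construct a set of resource points
#'
#' @param xy Two-column matrix of planar metre coordinates (may have 0 rows).
#' @param category Integer vector of category codes (1..8), one per point.
#' @return A data.frame of class `resource_points` with columns `x`, `y`,
#'   `category`, `score`.
#' @export
resource_points <- function(xy, category) {
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  if (nrow(xy) != length(category))
    stop("one category code per point required", call. = FALSE)
  out <- data.frame(x = xy[, 1], y = xy[, 2],
                    category = as.integer(category),
                    score = category_score(category))
  class(out) <- c("resource_points", "data.frame")
  out
}

#' Construct a census site
#'
#' One census survey unit: a settlement polygon, its stratum label, the mapped
#' resource points, and the dogs recorded during the spot census.
#'
#' @param id Site identifier.
#' @param polygon A [polygon2d()] delineating the surveyed settlement.
#' @param settlement `"rural"` or `"urban"`.
#' @param resources A [resource_points()] data.frame (planar coordinates in
#'   the same frame as `polygon`).
#' @param dogs A data.frame with one row per dog record and columns
#'   `sex` (`"M"`, `"F"`, `"U"`) and `age` (`"pup"`, `"juvenile"`, `"adult"`).
#' @return An object of class `census_site`.
#' @details Resource points lying outside the polygon trigger a warning, not
#'   an error: boundary GPS noise is expected in field data. Polygon areas
#'   outside the surveyed size range of roughly 1.29-161 ha also warn.
#' @export
census_site <- function(id, polygon, settlement,
                        resources = resource_points(matrix(numeric(0), 0, 2), integer(0)),
                        dogs = data.frame(sex = character(0), age = character(0))) {
  stopifnot(inherits(polygon, "polygon2d"))
  settlement <- match.arg(settlement, c("rural", "urban"))
  if (!all(dogs$sex %in% c("M", "F", "U")))
    stop("dog sex must be M, F or U", call. = FALSE)
  if (!all(dogs$age %in% c("pup", "juvenile", "adult")))
    stop("dog age must be pup, juvenile or adult", call. = FALSE)
  area <- polygon_area_ha(polygon)
  if (area < 1.29 || area > 161)
    warning(sprintf("site %s: area %.3g ha outside the surveyed 1.29-161 ha range", id, area))
  if (nrow(resources) > 0) {
    inside <- points_in_polygon(cbind(resources$x, resources$y), polygon)
    if (any(!inside))
      warning(sprintf("site %s: %d resource point(s) fall outside the polygon", id, sum(!inside)))
  }
  structure(list(id = id, polygon = polygon, settlement = settlement,
                 area_ha = area, resources = resources, dogs = dogs),
            class = "census_site")
}

#' @export
print.census_site <- function(x, ...) {
  cat(sprintf("<census_site %s: %s, %.3g ha, %d resource points, %d dogs>\n",
              x$id, x$settlement, x$area_ha, nrow(x$resources), nrow(x$dogs)))
  invisible(x)
}

#' Sum of food-source scores
#'
#' @param points A [resource_points()] data.frame (or anything with a
#'   `score`/`category` column).
#' @return The total score, 0 for an empty set.
#' @export
score_sum <- function(points) {
  if (is.null(points) || nrow(points) == 0) return(0)
  sc <- if (!is.null(points$score)) points$score else category_score(points$category)
  sum(sc)
}

#' Area-standardized resource density of a census site
#'
#' Total food-source score inside the survey polygon divided by polygon area:
#' score per hectare.
#'
#' @param site A [census_site()].
#' @return Resource density in score per hectare.
#' @export
resource_density <- function(site) {
  stopifnot(inherits(site, "census_site"))
  if (!is.finite(site$area_ha) || site$area_ha <= 0)
    stop("site polygon has non-positive area", call. = FALSE)
  score_sum(site$resources) / site$area_ha
}

#' Dog density of a census site
#'
#' Number of recorded dogs divided by polygon area (dogs per hectare). Pups
#' and juveniles are included: the spot census records age class but all
#' observed dogs enter the density.
#'
#' @param site A [census_site()].
#' @param sex Optional restriction: `"M"`, `"F"`, or `"U"`; default counts all
#'   records.
#' @return Dogs per hectare.
#' @export
dog_density <- function(site, sex = NULL) {
  stopifnot(inherits(site, "census_site"))
  if (!is.finite(site$area_ha) || site$area_ha <= 0)
    stop("site polygon has non-positive area", call. = FALSE)
  n <- if (is.null(sex)) nrow(site$dogs) else sum(site$dogs$sex == sex)
  n / site$area_ha
}
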