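# Planar geometry primitives shared by the census and territory pipelines.
# Internal unit is metres; areas are reported in hectares.

#' WGS84 ellipsoid constants
#' @noRd
.wgs84 <- list(a = 6378137, e2 = 0.00669437999014)

.meridional_radius <- function(lat_rad) {
  .wgs84$a * (1 - .wgs84$e2) / (1 - .wgs84$e2 * sin(lat_rad)^2)^1.5
}

.normal_radius <- function(lat_rad) {
  .wgs84$a / sqrt(1 - .wgs84$e2 * sin(lat_rad)^2)
}

#' Define a local planar projection for a study site
#'
#' Sets up a local planarization centred on `(lon0, lat0)`: northings use the
#' ellipsoidal meridional radius of curvature at the origin, eastings use the
#' prime-vertical radius scaled by each point's own latitude, so meridian
#' convergence is carried exactly. Over extents up to ~50 km, planar distances
#' agree with WGS84 geodesics to better than 0.1%.
#'
#' @param lon0,lat0 Origin longitude and latitude in decimal degrees.
#' @return An object of class `local_projection`.
#' @seealso [project_points()], [unproject_points()]
#' @export
#' @examples
#' prj <- local_projection(88.36, 22.57)
#' project_points(cbind(88.36, 22.58), prj)
local_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0))
  if (lat0 < -90 || lat0 > 90 || lon0 < -180 || lon0 > 180)
    stop("projection origin out of range", call. = FALSE)
  structure(
    list(lon0 = lon0, lat0 = lat0,
         M = .meridional_radius(lat0 * pi / 180),
         N = .normal_radius(lat0 * pi / 180),
         method = "local_planar_ellipsoidal"),
    class = "local_projection")
}

#' Project geographic coordinates to local planar metres
#'
#' @param lonlat A two-column matrix (or data.frame) of longitude, latitude in
#'   decimal degrees.
#' @param projection A [local_projection()].
#' @return A two-column matrix with columns `x`, `y` in metres, rows in input
#'   order.
#' @export
project_points <- function(lonlat, projection) {
  stopifnot(inherits(projection, "local_projection"))
  lonlat <- as.matrix(lonlat)
  if (ncol(lonlat) != 2) stop("lonlat must have two columns", call. = FALSE)
  lon <- lonlat[, 1]; lat <- lonlat[, 2]
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180", call. = FALSE)
  rad <- pi / 180
  y <- projection$M * (lat - projection$lat0) * rad
  x <- projection$N * cos(lat * rad) * (lon - projection$lon0) * rad
  cbind(x = x, y = y)
}

#' Invert a local planar projection
#'
#' @param xy Two-column matrix of planar metres.
#' @inheritParams project_points
#' @return Two-column matrix of `lon`, `lat` in decimal degrees.
#' @export
unproject_points <- function(xy, projection) {
  stopifnot(inherits(projection, "local_projection"))
  xy <- as.matrix(xy)
  rad <- pi / 180
  lat <- projection$lat0 + xy[, 2] / projection$M / rad
  lon <- projection$lon0 + xy[, 1] / (projection$N * cos(lat * rad)) / rad
  cbind(lon = lon, lat = lat)
}

#' Construct a simple polygon from planar vertices
#'
#' Vertices are an ordered ring (the closing edge back to the first vertex is
#' implied). The constructor validates vertex count, finiteness, non-zero area
#' and (for small polygons) simplicity.
#'
#' @param vertices Two-column matrix of x, y metre coordinates, one row per
#'   vertex, >= 3 rows.
#' @param check_simple Check for self-intersection (O(n^2); default TRUE).
#' @return An object of class `polygon2d`.
#' @export
polygon2d <- function(vertices, check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must have two columns", call. = FALSE)
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  # drop a duplicated closing vertex if supplied
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 distinct vertices", call. = FALSE)
  if (abs(.shoelace(vertices)) < 1e-9)
    stop("degenerate polygon: zero area (collinear vertices?)", call. = FALSE)
  if (check_simple && .self_intersects(vertices))
    stop("polygon is self-intersecting", call. = FALSE)
  structure(list(vertices = unname(vertices)), class = "polygon2d")
}

#' @export
print.polygon2d <- function(x, ...) {
  cat(sprintf("<polygon2d: %d vertices, %.4g ha>\n",
              nrow(x$vertices), polygon_area_ha(x)))
  invisible(x)
}

# signed shoelace area in m^2
.shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# proper-crossing test between non-adjacent edges (endpoint touching allowed)
.self_intersects <- function(v) {
  n <- nrow(v)
  if (n > 400) return(FALSE)  # generator polygons are star-shaped by construction
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      d1 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area in hectares
#'
#' Shoelace area of the vertex ring divided by 10,000. Orientation is ignored
#' (absolute value), and the result is invariant to rotation of the vertex
#' order.
#'
#' @param poly A [polygon2d()] or a two-column vertex matrix.
#' @return Area in hectares.
#' @export
#' @examples
#' sq <- polygon2d(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' polygon_area_ha(sq)  # 1 ha
polygon_area_ha <- function(poly) {
  v <- if (inherits(poly, "polygon2d")) poly$vertices else polygon2d(poly)$vertices
  abs(.shoelace(v)) / 1e4
}

#' Convex hull of planar points
#'
#' Minimal convex polygon containing all input points; hull vertices are a
#' subset of the inputs. Used to turn recorded territory marking/defence
#' points into a territory polygon.
#'
#' @param points Two-column matrix of x, y metres (>= 3 points, not all
#'   collinear).
#' @return A [polygon2d()] whose vertices trace the hull.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points for a hull", call. = FALSE)
  idx <- grDevices::chull(points[, 1], points[, 2])
  if (length(idx) < 3 || abs(.shoelace(points[idx, , drop = FALSE])) < 1e-9)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  polygon2d(points[idx, , drop = FALSE], check_simple = FALSE)
}

# vectorized even-odd crossing test (no boundary handling); m points x n edges
.in_poly <- function(pts, v) {
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  wx <- v[c(2:n, 1), 1]; wy <- v[c(2:n, 1), 2]
  x <- pts[, 1]; y <- pts[, 2]
  Y <- outer(y, vy, ">"); W <- outer(y, wy, ">")
  crosses <- Y != W
  # x-coordinate of each edge at height y
  XI <- outer(y, vy, "-") * rep(( wx - vx) / (wy - vy), each = length(y)) +
    rep(vx, each = length(y))
  dim(XI) <- c(length(y), n)
  hits <- crosses & (x < XI)
  rowSums(hits, na.rm = TRUE) %% 2 == 1
}

#' Point-in-polygon test
#'
#' Even-odd ray casting; points exactly on the boundary count as inside.
#'
#' @param points Two-column matrix of x, y.
#' @param poly A [polygon2d()].
#' @return Logical vector, one entry per point.
#' @export
points_in_polygon <- function(points, poly) {
  stopifnot(inherits(poly, "polygon2d"))
  pts <- as.matrix(points)
  if (nrow(pts) == 0) return(logical(0))
  v <- poly$vertices
  inside <- .in_poly(pts, v)
  if (all(inside)) return(inside)
  # boundary points count as inside
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  wx <- v[c(2:n, 1), 1]; wy <- v[c(2:n, 1), 2]
  for (k in which(!inside)) {
    d <- .point_segment_dist(pts[k, 1], pts[k, 2], vx, vy, wx, wy)
    if (min(d) < 1e-9) inside[k] <- TRUE
  }
  inside
}

.point_segment_dist <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / pmax(len2, 1e-300)))
  px <- ax + t * dx; py <- ay + t * dy
  sqrt((x - px)^2 + (y - py)^2)
}
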