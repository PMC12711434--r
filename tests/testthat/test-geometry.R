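test_that("projection maps identical points to zero distance and preserves order", {
  prj <- local_projection(88.36, 22.57)
  xy <- project_points(rbind(c(88.40, 22.60), c(88.40, 22.60)), prj)
  expect_equal(sqrt(sum((xy[1, ] - xy[2, ])^2)), 0)

  pts <- cbind(88.36 + runif(10, -0.1, 0.1), 22.57 + runif(10, -0.1, 0.1))
  a <- project_points(pts, prj)
  perm <- sample(10)
  b <- project_points(pts[perm, ], prj)
  expect_equal(b, a[perm, ])
})

test_that("a 0.01 degree latitude separation projects to the geodesic arc length", {
  prj <- local_projection(0, 0)
  xy <- project_points(rbind(c(0, 0), c(0, 0.01)), prj)
  d <- sqrt(sum((xy[1, ] - xy[2, ])^2))
  expect_equal(d, 1105.7, tolerance = 1 / 1105.7)
})

test_that("planar distances track WGS84 geodesics within 0.1% over a 50 km extent", {
  library(geosphere)
  set.seed(71)
  lon0 <- 88.36; lat0 <- 22.57
  prj <- local_projection(lon0, lat0)
  ll <- cbind(lon0 + runif(25, -0.24, 0.24), lat0 + runif(25, -0.22, 0.22))
  xy <- project_points(ll, prj)
  for (i in 1:24) for (j in (i + 1):25) {
    dg <- distGeo(ll[i, ], ll[j, ])
    de <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    expect_lt(abs(de - dg) / dg, 0.001)
  }
  # round trip geographic -> planar -> geographic (< 1 m equivalent)
  back <- unproject_points(xy, prj)
  expect_equal(unname(back), unname(ll), tolerance = 1e-9)
})

test_that("projection rejects out-of-range coordinates", {
  prj <- local_projection(0, 0)
  expect_error(project_points(cbind(200, 10), prj), "out of range")
  expect_error(project_points(cbind(10, 95), prj), "out of range")
})

test_that("polygon areas match closed forms and a Monte-Carlo oracle", {
  expect_equal(polygon_area_ha(square_poly(100)), 1.0)
  tri <- polygon2d(rbind(c(0, 0), c(200, 0), c(0, 200)))
  expect_equal(polygon_area_ha(tri), 2.0)

  set.seed(42)
  theta <- sort(runif(8, 0, 2 * pi))
  v <- cbind(300 * exp(rnorm(8, 0, 0.3)) * cos(theta),
             300 * exp(rnorm(8, 0, 0.3)) * sin(theta))
  poly <- polygon2d(v)
  # rejection-sampling oracle on the bounding box
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  m <- 1e6
  pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
  frac <- mean(points_in_polygon(pts, poly))
  mc_area <- frac * (hi[1] - lo[1]) * (hi[2] - lo[2]) / 1e4
  expect_equal(polygon_area_ha(poly), mc_area, tolerance = 0.01)
})

test_that("area is invariant to rigid motions and scales quadratically", {
  set.seed(7)
  theta <- sort(runif(9, 0, 2 * pi))
  v <- cbind(50 * exp(rnorm(9, 0, 0.2)) * cos(theta),
             50 * exp(rnorm(9, 0, 0.2)) * sin(theta))
  a0 <- polygon_area_ha(polygon2d(v))
  # translation
  expect_equal(polygon_area_ha(polygon2d(sweep(v, 2, c(123.4, -56.7), "+"))),
               a0, tolerance = 1e-6)
  # rotation
  ang <- 0.83
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(polygon_area_ha(polygon2d(v %*% R)), a0, tolerance = 1e-6)
  # orientation reversal and vertex-ring rotation
  expect_equal(polygon_area_ha(polygon2d(v[nrow(v):1, ])), a0)
  expect_equal(polygon_area_ha(polygon2d(v[c(4:9, 1:3), ])), a0)
  # scaling: area by k^2, pairwise distances by k
  k <- 3.7
  expect_equal(polygon_area_ha(polygon2d(v * k)), a0 * k^2, tolerance = 1e-10)
  expect_equal(as.numeric(dist(v * k)), k * as.numeric(dist(v)))
})

test_that("degenerate polygons are rejected", {
  expect_error(polygon2d(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(polygon2d(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  bowtie <- rbind(c(0, 0), c(4, 2), c(4, 0), c(0, 1))  # unequal lobes
  expect_error(polygon2d(bowtie), "self-intersecting")
})

test_that("convex hull excludes interior points and matches a brute-force oracle", {
  sq_plus_centre <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq_plus_centre)
  expect_equal(nrow(h$vertices), 4)
  expect_equal(polygon_area_ha(h) * 1e4, 1)

  # brute force: p is a hull vertex iff it lies strictly inside no triangle
  # of other input points
  set.seed(9)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  combs <- utils::combn(50, 3)
  interior <- rep(FALSE, 50)
  for (k in seq_len(ncol(combs))) {
    tri <- combs[, k]
    for (i in setdiff(seq_len(50), tri)) {
      if (!interior[i] &&
          in_triangle(pts[i, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ]))
        interior[i] <- TRUE
    }
  }
  oracle_hull <- sort(which(!interior))
  h2 <- convex_hull(pts)
  found <- sort(apply(h2$vertices, 1, function(r)
    which(pts[, 1] == r[1] & pts[, 2] == r[2])))
  expect_equal(found, oracle_hull)

  # hull contains every input triangle
  for (k in sample(ncol(combs), 25)) {
    tri_area <- abs((function(v) v)(polygon_area_ha(polygon2d(
      pts[combs[, k], ], check_simple = FALSE))))
    expect_gte(polygon_area_ha(h2) + 1e-12, tri_area)
  }
})

test_that("convex hull is idempotent and rejects collinear input", {
  set.seed(10)
  pts <- cbind(rnorm(30), rnorm(30)) * 40
  h <- convex_hull(pts)
  h2 <- convex_hull(h$vertices)
  expect_equal(polygon_area_ha(h2), polygon_area_ha(h))
  expect_equal(nrow(h2$vertices), nrow(h$vertices))
  expect_error(convex_hull(cbind(1:5, 2 * (1:5))), "collinear")
})
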