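# Serialization: GeoJSON FeatureCollections (WGS84 lon/lat) for polygons and
# points, CSV dialects for census and territory tables. Internal planar
# coordinates are never serialized; geographic coordinates are produced by
# inverting the site projection.

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys Named list of [polygon2d()] objects (names become feature
#'   ids).
#' @param path Output file.
#' @param projection [local_projection()] used to express vertices as WGS84
#'   lon/lat.
#' @param properties Optional data.frame of per-feature properties (one row
#'   per polygon).
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path, projection, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    v <- polys[[i]]$vertices
    ll <- unproject_points(v, projection)
    ring <- rbind(ll, ll[1, , drop = FALSE])
    props <- list(id = names(polys)[i] %||% i)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file with Polygon features (WGS84 lon/lat).
#' @param projection [local_projection()] used to planarize; when `NULL` a
#'   projection centred on the mean coordinate is created.
#' @return List with `polygons` (named list of [polygon2d()]), `properties`
#'   (data.frame) and `projection`.
#' @export
read_polygons_geojson <- function(path, projection = NULL) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rings <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    do.call(rbind, lapply(f$geometry$coordinates[[1]],
                          function(p) c(p[[1]], p[[2]])))
  })
  if (is.null(projection)) {
    all_ll <- do.call(rbind, rings)
    projection <- local_projection(mean(all_ll[, 1]), mean(all_ll[, 2]))
  }
  polys <- lapply(rings, function(r) polygon2d(project_points(r, projection)))
  ids <- vapply(gj$features, function(f) as.character(f$properties$id %||% ""), "")
  names(polys) <- ids
  props <- lapply(gj$features, function(f) f$properties)
  keys <- unique(unlist(lapply(props, names)))
  properties <- as.data.frame(
    lapply(stats::setNames(keys, keys),
           function(k) vapply(props, function(p) {
             v <- p[[k]]
             if (is.null(v)) NA_character_ else as.character(v)
           }, "")), stringsAsFactors = FALSE)
  list(polygons = polys, properties = properties, projection = projection)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write resource points to CSV
#'
#' One row per point: `site_id`, `lon`, `lat`, `category_code`.
#'
#' @param points Named list of [resource_points()] (names = site ids).
#' @param path Output CSV.
#' @param projection [local_projection()] for planar-to-geographic inversion.
#' @return `path`, invisibly.
#' @export
write_resources_csv <- function(points, path, projection) {
  rows <- do.call(rbind, lapply(names(points), function(id) {
    p <- points[[id]]
    if (nrow(p) == 0) return(NULL)
    ll <- unproject_points(cbind(p$x, p$y), projection)
    data.frame(site_id = id, lon = ll[, 1], lat = ll[, 2],
               category_code = p$category)
  }))
  if (is.null(rows))
    rows <- data.frame(site_id = character(0), lon = numeric(0),
                       lat = numeric(0), category_code = integer(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write the category/score lookup to CSV
#'
#' Machine-readable mirror of [resource_categories()].
#'
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(path) {
  utils::write.csv(resource_categories(), path, row.names = FALSE)
  invisible(path)
}

#' Write a group x season metrics table to CSV
#'
#' @param metrics A [metrics_table()] data.frame.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficient table (estimate, SE, statistic, p, rate ratios and
#' CIs where applicable) plus fit summaries, mirroring the layout of the
#' published model tables.
#'
#' @param fit A `model_fit` or `gamma_glmm_fit`.
#' @param path Output JSON.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "model_fit")) {
    list(table = fit$table, n = fit$n, n_dropped = fit$n_dropped,
         deviance = fit$deviance, null_deviance = fit$null_deviance,
         aic = fit$aic, dispersion = fit$dispersion)
  } else if (inherits(fit, "gamma_glmm_fit")) {
    list(fixed = data.frame(term = names(fit$coefficients),
                            estimate = unname(fit$coefficients),
                            std.error = unname(fit$se),
                            z = unname(fit$zval), p.value = unname(fit$pval)),
         dispersion_model = data.frame(term = names(fit$disp_coefficients),
                                       estimate = unname(fit$disp_coefficients),
                                       std.error = unname(fit$disp_se)),
         group_sd = fit$sigma, loglik = fit$loglik, aic = fit$aic,
         bic = fit$bic, n = fit$n, singular = fit$singular,
         convergence = fit$convergence)
  } else stop("unsupported fit object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(path)
}
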