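#' Create a vector layer
#'
#' A minimal planar vector container: a tibble of features (one row each) with
#' a geometry list-column plus arbitrary attribute columns, and a single
#' projected CRS. Geometry encoding: points are length-2 numeric vectors;
#' polylines are n x 2 coordinate matrices (n >= 2); polygons are lists of
#' rings (closed n x 2 matrices, exterior first, subsequent rings are holes).
#'
#' @param features a data frame with at least columns `geom_type`
#'   (`"point"`, `"polyline"` or `"polygon"`) and `geometry` (list-column as
#'   described above); other columns are feature attributes.
#' @param crs projected CRS identifier.
#' @return A `vector_layer` object.
#' @export
vector_layer <- function(features, crs = "EPSG:26918") {
  check_projected_crs(crs)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("geom_type", "geometry") %in% names(features)))
  stopifnot(all(features$geom_type %in% c("point", "polyline", "polygon")))
  for (i in seq_len(nrow(features))) {
    g <- features$geometry[[i]]
    switch(features$geom_type[i],
      point = stopifnot(is.numeric(g), length(g) == 2),
      polyline = stopifnot(is.matrix(g), nrow(g) >= 2, ncol(g) == 2),
      polygon = {
        stopifnot(is.list(g), length(g) >= 1)
        for (ring in g) {
          stopifnot(is.matrix(ring), nrow(ring) >= 4,
                    all(ring[1, ] == ring[nrow(ring), ]))
        }
      })
  }
  structure(list(features = features, crs = crs), class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  cat(sprintf("<vector_layer> %d features (%s), %s\n", nrow(x$features),
              paste(unique(x$features$geom_type), collapse = ", "), x$crs))
  invisible(x)
}

#' Read and write vector layers as GeoJSON
#'
#' GeoJSON FeatureCollections with a named `crs` member (the layer's projected
#' CRS identifier). Layers in a geographic (degree) CRS are rejected with an
#' error asking for reprojection: all analysis here is metric.
#'
#' @param path path to a `.geojson` file.
#' @return `read_vector()` returns a [vector_layer()].
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  crs <- gj$crs$properties$name
  if (is.null(crs)) {
    stop("CRS is missing from ", path,
         "; write layers with write_vector() or add a named crs member",
         call. = FALSE)
  }
  check_projected_crs(crs)
  feats <- purrr::map(gj$features, function(f) {
    geom <- f$geometry
    coords <- geom$coordinates
    parsed <- switch(geom$type,
      Point = list(type = "point", g = as.numeric(unlist(coords))),
      LineString = list(type = "polyline", g = coord_matrix(coords)),
      Polygon = list(type = "polygon", g = purrr::map(coords, coord_matrix)),
      stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE))
    props <- if (is.null(f$properties)) list() else f$properties
    list(parsed = parsed, props = props)
  })
  prop_names <- unique(unlist(purrr::map(feats, ~ names(.x$props))))
  features <- tibble::tibble(
    geom_type = purrr::map_chr(feats, ~ .x$parsed$type),
    geometry = purrr::map(feats, ~ .x$parsed$g)
  )
  for (nm in prop_names) {
    features[[nm]] <- purrr::map(feats, ~ .x$props[[nm]]) |>
      purrr::map(~ if (is.null(.x)) NA else .x) |>
      unlist()
  }
  vector_layer(features, crs = crs)
}

coord_matrix <- function(coords) {
  do.call(rbind, purrr::map(coords, ~ as.numeric(unlist(.x))))
}

#' @rdname read_vector
#' @param layer a [vector_layer()] to write.
#' @export
write_vector <- function(layer, path) {
  stopifnot(inherits(layer, "vector_layer"))
  attr_cols <- setdiff(names(layer$features), c("geom_type", "geometry"))
  features <- purrr::map(seq_len(nrow(layer$features)), function(i) {
    g <- layer$features$geometry[[i]]
    geom <- switch(layer$features$geom_type[i],
      point = list(type = "Point", coordinates = as.numeric(g)),
      polyline = list(type = "LineString", coordinates = mat_to_coords(g)),
      polygon = list(type = "Polygon",
                     coordinates = purrr::map(g, mat_to_coords)))
    props <- purrr::map(rlang::set_names(attr_cols),
                        ~ layer$features[[.x]][[i]])
    list(type = "Feature", geometry = geom, properties = props)
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = layer$crs)),
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

mat_to_coords <- function(m) purrr::map(seq_len(nrow(m)), ~ m[.x, ])
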