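#' Extract wetland patches from a land-cover raster
#'
#' Connected components (8-connectivity) of the wetland classes, used both as
#' the wetland "polygon" layer for per-point distance covariates and as
#' candidate core habitat nodes. Patches are unions of 30 m cell squares;
#' distances to and between patches are computed edge-to-edge against those
#' squares.
#'
#' @param raster a categorical [raster_grid()].
#' @param codes raster values treated as wetland (default [wetland_codes()];
#'   use `5L` for a consolidated raster).
#' @return A tibble: `patch_id`, `n_cells`, `area` (m^2), `cells` (list-column
#'   of row/col matrices), `boundary` (list-column of boundary cell matrices).
#' @export
wetland_patches <- function(raster, codes = wetland_codes()) {
  stopifnot(inherits(raster, "raster_grid"))
  mask <- !is.na(raster$values) & raster$values %in% codes
  if (!any(mask)) {
    return(tibble::tibble(patch_id = integer(), n_cells = integer(),
                          area = numeric(), cells = list(), boundary = list()))
  }
  lab <- label_components(mask, connectivity = 8)
  ids <- sort(unique(lab[lab > 0]))
  cells <- purrr::map(ids, ~ which(lab == .x, arr.ind = TRUE))
  tibble::tibble(
    patch_id = ids,
    n_cells = purrr::map_int(cells, nrow),
    area = purrr::map_dbl(cells, nrow) * raster$cell_size^2,
    cells = cells,
    boundary = purrr::map(ids, ~ boundary_cells(lab, .x))
  )
}

# distance from point p to a patch (union of cell squares), plus the nearest
# point of the patch to p
patch_distance <- function(p, cells, grid) {
  ctr <- cell_center(grid, cells[, 1], cells[, 2])
  half <- grid$cell_size / 2
  gx <- pmax(0, abs(p[1] - ctr[, 1]) - half)
  gy <- pmax(0, abs(p[2] - ctr[, 2]) - half)
  d <- sqrt(gx^2 + gy^2)
  i <- which.min(d)
  nearest <- c(
    min(max(p[1], ctr[i, 1] - half), ctr[i, 1] + half),
    min(max(p[2], ctr[i, 2] - half), ctr[i, 2] + half)
  )
  list(dist = d[i], nearest = nearest)
}

# minimum edge-to-edge distance between two patches (boundary cell squares)
patch_patch_distance <- function(cells_a, cells_b, grid) {
  ca <- cell_center(grid, cells_a[, 1], cells_a[, 2])
  cb <- cell_center(grid, cells_b[, 1], cells_b[, 2])
  cs <- grid$cell_size
  gx <- pmax(0, abs(outer(ca[, 1], cb[, 1], "-")) - cs)
  gy <- pmax(0, abs(outer(ca[, 2], cb[, 2], "-")) - cs)
  min(sqrt(gx^2 + gy^2))
}

#' Wetland distance covariates for tethered points
#'
#' For each event on a route, wetland patches are split into the two sides of
#' the road by the sign of the cross product of the local route tangent with
#' the vector to the patch's nearest point. Three distances are returned:
#' `nearest` (min edge distance over the closer side), `opposite` (min over
#' the other side), and `between` (min edge-to-edge straight-line distance
#' between the two selected patches — which can be less than
#' `nearest + opposite` when the patches are laterally offset). A side with
#' no wetland within `search_radius` is censored at `search_radius` and
#' flagged; censored points should be excluded from distance statistics. A
#' point lying inside a wetland patch has `nearest = 0`.
#'
#' @param events tibble of linear events from [tether_points()].
#' @param network a `road_network`.
#' @param patches wetland patches from [wetland_patches()].
#' @param grid the [raster_grid()] the patches were derived from.
#' @param search_radius censoring radius in meters (default 5000).
#' @return A tibble: `record_id`, `nearest`, `opposite`, `between`,
#'   `censored` (logical).
#' @export
wetland_distances <- function(events, network, patches, grid,
                              search_radius = 5000) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(events) == 0) {
    return(tibble::tibble(record_id = integer(), nearest = numeric(),
                          opposite = numeric(), between = numeric(),
                          censored = logical()))
  }
  # patch bounding boxes (outer cell edges) for cheap lower-bound distances
  half <- grid$cell_size / 2
  bbox <- purrr::map(patches$cells, function(cells) {
    ctr <- cell_center(grid, cells[, 1], cells[, 2])
    c(min(ctr[, 1]) - half, max(ctr[, 1]) + half,
      min(ctr[, 2]) - half, max(ctr[, 2]) + half)
  })
  bb <- do.call(rbind, bbox)
  purrr::map(seq_len(nrow(events)), function(i) {
    rid <- events$route_id[i]
    g <- network$routes$geometry[[which(network$routes$route_id == rid)]]
    loc <- point_along_polyline(g, events$measure[i])
    p <- c(events$x[i], events$y[i])
    tangent <- loc$tangent
    d_side <- list(left = Inf, right = Inf)
    p_side <- list(left = NA_integer_, right = NA_integer_)
    # visit patches in order of bbox distance (a lower bound on the true
    # distance); stop once no remaining patch can improve either side
    bbd <- sqrt(pmax(0, pmax(bb[, 1] - p[1], p[1] - bb[, 2]))^2 +
                pmax(0, pmax(bb[, 3] - p[2], p[2] - bb[, 4]))^2)
    for (j in order(bbd)) {
      if (bbd[j] > search_radius) break
      if (bbd[j] > max(d_side$left, d_side$right)) break
      pd <- patch_distance(p, patches$cells[[j]], grid)
      if (pd$dist > search_radius) next
      s <- cross2(tangent, pd$nearest - p)
      sides <- if (pd$dist == 0 || s == 0) c("left", "right")
               else if (s > 0) "left" else "right"
      for (sd in sides) {
        if (pd$dist < d_side[[sd]]) {
          d_side[[sd]] <- pd$dist
          p_side[[sd]] <- j
        }
      }
    }
    dl <- d_side$left; dr <- d_side$right
    censored <- !is.finite(dl) || !is.finite(dr)
    nearest <- min(dl, dr)
    opposite <- max(min(dl, search_radius), min(dr, search_radius))
    if (!is.finite(nearest)) nearest <- search_radius
    between <- if (censored) NA_real_ else {
      jn <- if (dl <= dr) p_side$left else p_side$right
      jo <- if (dl <= dr) p_side$right else p_side$left
      if (jn == jo) 0 else patch_patch_distance(
        patches$boundary[[jn]], patches$boundary[[jo]], grid)
    }
    tibble::tibble(record_id = events$record_id[i], nearest = nearest,
                   opposite = opposite, between = between,
                   censored = censored)
  }) |>
    dplyr::bind_rows()
}

#' Land-cover composition within circular buffers
#'
#' Counts raster cells whose center lies within `radius` meters (Euclidean)
#' of each point and converts class counts to proportions over the valid
#' (non-nodata) cells. If no cell center falls inside the buffer (radius
#' smaller than half a cell), the single cell containing the point is used.
#'
#' @param points a data frame with columns `id`, `x`, `y`.
#' @param raster a categorical [raster_grid()] (typically consolidated, codes
#'   1-5).
#' @param radii buffer radii in meters (default `c(50, 100, 250)`).
#' @param classes class codes to report (default 1-5, the consolidated set).
#' @return A long tibble: `point_id`, `radius`, `class_code`, `class`,
#'   `proportion`, `valid_fraction`. Proportions sum to 1 per point and
#'   radius whenever any valid cell is present.
#' @export
buffer_composition <- function(points, raster, radii = c(50, 100, 250),
                               classes = 1:5) {
  stopifnot(inherits(raster, "raster_grid"))
  points <- tibble::as_tibble(points)
  cs <- raster$cell_size
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  class_names <- if (identical(classes, 1:5)) consolidated_classes()
                 else as.character(classes)
  out <- list()
  for (i in seq_len(nrow(points))) {
    p <- c(points$x[i], points$y[i])
    for (radius in radii) {
      r0 <- max(1L, floor((raster$origin[2] - (p[2] + radius)) / cs) + 1L)
      r1 <- min(nr, floor((raster$origin[2] - (p[2] - radius)) / cs) + 1L)
      c0 <- max(1L, floor(((p[1] - radius) - raster$origin[1]) / cs) + 1L)
      c1 <- min(nc, floor(((p[1] + radius) - raster$origin[1]) / cs) + 1L)
      sel <- NULL
      if (r0 <= r1 && c0 <= c1) {
        rc <- expand.grid(row = r0:r1, col = c0:c1)
        ctr <- cell_center(raster, rc$row, rc$col)
        inside <- (ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 <= radius^2
        sel <- rc[inside, , drop = FALSE]
      }
      if (is.null(sel) || nrow(sel) == 0) {
        rc1 <- coord_to_cell(raster, p[1], p[2])
        if (is.na(rc1[1, 1])) next
        sel <- data.frame(row = rc1[1, 1], col = rc1[1, 2])
      }
      vals <- raster$values[cbind(sel$row, sel$col)]
      valid <- !is.na(vals)
      n_valid <- sum(valid)
      counts <- vapply(classes, function(k) sum(vals[valid] == k), numeric(1))
      prop <- if (n_valid > 0) counts / n_valid else rep(NA_real_, length(classes))
      out[[length(out) + 1L]] <- tibble::tibble(
        point_id = points$id[i], radius = radius,
        class_code = classes, class = class_names,
        proportion = prop,
        valid_fraction = n_valid / nrow(sel)
      )
    }
  }
  dplyr::bind_rows(out)
}
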