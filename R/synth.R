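#' Configuration for the synthetic landscape generator
#'
#' Defines the study conditions emulated by the generator: a rural,
#' wetland-rich landscape (default class composition = the study region's
#' NLCD breakdown), a sparse road network, and road encounter records that
#' are attracted to wetlands and clustered at a small number of planted
#' hotspot segments. The defaults emulate the empirical structure the
#' analysis assumes: 249 road records, exponential wetland-distance decay at
#' a 100 m scale (the buffer scale with the strongest land-cover effects),
#' and about 40% of records concentrated in planted hotspots.
#'
#' @param extent landscape extent `(x, y)` in meters. The default 12 x 12 km
#'   with 16 roads gives about 190 road-km, so 249 records emulate the
#'   study's sampled-network record density of roughly 1 record per road-km.
#' @param cell_size raster cell size in meters (default 30).
#' @param class_proportions named fractions per NLCD code, summing to 1
#'   (default: the study region composition).
#' @param patch_scale characteristic patch diameter in meters (default 300).
#' @param n_routes number of roads (default 16).
#' @param n_encounters number of road encounter records (default 249).
#' @param wetland_attraction log-odds-style decay rate `beta_w >= 0`:
#'   background records are placed with weight
#'   `exp(-beta_w * distance_to_wetland / decay_scale)` (default 0.25 — a
#'   moderate attraction yielding standardized wetland-distance contrasts of
#'   roughly medium effect size against matched nulls).
#' @param decay_scale distance decay scale in meters (default 100).
#' @param n_planted_hotspots number of planted encounter clusters (default 8).
#' @param hotspot_fraction fraction of records belonging to planted clusters
#'   (default 0.4).
#' @param hotspot_sd along-road spread (SD, meters) of planted clusters
#'   (default 50).
#' @param n_occupancy number of wetland occupancy records placed inside
#'   road-adjacent wetland patches (default 54).
#' @param crs CRS identifier stamped on all outputs.
#' @param seed integer seed recorded in all outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(extent = c(12000, 12000), cell_size = 30,
                         class_proportions = default_class_proportions(),
                         patch_scale = 300, n_routes = 16,
                         n_encounters = 249, wetland_attraction = 0.25,
                         decay_scale = 100, n_planted_hotspots = 8,
                         hotspot_fraction = 0.4, hotspot_sd = 50,
                         n_occupancy = 54, crs = "EPSG:26918", seed = 1L) {
  stopifnot(length(extent) == 2, all(extent > 0), cell_size > 0,
            n_routes >= 0, n_encounters >= 0, wetland_attraction >= 0,
            n_planted_hotspots >= 0, hotspot_sd >= 0, n_occupancy >= 0,
            hotspot_fraction >= 0, hotspot_fraction <= 1)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ",
         format(sum(class_proportions)), ")", call. = FALSE)
  }
  structure(list(
    extent = extent, cell_size = cell_size,
    class_proportions = class_proportions, patch_scale = patch_scale,
    n_routes = n_routes, n_encounters = n_encounters,
    wetland_attraction = wetland_attraction, decay_scale = decay_scale,
    n_planted_hotspots = n_planted_hotspots,
    hotspot_fraction = hotspot_fraction, hotspot_sd = hotspot_sd,
    n_occupancy = n_occupancy, crs = crs, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default land-cover composition of the emulated study region
#'
#' Per-class fractions (named by NLCD code) of a rural northeastern New York
#' landscape: deciduous forest dominant, extensive hay/pasture and woody
#' wetlands, little development. Normalized to sum to exactly 1.
#'
#' @return Named numeric vector of fractions.
#' @export
default_class_proportions <- function() {
  p <- c(`41` = 37.40, `81` = 16.40, `90` = 15.99, `42` = 7.75, `82` = 5.37,
         `43` = 3.65, `21` = 3.01, `11` = 2.53, `52` = 2.13, `95` = 1.67,
         `22` = 1.49, `71` = 1.36, `23` = 0.85, `24` = 0.25, `31` = 0.16)
  p / sum(p)
}

# separable Gaussian smoothing with reflected boundaries
gaussian_smooth <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (o in -h:h) {
      j <- seq_len(n) + o
      while (any(j < 1 | j > n)) {  # reflect (repeatedly, for narrow grids)
        j <- ifelse(j < 1, 2 - j, j)
        j <- ifelse(j > n, 2 * n - j, j)
      }
      B[cbind(seq_len(n), j)] <- B[cbind(seq_len(n), j)] + k[o + h + 1]
    }
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a synthetic categorical landscape
#'
#' Smoothed Gaussian noise is thresholded at per-class quantiles so that the
#' realized class composition matches the configured proportions to within a
#' cell, while patches stay spatially autocorrelated at roughly
#' `patch_scale`. Classes are assigned to field quantile bands along a
#' moisture gradient (open water, then emergent and woody wetlands, forest,
#' shrub, grassland and agriculture, and developed land last), so wetlands
#' neighbor forest rather than cropland — the adjacency structure of a rural
#' lowland landscape.
#'
#' @param config a [synth_config()].
#' @return A categorical [raster_grid()] of NLCD codes.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nc <- round(config$extent[1] / config$cell_size)
  nr <- round(config$extent[2] / config$cell_size)
  field <- with_seed(config$seed, {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    gaussian_smooth(noise, sigma = config$patch_scale / (2 * config$cell_size))
  })
  codes <- as.integer(names(config$class_proportions))
  # wet-to-dry gradient: quantile bands of the smoothed field follow this
  # order so class adjacency mimics a real lowland landscape
  gradient <- c(11L, 95L, 90L, 41L, 43L, 42L, 52L, 71L, 81L, 82L, 31L,
                21L, 22L, 23L, 24L)
  ord <- order(match(codes, gradient, nomatch = length(gradient) + 1L), codes)
  codes <- codes[ord]
  props <- as.numeric(config$class_proportions)[ord]
  n_cells <- nr * nc
  counts <- diff(c(0, round(cumsum(props) * n_cells)))
  rank_order <- order(field)
  values <- integer(n_cells)
  start <- 1L
  for (i in seq_along(codes)) {
    if (counts[i] > 0) {
      values[rank_order[start:(start + counts[i] - 1L)]] <- codes[i]
      start <- start + counts[i]
    }
  }
  raster_grid(matrix(values, nr, nc), cell_size = config$cell_size,
              origin = c(0, nr * config$cell_size), crs = config$crs)
}

#' Generate a synthetic road network
#'
#' `n_routes` gently meandering roads spanning the extent, alternating
#' east-west and north-south so the network is connected by crossings.
#' Vertices stay inside the extent.
#'
#' @param config a [synth_config()].
#' @return A [vector_layer()] of polylines with a `name` attribute; total
#'   length is attached as attribute `total_length`.
#' @export
generate_road_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ex <- config$extent
  geoms <- with_seed(config$seed + 1L, {
    purrr::map(seq_len(config$n_routes), function(i) {
      horizontal <- i %% 2 == 1
      along_max <- if (horizontal) ex[1] else ex[2]
      across_max <- if (horizontal) ex[2] else ex[1]
      k <- ceiling(i / 2)
      n_side <- ceiling(config$n_routes / 2)
      base <- across_max * k / (n_side + 1) +
        stats::runif(1, -0.05, 0.05) * across_max
      along <- seq(0, along_max, by = 250)
      if (along[length(along)] < along_max) along <- c(along, along_max)
      wiggle <- cumsum(stats::rnorm(length(along), 0, 25))
      wiggle <- wiggle - mean(wiggle)
      across <- pmin(pmax(base + wiggle, 0.02 * across_max), 0.98 * across_max)
      if (horizontal) cbind(along, across) else cbind(across, along)
    })
  })
  layer <- vector_layer(tibble::tibble(
    geom_type = "polyline",
    geometry = purrr::map(geoms, unname),
    name = paste0("road_", seq_along(geoms))
  ), crs = config$crs)
  attr(layer, "total_length") <- sum(purrr::map_dbl(geoms, polyline_length))
  layer
}

#' Generate synthetic road encounter records with ground truth
#'
#' Places `n_encounters` records on the road network: background records are
#' sampled along the network with weight
#' `exp(-beta_w * distance_to_wetland / decay_scale)`, and
#' `n_planted_hotspots` Gaussian clusters (along-road SD `hotspot_sd`) are
#' planted at road positions flanked by occupied wetland patches on both
#' sides — positions that wetland-to-wetland movement corridors cross. All
#' records lie within 10 m of a road. Occupancy records (points inside
#' road-adjacent wetland patches of core-node size) are generated alongside
#' and shipped in the truth object.
#'
#' @param landscape a categorical [raster_grid()] from [generate_landscape()].
#' @param roads a [vector_layer()] from [generate_road_network()].
#' @param config a [synth_config()].
#' @return A list: `records` (tibble `id`, `x`, `y`, `route_id`, `measure`,
#'   `process`) and `truth` (a `synth_truth` list: `labels`, `intervals`,
#'   `occupancy`, `occupied_patches`, `seed`).
#' @export
generate_encounters <- function(landscape, roads, config) {
  stopifnot(inherits(config, "synth_config"))
  network <- build_routes(roads)
  wet_mask <- !is.na(landscape$values) & landscape$values %in% wetland_codes()
  if (config$wetland_attraction > 0 && !any(wet_mask)) {
    stop("landscape contains no wetland cells but wetland_attraction > 0",
         call. = FALSE)
  }
  with_seed(config$seed + 2L, {
    n_hot <- if (config$n_planted_hotspots > 0) {
      round(config$hotspot_fraction * config$n_encounters)
    } else 0L
    n_bg <- config$n_encounters - n_hot

    # along-network candidate grid, 25 m spacing
    cand <- purrr::map(seq_len(nrow(network$routes)), function(j) {
      len <- network$routes$length[j]
      ms <- seq(0, len, by = 25)
      g <- network$routes$geometry[[j]]
      pts <- purrr::map(ms, ~ point_along_polyline(g, .x))
      tibble::tibble(
        route_id = network$routes$route_id[j], measure = ms,
        x = purrr::map_dbl(pts, ~ .x$xy[1]),
        y = purrr::map_dbl(pts, ~ .x$xy[2]),
        tx = purrr::map_dbl(pts, ~ .x$tangent[1]),
        ty = purrr::map_dbl(pts, ~ .x$tangent[2])
      )
    }) |> dplyr::bind_rows()

    d_wet <- if (any(wet_mask)) {
      dt <- chamfer_distance(wet_mask, landscape$cell_size)
      v <- raster_value_lookup(dt, landscape, cand$x, cand$y)
      v[is.na(v)] <- max(dt[is.finite(dt)])
      v
    } else rep(0, nrow(cand))

    # occupancy: occupied wetland patches (> 1 ha) nearest the network
    patches <- wetland_patches(landscape)
    eligible <- which(patches$area > 10000)
    occ_pts <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                              patch_id = integer())
    occupied <- integer()
    if (length(eligible) > 0 && config$n_occupancy > 0) {
      # cheap patch-to-road distance: chamfer transform from road cells
      road_mask <- matrix(FALSE, nrow(landscape$values), ncol(landscape$values))
      rc <- coord_to_cell(landscape, cand$x, cand$y)
      rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
      road_mask[rc] <- TRUE
      road_dt <- chamfer_distance(road_mask, landscape$cell_size)
      road_d <- purrr::map_dbl(eligible, function(j) {
        b <- patches$boundary[[j]]
        min(road_dt[b])
      })
      take <- eligible[order(road_d)][seq_len(min(config$n_occupancy,
                                                  length(eligible)))]
      occupied <- patches$patch_id[take]
      occ_xy <- purrr::map(take, function(j) {
        cells <- patches$cells[[j]]
        ctr <- cell_center(landscape, cells[, 1], cells[, 2])
        ctr[sample.int(nrow(ctr), 1), ]
      })
      occ_pts <- tibble::tibble(
        id = seq_along(take),
        x = purrr::map_dbl(occ_xy, 1), y = purrr::map_dbl(occ_xy, 2),
        patch_id = occupied
      )
    }

    # planted cluster centers: road positions crossed by wetland-to-wetland
    # movement corridors. The corridors are real least-cost paths between
    # the occupied patches over the default resistance surface; when fewer
    # than two occupied patches exist, fall back to wetland-adjacent
    # positions.
    centers <- tibble::tibble(route_id = integer(), measure = numeric())
    if (config$n_planted_hotspots > 0) {
      score <- d_wet
      eligible <- rep(TRUE, nrow(cand))
      take_idx <- match(occupied, patches$patch_id)
      if (length(take_idx) >= 2) {
        nodes <- tibble::tibble(node_id = seq_along(take_idx),
                                cells = patches$cells[take_idx])
        resistance <- reclassify_resistance(landscape)
        lcps <- connect_nodes(nodes, resistance)
        if (nrow(lcps) > 0) {
          lcp_mask <- matrix(FALSE, nrow(landscape$values),
                             ncol(landscape$values))
          for (pth in lcps$path) {
            rc <- coord_to_cell(landscape, pth[, 1], pth[, 2])
            lcp_mask[rc[!is.na(rc[, 1]), , drop = FALSE]] <- TRUE
          }
          lcp_dt <- chamfer_distance(lcp_mask, landscape$cell_size)
          d_lcp <- raster_value_lookup(lcp_dt, landscape, cand$x, cand$y)
          d_lcp[is.na(d_lcp)] <- Inf
          # clusters must sit where a corridor crosses the road (within
          # 1.5 cells); among crossings prefer wetland-adjacent ones — a
          # crossing near the wetland endpoints is where a moving animal
          # actually meets the road. If fewer well-separated crossings
          # exist than requested, fewer clusters are planted (the truth
          # records how many): planting off-corridor would break the
          # generating model.
          eligible <- d_lcp <= 1.5 * landscape$cell_size
          if (!any(eligible)) eligible <- rep(TRUE, nrow(cand))
        }
      }
      sep <- max(600, 4 * config$hotspot_sd + 400)
      ord <- sample.int(nrow(cand))  # random among equally good candidates
      ord <- ord[order(score[ord])]
      chosen <- integer()
      for (i in ord) {
        if (length(chosen) >= config$n_planted_hotspots) break
        if (!eligible[i]) next
        if (all(sqrt((cand$x[chosen] - cand$x[i])^2 +
                     (cand$y[chosen] - cand$y[i])^2) >= sep)) {
          chosen <- c(chosen, i)
        }
      }
      centers <- cand[chosen, c("route_id", "measure")]
    }

    records <- list()
    labels <- character()
    if (n_bg > 0) {
      w <- exp(-config$wetland_attraction * d_wet / config$decay_scale)
      pick <- sample.int(nrow(cand), n_bg, replace = TRUE, prob = w)
      ms <- cand$measure[pick] + stats::runif(n_bg, -12.5, 12.5)
      records[[1]] <- place_on_network(network, cand$route_id[pick], ms)
      labels <- c(labels, rep("background", n_bg))
    }
    if (nrow(centers) > 0 && n_hot > 0) {
      sizes <- rep(floor(n_hot / nrow(centers)), nrow(centers))
      extra <- n_hot - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      for (k in seq_len(nrow(centers))) {
        if (sizes[k] == 0) next
        ms <- stats::rnorm(sizes[k], centers$measure[k], config$hotspot_sd)
        records[[length(records) + 1L]] <-
          place_on_network(network, rep(centers$route_id[k], sizes[k]), ms)
        labels <- c(labels, rep(paste0("hotspot_", k), sizes[k]))
      }
    }
    records <- dplyr::bind_rows(records)
    if (nrow(records) > 0) {
      records$id <- seq_len(nrow(records))
      records$process <- labels
      records <- dplyr::relocate(records, "id")
    } else {
      records <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                                route_id = integer(), measure = numeric(),
                                process = character())
    }
    intervals <- if (nrow(centers) > 0) {
      lens <- network$routes$length[match(centers$route_id,
                                          network$routes$route_id)]
      tibble::tibble(
        hotspot = seq_len(nrow(centers)),
        route_id = centers$route_id,
        center = centers$measure,
        start = pmax(0, centers$measure - 2 * config$hotspot_sd),
        end = pmin(lens, centers$measure + 2 * config$hotspot_sd)
      )
    } else {
      tibble::tibble(hotspot = integer(), route_id = integer(),
                     center = numeric(), start = numeric(), end = numeric())
    }
    truth <- structure(list(
      labels = tibble::tibble(id = records$id, process = records$process),
      intervals = intervals,
      occupancy = occ_pts,
      occupied_patches = occupied,
      seed = config$seed
    ), class = "synth_truth")
    list(records = records, truth = truth)
  })
}

# snap measures onto routes and emit jittered roadside coordinates
place_on_network <- function(network, route_ids, measures) {
  n <- length(measures)
  side <- sample(c(-1, 1), n, replace = TRUE)
  off <- stats::runif(n, 0, 5)
  rows <- purrr::map(seq_len(n), function(i) {
    j <- which(network$routes$route_id == route_ids[i])
    g <- network$routes$geometry[[j]]
    m <- min(max(measures[i], 0), network$routes$length[j])
    loc <- point_along_polyline(g, m)
    normal <- c(-loc$tangent[2], loc$tangent[1])
    tibble::tibble(x = loc$xy[1] + side[i] * off[i] * normal[1],
                   y = loc$xy[2] + side[i] * off[i] * normal[2],
                   route_id = route_ids[i], measure = m)
  })
  dplyr::bind_rows(rows)
}

# look up a value matrix aligned with `grid` at coordinates
raster_value_lookup <- function(values, grid, x, y) {
  rc <- coord_to_cell(grid, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}
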