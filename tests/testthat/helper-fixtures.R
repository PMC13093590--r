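# Shared fixtures, all built in code.

# a straight east-west road of given length as a vector layer
straight_road <- function(length = 1000, y = 0, crs = "EPSG:26918") {
  vector_layer(tibble::tibble(
    geom_type = "polyline",
    geometry = list(cbind(c(0, length), c(y, y)))
  ), crs = crs)
}

# several parallel straight roads
parallel_roads <- function(lengths, ys, crs = "EPSG:26918") {
  vector_layer(tibble::tibble(
    geom_type = "polyline",
    geometry = purrr::map2(lengths, ys, ~ cbind(c(0, .x), c(.y, .y)))
  ), crs = crs)
}

# a uniform categorical raster
uniform_raster <- function(code, nr = 10, nc = 10, cell = 30) {
  raster_grid(matrix(code, nr, nc), cell_size = cell)
}

# small synthetic scene shared by several suites
small_scene <- function(seed = 1, extent = 3000, n_routes = 4,
                        n_encounters = 40, n_planted = 2, n_occupancy = 8,
                        beta = 0.25) {
  cfg <- synth_config(extent = c(extent, extent), n_routes = n_routes,
                      n_encounters = n_encounters,
                      wetland_attraction = beta,
                      n_planted_hotspots = n_planted,
                      n_occupancy = n_occupancy, seed = seed)
  landscape <- generate_landscape(cfg)
  roads <- generate_road_network(cfg)
  enc <- generate_encounters(landscape, roads, cfg)
  list(cfg = cfg, landscape = landscape, roads = roads,
       records = enc$records, truth = enc$truth,
       network = build_routes(roads))
}

# independent shortest-path oracle: Bellman-Ford relaxation to a fixpoint on
# the 8-connected lattice (never calls the package's Dijkstra)
oracle_cost_distance <- function(values, cell_size, src_rc) {
  nr <- nrow(values); nc <- ncol(values)
  d <- matrix(Inf, nr, nc)
  d[src_rc] <- 0
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (is.na(values[r, c])) next
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]; c2 <- c + offs$dc[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(values[r2, c2])) next
        fac <- if (offs$dr[k] != 0 && offs$dc[k] != 0) sqrt(2) else 1
        w <- (values[r, c] + values[r2, c2]) / 2 * cell_size * fac
        if (d[r2, c2] + w < d[r, c] - 1e-12) {
          d[r, c] <- d[r2, c2] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}
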