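#' Build measured routes from road polylines
#'
#' Converts each polyline of a road layer into a linearly referenced route:
#' positions along it are addressed by a measure in meters from the route
#' origin (its first vertex). Zero-length polylines are dropped with a
#' warning.
#'
#' @param roads a [vector_layer()] of polylines.
#' @return A `road_network` object: a tibble of routes (`route_id`, `length`,
#'   `geometry` list-column) plus the CRS.
#' @export
build_routes <- function(roads) {
  stopifnot(inherits(roads, "vector_layer"))
  lines <- roads$features[roads$features$geom_type == "polyline", ]
  if (nrow(lines) == 0) stop("no polyline features in input", call. = FALSE)
  lens <- purrr::map_dbl(lines$geometry, polyline_length)
  dropped <- sum(lens <= 0)
  if (dropped > 0) {
    warning(dropped, " zero-length polyline(s) dropped", call. = FALSE)
  }
  keep <- lens > 0
  routes <- tibble::tibble(
    route_id = seq_len(sum(keep)),
    length = lens[keep],
    geometry = lines$geometry[keep]
  )
  structure(list(routes = routes, crs = roads$crs), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d routes, %.1f km total, %s\n",
              nrow(x$routes), sum(x$routes$length) / 1000, x$crs))
  invisible(x)
}

#' Total network length in meters
#' @param network a `road_network`.
#' @export
network_length <- function(network) sum(network$routes$length)

#' Tether points to the nearest route
#'
#' Assigns each point to the nearest route within `max_offset` meters and
#' records its along-route measure (arc-length projection) and perpendicular
#' offset. Points farther than `max_offset` from every route are excluded;
#' the exclusion count is attached as attribute `n_excluded`. Ties between
#' routes at identical distance go to the lower `route_id`.
#'
#' @param points a data frame with columns `id`, `x`, `y`.
#' @param network a `road_network` from [build_routes()].
#' @param max_offset maximum perpendicular distance in meters (default 10 m,
#'   the validity radius for a road occurrence record).
#' @return A tibble of linear events: `record_id`, `route_id`, `measure`,
#'   `offset`, `x`, `y` (snapped coordinates).
#' @export
tether_points <- function(points, network, max_offset = 10) {
  stopifnot(inherits(network, "road_network"))
  points <- tibble::as_tibble(points)
  out <- purrr::map(seq_len(nrow(points)), function(i) {
    p <- c(points$x[i], points$y[i])
    best <- NULL
    for (j in seq_len(nrow(network$routes))) {
      pr <- project_point_polyline(network$routes$geometry[[j]], p)
      # strict < keeps the first (lowest route_id) on exact ties
      if (is.null(best) || pr$offset < best$offset - 1e-12) {
        best <- pr
        best$route_id <- network$routes$route_id[j]
      }
    }
    if (best$offset <= max_offset) {
      tibble::tibble(record_id = points$id[i], route_id = best$route_id,
                     measure = best$measure, offset = best$offset,
                     x = best$xy[1], y = best$xy[2])
    } else {
      NULL
    }
  })
  events <- dplyr::bind_rows(out)
  if (nrow(events) == 0) {
    events <- tibble::tibble(record_id = integer(), route_id = integer(),
                             measure = numeric(), offset = numeric(),
                             x = numeric(), y = numeric())
  }
  attr(events, "n_excluded") <- nrow(points) - nrow(events)
  events
}

#' Trim a road network by occurrence proximity
#'
#' Retains only routes with at least one occurrence within `radius` meters
#' (inclusive) of any point of the route geometry, removing roads that were
#' plausibly never surveyed. The retained length is attached as attribute
#' `retained_length`.
#'
#' @param network a `road_network`.
#' @param occurrences a data frame with columns `x`, `y`.
#' @param radius inclusion radius in meters (default 100).
#' @return A `road_network` with the retained routes (original `route_id`s).
#' @export
trim_network <- function(network, occurrences, radius = 100) {
  stopifnot(inherits(network, "road_network"))
  occurrences <- tibble::as_tibble(occurrences)
  keep <- purrr::map_lgl(network$routes$geometry, function(g) {
    for (i in seq_len(nrow(occurrences))) {
      p <- c(occurrences$x[i], occurrences$y[i])
      if (dist_point_polyline(g, p) <= radius) return(TRUE)
    }
    FALSE
  })
  trimmed <- network
  trimmed$routes <- network$routes[keep, ]
  attr(trimmed, "retained_length") <- sum(trimmed$routes$length)
  trimmed
}

#' Generate matched null (pseudoabsence) points
#'
#' For each tethered occurrence event, places a comparison point on the same
#' route at `offset` meters road distance in either direction. A candidate
#' position is valid only if it lies on the route (measure within
#' `[0, length]`) and its along-road distance to every event on that route is
#' at least `min_separation`. When both directions are valid one is chosen by
#' a seeded coin flip; when neither is, the route is scanned outward from the
#' event in `step`-meter increments and the nearest valid position is taken
#' (ties at equal scan distance break toward increasing measure). Events with
#' no valid position yield no null point. Coincident null points are
#' deduplicated. Along-road distance is only defined within a route; events
#' on other routes do not constrain a candidate.
#'
#' @param events tibble of linear events from [tether_points()].
#' @param network a `road_network`.
#' @param offset target road distance from the event in meters (default 1000).
#' @param min_separation minimum road distance from every event (default 1000).
#' @param step outward scan increment in meters (default 10).
#' @param seed integer seed for the direction coin flips.
#' @return A tibble: `record_id` (paired event), `route_id`, `measure`, `x`,
#'   `y`. Attributes `n_failed` (events with no valid position) and
#'   `n_deduplicated`.
#' @export
generate_null_points <- function(events, network, offset = 1000,
                                 min_separation = 1000, step = 10,
                                 seed = 1L) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(events) == 0) {
    return(tibble::tibble(record_id = integer(), route_id = integer(),
                          measure = numeric(), x = numeric(), y = numeric()))
  }
  rng <- make_rng(seed)
  route_len <- rlang::set_names(network$routes$length, network$routes$route_id)
  by_route <- split(events$measure, events$route_id)
  n_failed <- 0L
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    rid <- as.character(events$route_id[i])
    len <- route_len[[rid]]
    ms <- by_route[[rid]]
    m0 <- events$measure[i]
    valid <- function(m) {
      m >= 0 && m <= len && all(abs(m - ms) >= min_separation - 1e-9)
    }
    cand <- c(m0 - offset, m0 + offset)
    ok <- vapply(cand, valid, logical(1))
    pick <- if (all(ok)) {
      cand[if (rng(1) < 0.5) 1 else 2]
    } else if (any(ok)) {
      cand[ok][1]
    } else {
      # outward scan: nearest valid position at distance offset + k*step,
      # increasing-measure side preferred on ties
      found <- NA_real_
      k <- 1
      max_k <- ceiling(len / step) + 1
      while (is.na(found) && k <= max_k) {
        d <- offset + k * step
        for (m in c(m0 + d, m0 - d)) {
          if (valid(m)) { found <- m; break }
        }
        k <- k + 1
      }
      found
    }
    if (is.na(pick)) {
      n_failed <<- n_failed + 1L
      return(NULL)
    }
    tibble::tibble(record_id = events$record_id[i],
                   route_id = events$route_id[i], measure = pick)
  })
  nulls <- dplyr::bind_rows(rows)
  if (nrow(nulls) == 0) {
    nulls <- tibble::tibble(record_id = integer(), route_id = integer(),
                            measure = numeric())
  }
  n_dedup <- 0L
  if (nrow(nulls) > 0) {
    dup <- duplicated(nulls[c("route_id", "measure")])
    n_dedup <- sum(dup)
    nulls <- nulls[!dup, ]
    xy <- purrr::map2(nulls$route_id, nulls$measure, function(rid, m) {
      g <- network$routes$geometry[[which(network$routes$route_id == rid)]]
      point_along_polyline(g, m)$xy
    })
    nulls$x <- purrr::map_dbl(xy, 1)
    nulls$y <- purrr::map_dbl(xy, 2)
  } else {
    nulls$x <- numeric()
    nulls$y <- numeric()
  }
  attr(nulls, "n_failed") <- n_failed
  attr(nulls, "n_deduplicated") <- n_dedup
  nulls
}

# Deterministic uniform RNG stream isolated from the global .Random.seed:
# returns a closure producing n U(0,1) draws per call.
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    out
  }
}

# run expr with a local deterministic seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  expr
}
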