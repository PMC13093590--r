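#' Network-constrained kernel density profile along a route
#'
#' One-dimensional Epanechnikov kernel density of tethered events along a
#' measured route, `K(u) = 0.75 (1 - u^2)` for `|u| <= 1` with
#' `u = (s - m_i) / h`. Each event contributes unit mass: its kernel is
#' renormalized by the analytically integrated mass remaining inside
#' `[0, route_length]` (edge correction), so the integral of the profile over
#' the route equals the number of events.
#'
#' @param measures event measures (m) on the route.
#' @param route_length route length in meters.
#' @param h kernel bandwidth (half-width) in meters, typically 100 or 200.
#' @param step sampling interval of the profile in meters (default 5).
#' @return A `density_profile`: tibble with columns `s` (measure) and
#'   `density` (events per meter), with `h`, `step`, `route_length`,
#'   `n_events` attached as attributes.
#' @export
kde_profile <- function(measures, route_length, h = 200, step = 5) {
  if (route_length < step) {
    stop("route shorter than the sampling step", call. = FALSE)
  }
  s <- seq(0, route_length, by = step)
  if (s[length(s)] < route_length) s <- c(s, route_length)
  dens <- rep(0, length(s))
  if (length(measures) > 0) {
    # Epanechnikov CDF (of u) up to clipping: F(u) = 0.75 (u - u^3/3) + 0.5
    epa_cdf <- function(u) {
      u <- pmin(pmax(u, -1), 1)
      0.75 * (u - u^3 / 3) + 0.5
    }
    mass <- epa_cdf((route_length - measures) / h) - epa_cdf((0 - measures) / h)
    u <- outer(s, measures, "-") / h
    k <- 0.75 * pmax(1 - u^2, 0) / h
    dens <- as.numeric(k %*% (1 / mass))
  }
  structure(tibble::tibble(s = s, density = dens),
            h = h, step = step, route_length = route_length,
            n_events = length(measures),
            class = c("density_profile", "tbl_df", "tbl", "data.frame"))
}

#' Integrated mass of a density profile
#'
#' Composite Simpson quadrature on the profile grid; the profile is piecewise
#' quadratic (a sum of Epanechnikov kernels), so the integral is recovered to
#' near machine precision away from kernel break points.
#'
#' @param profile a `density_profile`.
#' @export
profile_mass <- function(profile) {
  s <- profile$s; d <- profile$density
  n <- length(s)
  if (n < 3) return(sum(diff(s) * (d[-1] + d[-n]) / 2))
  # Simpson needs uniform spacing; the final interval may be shorter
  h <- s[2] - s[1]
  uniform <- which(abs(diff(s) - h) < 1e-9)
  n_u <- max(uniform) + 1L  # first n_u points are uniformly spaced
  m <- if ((n_u - 1) %% 2 == 0) n_u else n_u - 1L
  w <- rep(c(4, 2), length.out = m - 2)
  simpson <- h / 3 * (d[1] + sum(w * d[2:(m - 1)]) + d[m])
  tail_idx <- m:n
  tail <- if (length(tail_idx) > 1) {
    sum(diff(s[tail_idx]) * (d[tail_idx][-1] +
                             d[tail_idx][-length(tail_idx)]) / 2)
  } else 0
  simpson + tail
}

#' Monte-Carlo significance threshold for a density profile
#'
#' Simulates `n_sim` placements of `n_events` points uniformly along the
#' route, computes the kernel density profile of each, and takes the
#' pointwise `1 - alpha` quantile at each profile position. Densities above
#' this envelope are significantly denser than a uniform (complete spatial
#' randomness) null at that position.
#'
#' @param route_length route length in meters.
#' @param n_events number of events on the route.
#' @param h bandwidth in meters.
#' @param step profile sampling interval in meters.
#' @param n_sim number of Monte-Carlo placements (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return A tibble with columns `s` and `threshold`, with the simulation
#'   parameters attached as attributes.
#' @export
significance_threshold <- function(route_length, n_events, h = 200, step = 5,
                                   n_sim = 999, alpha = 0.05, seed = 1L) {
  s <- seq(0, route_length, by = step)
  if (s[length(s)] < route_length) s <- c(s, route_length)
  if (n_events == 0) {
    thr <- rep(0, length(s))
  } else {
    sims <- with_seed(seed, matrix(stats::runif(n_sim * n_events, 0, route_length),
                                   nrow = n_sim))
    qidx <- ceiling((1 - alpha) * n_sim)
    acc <- matrix(0, n_sim, length(s))
    for (j in seq_len(n_sim)) {
      acc[j, ] <- kde_profile(sims[j, ], route_length, h = h, step = step)$density
    }
    thr <- apply(acc, 2, function(col) sort(col)[qidx])
  }
  structure(tibble::tibble(s = s, threshold = thr),
            h = h, step = step, n_sim = n_sim, alpha = alpha, seed = seed,
            class = c("tbl_df", "tbl", "data.frame"))
}

#' Extract hotspot clusters from a density profile
#'
#' Maximal contiguous intervals where the density exceeds the significance
#' threshold; intervals separated by a gap shorter than the sampling step are
#' merged. Each cluster must contain at least one event; its centroid is the
#' excess-mass-weighted mean measure, located back onto the route geometry
#' when one is supplied.
#'
#' @param profile a `density_profile` from [kde_profile()].
#' @param threshold a threshold tibble from [significance_threshold()] (or a
#'   single number).
#' @param measures the event measures on the route.
#' @param route_geometry optional n x 2 polyline to locate centroids in x/y.
#' @return A tibble of hotspots: `start`, `end`, `length`, `n_events`,
#'   `centroid_measure`, `centroid_x`, `centroid_y`, `excess_mass`.
#' @export
extract_clusters <- function(profile, threshold, measures,
                             route_geometry = NULL) {
  s <- profile$s
  thr <- if (is.data.frame(threshold)) threshold$threshold
         else rep(threshold, length(s))
  stopifnot(length(thr) == length(s))
  above <- profile$density > thr
  if (!any(above)) return(empty_hotspots())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  iv <- data.frame(start = s[starts[runs$values]], end = s[ends[runs$values]])
  # merge intervals separated by a gap narrower than the step
  step <- attr(profile, "step")
  if (nrow(iv) > 1) {
    merged <- iv[1, ]
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - merged$end[nrow(merged)] < step) {
        merged$end[nrow(merged)] <- iv$end[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  excess <- pmax(0, profile$density - thr)
  out <- purrr::map(seq_len(nrow(iv)), function(i) {
    inside <- s >= iv$start[i] & s <= iv$end[i]
    n_ev <- sum(measures >= iv$start[i] & measures <= iv$end[i])
    if (n_ev == 0) return(NULL)
    w <- excess[inside]
    cm <- if (sum(w) > 0) sum(s[inside] * w) / sum(w)
          else mean(c(iv$start[i], iv$end[i]))
    em <- trapz(s[inside], w)
    tibble::tibble(start = iv$start[i], end = iv$end[i],
                   length = iv$end[i] - iv$start[i],
                   n_events = n_ev, centroid_measure = cm,
                   excess_mass = em)
  })
  hs <- dplyr::bind_rows(out)
  if (nrow(hs) == 0) return(empty_hotspots())
  if (!is.null(route_geometry)) {
    xy <- purrr::map(hs$centroid_measure,
                     ~ point_along_polyline(route_geometry, .x)$xy)
    hs$centroid_x <- purrr::map_dbl(xy, 1)
    hs$centroid_y <- purrr::map_dbl(xy, 2)
  } else {
    hs$centroid_x <- NA_real_
    hs$centroid_y <- NA_real_
  }
  hs
}

empty_hotspots <- function() {
  tibble::tibble(start = numeric(), end = numeric(), length = numeric(),
                 n_events = integer(), centroid_measure = numeric(),
                 excess_mass = numeric(), centroid_x = numeric(),
                 centroid_y = numeric())
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Cluster strength: ranked intensity of hotspots
#'
#' The strength of a hotspot is its excess mass — the integral of
#' `(density - threshold)+` over its interval — normalized by the maximum
#' excess mass over all hotspots on the analyzed network, so the most intense
#' hotspot scores 1 and strength is monotone in excess mass.
#'
#' @param hotspots a hotspot tibble (with column `excess_mass`), typically
#'   the row-bound hotspots of all routes.
#' @return The tibble with a `strength` column in (0, 1] appended.
#' @export
cluster_strength <- function(hotspots) {
  if (nrow(hotspots) == 0) {
    hotspots$strength <- numeric()
    return(hotspots)
  }
  mx <- max(hotspots$excess_mass)
  hotspots$strength <- if (mx > 0) hotspots$excess_mass / mx
                       else rep(0, nrow(hotspots))
  hotspots
}

#' Detect road encounter hotspots across a network
#'
#' Runs the full per-route hotspot analysis: kernel density profile,
#' Monte-Carlo significance envelope, cluster extraction, and network-wide
#' cluster-strength ranking. Events are analyzed per route; no kernel mass
#' crosses route endpoints.
#'
#' @param events tethered events from [tether_points()].
#' @param network a `road_network`.
#' @param h bandwidth in meters (default 200).
#' @param step profile sampling interval (default 5 m).
#' @param n_sim Monte-Carlo placements per route (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return A tibble of hotspots with `route_id`, interval columns and
#'   `strength`; analysis parameters are attached as attributes.
#' @export
find_hotspots <- function(events, network, h = 200, step = 5, n_sim = 999,
                          alpha = 0.05, seed = 1L) {
  stopifnot(inherits(network, "road_network"))
  out <- list()
  for (j in seq_len(nrow(network$routes))) {
    rid <- network$routes$route_id[j]
    len <- network$routes$length[j]
    if (len < step) next
    ms <- events$measure[events$route_id == rid]
    if (length(ms) == 0) next
    prof <- kde_profile(ms, len, h = h, step = step)
    thr <- significance_threshold(len, length(ms), h = h, step = step,
                                  n_sim = n_sim, alpha = alpha,
                                  seed = seed + j)
    hs <- extract_clusters(prof, thr, ms,
                           route_geometry = network$routes$geometry[[j]])
    if (nrow(hs) > 0) {
      hs$route_id <- rid
      out[[length(out) + 1L]] <- hs
    }
  }
  hs <- dplyr::bind_rows(out)
  if (nrow(hs) == 0) {
    hs <- empty_hotspots()
    hs$route_id <- integer()
    hs$strength <- numeric()
  } else {
    hs <- cluster_strength(hs)
    hs <- dplyr::arrange(hs, dplyr::desc(.data$strength))
  }
  hs <- dplyr::relocate(hs, "route_id")
  structure(hs, h = h, step = step, n_sim = n_sim, alpha = alpha,
            seed = seed, class = c("hotspots", class(tibble::tibble())))
}

#' Sub-polyline of a route between two measures
#'
#' Extracts the geometry of a road interval (e.g., a hotspot) as a polyline.
#'
#' @param network a `road_network`.
#' @param route_id route identifier.
#' @param start,end measures in meters.
#' @return An n x 2 coordinate matrix.
#' @export
route_subline <- function(network, route_id, start, end) {
  g <- network$routes$geometry[[which(network$routes$route_id == route_id)]]
  mv <- polyline_measures(g)
  p1 <- point_along_polyline(g, start)
  p2 <- point_along_polyline(g, end)
  mids <- which(mv > start & mv < end)
  rbind(p1$xy, g[mids, , drop = FALSE], p2$xy)
}
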