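#' Distance from features to the nearest least-cost path
#'
#' Minimum Euclidean distance from each feature — a point, or a hotspot's
#' road interval represented as its sub-polyline — to any LCP polyline; 0
#' when they touch or cross.
#'
#' @param features either a data frame of points (`x`, `y`) or a list of
#'   polylines (n x 2 matrices).
#' @param lcps a list of LCP polylines, or a tibble with a `path`
#'   list-column as returned by [connect_nodes()].
#' @return Numeric vector of distances in meters (Inf when no LCP exists).
#' @export
distance_to_nearest_lcp <- function(features, lcps) {
  segs <- segments_from_paths(lcp_paths(lcps))
  if (is.data.frame(features)) {
    features <- purrr::map(seq_len(nrow(features)),
                           ~ matrix(c(features$x[.x], features$y[.x]), 1, 2))
  }
  purrr::map_dbl(features, function(f) dist_polyline_segments(f, segs))
}

lcp_paths <- function(lcps) {
  if (is.data.frame(lcps) && "path" %in% names(lcps)) {
    purrr::compact(lcps$path)
  } else if (is.list(lcps)) {
    purrr::compact(lcps)
  } else {
    stop("lcps must be a list of polylines or a tibble with a path column",
         call. = FALSE)
  }
}

#' Length correction for hotspot-to-LCP distances
#'
#' Hotspots are intervals while null comparison locations are points, so
#' hotspots enjoy a purely geometric advantage in distance-to-LCP contrasts.
#' The correction adds half the mean hotspot length to each hotspot distance
#' (equivalently, measuring from the centroid), leaving null distances
#' unchanged — a conservative handicap against the hotspots.
#'
#' @param hotspot_distances distances from hotspot intervals to LCPs.
#' @param mean_hotspot_length mean hotspot length in meters.
#' @return Corrected distances.
#' @export
length_correction <- function(hotspot_distances, mean_hotspot_length) {
  hotspot_distances + mean_hotspot_length / 2
}

#' Compare hotspot and null distances to LCPs
#'
#' Medians, the median ratio (null / hotspot, reported at 1 decimal place),
#' and a Mann-Whitney test of the two distance samples.
#'
#' @param hotspot_distances,null_distances distance samples in meters.
#' @param alternative passed to [mann_whitney()] as the test of null
#'   distances against hotspot distances (default two-sided).
#' @return A one-row tibble: `n_hotspot`, `n_null`, `median_hotspot`,
#'   `median_null`, `ratio`, `U`, `z`, `p`.
#' @export
compare_to_lcp <- function(hotspot_distances, null_distances,
                           alternative = "two.sided") {
  mw <- mann_whitney(null_distances, hotspot_distances,
                     alternative = alternative)
  mh <- stats::median(hotspot_distances)
  mn <- stats::median(null_distances)
  tibble::tibble(
    n_hotspot = length(hotspot_distances), n_null = length(null_distances),
    median_hotspot = mh, median_null = mn,
    ratio = round(mn / mh, 1),
    U = mw$U, z = mw$z, p = mw$p
  )
}

#' Fraction of records and network length on LCP-crossed segments
#'
#' A route segment (a piece of the road geometry no longer than
#' `segment_length`) is "LCP-crossed" when any LCP polyline passes within
#' `tolerance` of it. The record fraction is the share of tethered events
#' whose measure falls on a crossed segment; the length fraction is the
#' crossed length over the total network length. When records concentrate
#' where movement corridors cross roads, the record fraction exceeds the
#' length fraction.
#'
#' @param events tethered events from [tether_points()].
#' @param network a `road_network`.
#' @param lcps LCP polylines (list or [connect_nodes()] tibble).
#' @param tolerance crossing tolerance in meters (default 30, one raster
#'   cell).
#' @param segment_length maximum segment length in meters (default 100);
#'   longer geometry edges are subdivided so crossing status has a bounded
#'   spatial granularity.
#' @return A one-row tibble: `record_fraction`, `length_fraction`,
#'   `crossed_length`, `total_length`, `n_records`, `n_records_crossed`.
#' @export
fraction_within_lcp <- function(events, network, lcps, tolerance = 30,
                                segment_length = 100) {
  stopifnot(inherits(network, "road_network"))
  segs <- segments_from_paths(lcp_paths(lcps))
  total_len <- network_length(network)
  crossed_len <- 0
  n_rec <- nrow(events)
  n_rec_crossed <- 0L
  for (j in seq_len(nrow(network$routes))) {
    g <- network$routes$geometry[[j]]
    len <- network$routes$length[j]
    rid <- network$routes$route_id[j]
    ev_m <- events$measure[events$route_id == rid]
    brk <- seq(0, len, by = segment_length)
    if (brk[length(brk)] < len) brk <- c(brk, len)
    for (i in seq_len(length(brk) - 1)) {
      piece <- route_subline(network, rid, brk[i], brk[i + 1])
      crossed <- nrow(segs) > 0 &&
        dist_polyline_segments(piece, segs) <= tolerance
      if (crossed) {
        crossed_len <- crossed_len + (brk[i + 1] - brk[i])
        n_rec_crossed <- n_rec_crossed +
          sum(ev_m >= brk[i] & ev_m <= brk[i + 1])
      }
    }
  }
  tibble::tibble(
    record_fraction = if (n_rec > 0) n_rec_crossed / n_rec else 0,
    length_fraction = if (total_len > 0) crossed_len / total_len else 0,
    crossed_length = crossed_len, total_length = total_len,
    n_records = n_rec, n_records_crossed = n_rec_crossed
  )
}

#' Validate hotspots against predicted movement corridors
#'
#' The full validation report: per-hotspot and per-null-point distances to
#' the nearest LCP, their medians and ratio, a Mann-Whitney contrast, the
#' same contrast after the hotspot length correction, and the enrichment of
#' records on LCP-crossed road segments.
#'
#' @param hotspots a hotspot tibble from [find_hotspots()] (needs `route_id`,
#'   `start`, `end`, `length`).
#' @param null_points a tibble of null points (`x`, `y`).
#' @param events tethered events (for the record-fraction statistic).
#' @param network a `road_network`.
#' @param lcps LCP polylines (list or [connect_nodes()] tibble).
#' @param tolerance crossing tolerance in meters for [fraction_within_lcp()].
#' @return A `validation_report` list: `hotspot_distances`,
#'   `null_distances`, `comparison`, `comparison_corrected`, `fractions`,
#'   `n_hotspots_intersecting_lcp`.
#' @export
validate_hotspots <- function(hotspots, null_points, events, network, lcps,
                              tolerance = 30) {
  sublines <- purrr::map(seq_len(nrow(hotspots)), function(i) {
    route_subline(network, hotspots$route_id[i], hotspots$start[i],
                  hotspots$end[i])
  })
  hd <- distance_to_nearest_lcp(sublines, lcps)
  nd <- distance_to_nearest_lcp(null_points, lcps)
  cmp <- compare_to_lcp(hd, nd)
  hd_corr <- length_correction(hd, mean(hotspots$length))
  cmp_corr <- compare_to_lcp(hd_corr, nd)
  structure(list(
    hotspot_distances = hd,
    null_distances = nd,
    comparison = cmp,
    comparison_corrected = cmp_corr,
    fractions = fraction_within_lcp(events, network, lcps,
                                    tolerance = tolerance),
    n_hotspots_intersecting_lcp = sum(hd == 0)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  hotspots: %d (%d intersect an LCP), null points: %d\n",
              length(x$hotspot_distances), x$n_hotspots_intersecting_lcp,
              length(x$null_distances)))
  cat(sprintf("  median distance to LCP: hotspot %.0f m, null %.0f m (ratio %.1f)\n",
              x$comparison$median_hotspot, x$comparison$median_null,
              x$comparison$ratio))
  cat(sprintf("  Mann-Whitney z = %.2f, p = %.3g (corrected: z = %.2f, p = %.3g)\n",
              x$comparison$z, x$comparison$p,
              x$comparison_corrected$z, x$comparison_corrected$p))
  cat(sprintf("  records on LCP-crossed segments: %.1f%% of records on %.1f%% of length\n",
              100 * x$fractions$record_fraction,
              100 * x$fractions$length_fraction))
  invisible(x)
}
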