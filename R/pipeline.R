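#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis with defaults
#' matching the study design: 10 m tether, 100 m network trim, 1 km matched
#' null points, 50/100/250 m covariate buffers, 100/200 m KDE bandwidths,
#' 1 ha minimum core-node area, 250 m hotspot buffers and null exclusion.
#'
#' @param synth a [synth_config()] describing the synthetic inputs (ignored
#'   when real inputs are passed to [run_all()]).
#' @param tether_offset max tether distance, m.
#' @param trim_radius network trimming radius, m.
#' @param null_offset,min_separation matched null-point parameters, m.
#' @param buffer_radii covariate buffer radii, m.
#' @param bandwidths KDE bandwidths, m.
#' @param kde_step KDE profile step, m.
#' @param alpha pointwise significance level of the hotspot envelope
#'   (default 0.005). The envelope is tested at every profile position, so
#'   the pointwise level is set an order of magnitude below the nominal 5%
#'   to control the multiplicity over the roughly `route_length / 2h`
#'   independent positions per route; at 5% pointwise, about 5% of network
#'   length — dozens of spurious single-record clusters — would be flagged
#'   under a uniform null.
#' @param n_sim Monte-Carlo placements per route.
#' @param min_node_area minimum core-node area, m^2.
#' @param hotspot_buffer buffer radius around hotspot centroids, m.
#' @param null_exclusion exclusion radius around centroids for contrast null
#'   points, m.
#' @param contrast_null_factor contrast null points per hotspot (default 10).
#' @param search_radius wetland-distance censoring radius, m.
#' @param lcp_tolerance LCP crossing tolerance, m.
#' @param resistance_table resistance lookup (default
#'   [default_resistance_table()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), tether_offset = 10,
                            trim_radius = 100, null_offset = 1000,
                            min_separation = 1000,
                            buffer_radii = c(50, 100, 250),
                            bandwidths = c(100, 200), kde_step = 5,
                            alpha = 0.005, n_sim = 999,
                            min_node_area = 10000, hotspot_buffer = 250,
                            null_exclusion = 250, contrast_null_factor = 10,
                            search_radius = 5000, lcp_tolerance = 30,
                            resistance_table = default_resistance_table(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full road-encounter hotspot analysis
#'
#' Executes the pipeline stages in order on synthetic inputs (or supplied
#' real inputs): generate → tether → trim → matched nulls → landscape
#' covariates → statistics → KDE hotspots → hotspot land-cover contrast →
#' least-cost paths → validation. Rerunning with the same configuration
#' reproduces the same results. Stage record counts are logged with
#' `message()`.
#'
#' @param config a [pipeline_config()].
#' @param landscape,roads,records optional real inputs (a [raster_grid()], a
#'   [vector_layer()] of polylines, a points tibble); when `NULL` they are
#'   generated from `config$synth`.
#' @param occupancy optional extra occurrence points (e.g. wetland survey
#'   records) used for core-node selection.
#' @param stages subset of stages to run (default all); later stages that
#'   depend on a skipped stage are skipped too.
#' @param out_dir optional directory: artifacts (rasters, layers, tables and
#'   a JSON manifest) are written there.
#' @param quiet suppress stage messages.
#' @return A list of stage outputs plus a `manifest` of parameters and
#'   counts.
#' @export
run_all <- function(config = pipeline_config(), landscape = NULL,
                    roads = NULL, records = NULL, occupancy = NULL,
                    stages = c("synth", "tether", "nulls", "metrics", "stats",
                               "hotspots", "contrast", "lcp", "validate"),
                    out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(config = config)
  truth <- NULL

  if (is.null(landscape) || is.null(roads) || is.null(records)) {
    if (!"synth" %in% stages) stop("no inputs and synth stage not requested")
    landscape <- generate_landscape(config$synth)
    roads <- generate_road_network(config$synth)
    enc <- generate_encounters(landscape, roads, config$synth)
    records <- enc$records
    truth <- enc$truth
    if (is.null(occupancy)) occupancy <- truth$occupancy
    say("synth: %d x %d cells, %d roads, %d records",
        nrow(landscape$values), ncol(landscape$values),
        config$synth$n_routes, nrow(records))
  }
  res$landscape <- landscape
  res$records <- records
  res$truth <- truth

  network <- build_routes(roads)
  events <- tether_points(records, network, max_offset = config$tether_offset)
  say("tether: %d/%d records tethered", nrow(events), nrow(records))
  trimmed <- trim_network(network, records, radius = config$trim_radius)
  say("trim: %d/%d routes retained (%.1f km)", nrow(trimmed$routes),
      nrow(network$routes), network_length(trimmed) / 1000)
  res$network <- trimmed
  res$events <- events

  if ("nulls" %in% stages) {
    res$null_points <- generate_null_points(
      events, trimmed, offset = config$null_offset,
      min_separation = config$min_separation, seed = config$seed + 10L)
    say("nulls: %d null points for %d events", nrow(res$null_points),
        nrow(events))
  }

  consolidated <- consolidate(landscape)
  patches <- wetland_patches(landscape)
  res$patches <- patches

  if ("metrics" %in% stages && !is.null(res$null_points)) {
    res$covariates <- build_covariate_table(
      events, res$null_points, trimmed, patches, landscape, consolidated,
      radii = config$buffer_radii, search_radius = config$search_radius)
    say("metrics: covariates for %d points", nrow(res$covariates))
  }

  if ("stats" %in% stages && !is.null(res$covariates)) {
    res$stats <- encounter_statistics(res$covariates)
    say("stats: top model '%s' (AIC %.1f)", res$stats$models$model[1],
        res$stats$models$aic[1])
  }

  if ("hotspots" %in% stages) {
    res$hotspots <- purrr::map(config$bandwidths, function(h) {
      find_hotspots(events, trimmed, h = h, step = config$kde_step,
                    n_sim = config$n_sim, alpha = config$alpha,
                    seed = config$seed + 20L)
    })
    names(res$hotspots) <- paste0("h", config$bandwidths)
    say("hotspots: %s",
        paste(sprintf("%d @ %s m", purrr::map_int(res$hotspots, nrow),
                      config$bandwidths), collapse = ", "))
  }

  main_h <- paste0("h", max(config$bandwidths))
  if ("contrast" %in% stages && !is.null(res$hotspots) &&
      nrow(res$hotspots[[main_h]]) > 0) {
    res$contrast <- hotspot_lulc_contrast(
      res$hotspots[[main_h]], trimmed, landscape,
      radius = config$hotspot_buffer, exclusion = config$null_exclusion,
      n_null = config$contrast_null_factor * nrow(res$hotspots[[main_h]]),
      seed = config$seed + 30L)
    say("contrast: %d land-cover classes compared", nrow(res$contrast))
  }

  if ("lcp" %in% stages) {
    resistance <- reclassify_resistance(landscape, config$resistance_table)
    occ_all <- dplyr::bind_rows(records[c("x", "y")],
                                if (!is.null(occupancy)) occupancy[c("x", "y")])
    nodes <- extract_core_nodes(landscape, occ_all,
                                min_area = config$min_node_area)
    res$resistance <- resistance
    res$nodes <- nodes
    res$lcps <- if (nrow(nodes) >= 2) connect_nodes(nodes, resistance)
                else tibble::tibble(node_a = integer(), node_b = integer(),
                                    cost = numeric(), length = numeric(),
                                    path = list())
    say("lcp: %d core nodes, %d least-cost paths", nrow(nodes),
        nrow(res$lcps))
  }

  if ("validate" %in% stages && !is.null(res$hotspots) &&
      !is.null(res$lcps) && !is.null(res$null_points) &&
      nrow(res$null_points) > 0 &&
      nrow(res$hotspots[[main_h]]) > 0) {
    res$validation <- validate_hotspots(
      res$hotspots[[main_h]], res$null_points, events, trimmed, res$lcps,
      tolerance = config$lcp_tolerance)
    say("validate: median LCP distance hotspot %.0f m vs null %.0f m",
        res$validation$comparison$median_hotspot,
        res$validation$comparison$median_null)
  }

  res$manifest <- build_manifest(config, res)
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  invisible(res)
}

# assemble the per-point covariate table (encounters + nulls): wetland
# distances and buffer compositions in wide form
build_covariate_table <- function(events, null_points, network, patches,
                                  landscape, consolidated, radii,
                                  search_radius) {
  ev_pts <- tibble::tibble(id = paste0("enc_", events$record_id),
                           x = events$x, y = events$y)
  nl_pts <- tibble::tibble(id = paste0("null_", null_points$record_id),
                           x = null_points$x, y = null_points$y)
  nl_ev <- tibble::tibble(record_id = null_points$record_id,
                          route_id = null_points$route_id,
                          measure = null_points$measure,
                          x = null_points$x, y = null_points$y)
  wd_enc <- wetland_distances(events, network, patches, landscape,
                              search_radius = search_radius)
  wd_null <- wetland_distances(nl_ev, network, patches, landscape,
                               search_radius = search_radius)
  comp <- buffer_composition(dplyr::bind_rows(ev_pts, nl_pts), consolidated,
                             radii = radii)
  comp_wide <- comp |>
    dplyr::mutate(var = paste0(.data$class, "_", .data$radius)) |>
    dplyr::select("point_id", "var", "proportion") |>
    tidyr::pivot_wider(names_from = "var", values_from = "proportion")
  wd <- dplyr::bind_rows(
    dplyr::mutate(wd_enc, point_id = paste0("enc_", .data$record_id),
                  is_encounter = 1L),
    dplyr::mutate(wd_null, point_id = paste0("null_", .data$record_id),
                  is_encounter = 0L)
  ) |>
    dplyr::select("point_id", "record_id", "is_encounter", "nearest",
                  "opposite", "between", "censored")
  dplyr::left_join(wd, comp_wide, by = "point_id")
}

# the statistical battery over a covariate table: group contrasts with
# effect sizes, paired contrasts, exhaustive logistic selection, agreement
encounter_statistics <- function(covariates) {
  cv <- covariates[!covariates$censored, ]
  num_vars <- setdiff(names(cv), c("point_id", "record_id", "is_encounter",
                                   "censored"))
  enc <- cv[cv$is_encounter == 1, ]
  nul <- cv[cv$is_encounter == 0, ]
  group <- purrr::map(num_vars, function(v) {
    x <- enc[[v]][!is.na(enc[[v]])]
    y <- nul[[v]][!is.na(nul[[v]])]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    dplyr::mutate(two_sample_summary(x, y), variable = v, .before = 1)
  }) |> dplyr::bind_rows()
  paired <- purrr::map(num_vars, function(v) {
    m <- dplyr::inner_join(enc[c("record_id", v)], nul[c("record_id", v)],
                           by = "record_id", suffix = c("_enc", "_null"))
    diffs <- m[[paste0(v, "_enc")]] - m[[paste0(v, "_null")]]
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 2) return(NULL)
    dplyr::mutate(paired_summary(diffs), variable = v, .before = 1)
  }) |> dplyr::bind_rows()
  predictors <- intersect(
    c("nearest", "opposite", "between", "developed_100", "grassland_100",
      "wetland_100"), names(cv))
  dat <- cv[stats::complete.cases(cv[c("is_encounter", predictors)]), ]
  models <- exhaustive_logistic(dat, "is_encounter", predictors)
  best <- attr(models, "fits")[[1]]
  probs <- predict_probability(best, dat)
  agreement <- classification_agreement(probs, dat$is_encounter)
  list(group = group, paired = paired, models = models,
       agreement = agreement)
}

#' Land-cover contrast of hotspots versus non-hotspot road points
#'
#' Buffers hotspot centroids and length-uniform null road points (rejected
#' within `exclusion` of any centroid), tabulates NLCD composition within
#' each buffer, and compares hotspot versus null percent cover per class
#' with Mann-Whitney tests. A combined low+medium+high developed class (the
#' sum of the three per-point proportions) is appended.
#'
#' @param hotspots hotspot tibble with `centroid_x`, `centroid_y`.
#' @param network a `road_network` (the trimmed analysis network).
#' @param raster the categorical NLCD [raster_grid()].
#' @param radius buffer radius, m (default 250).
#' @param exclusion centroid exclusion radius for null points, m (default
#'   250).
#' @param n_null number of null points (default 10 per hotspot).
#' @param seed integer seed for null placement.
#' @return A tibble: `class` (NLCD code or `"developed_combined"`),
#'   `mean_pct_hotspot`, `mean_pct_null`, `sd_pct_hotspot`, `sd_pct_null`,
#'   `U`, `z`, `p`.
#' @export
hotspot_lulc_contrast <- function(hotspots, network, raster, radius = 250,
                                  exclusion = 250,
                                  n_null = 10 * nrow(hotspots), seed = 1L) {
  stopifnot(nrow(hotspots) > 0)
  centroids <- tibble::tibble(id = paste0("hot_", seq_len(nrow(hotspots))),
                              x = hotspots$centroid_x,
                              y = hotspots$centroid_y)
  nulls <- with_seed(seed, sample_network_points(
    network, n_null, exclude_xy = centroids, exclusion = exclusion))
  nulls$id <- paste0("null_", seq_len(nrow(nulls)))
  codes <- sort(unique(raster$values[!is.na(raster$values)]))
  comp <- buffer_composition(dplyr::bind_rows(centroids[c("id", "x", "y")],
                                              nulls[c("id", "x", "y")]),
                             raster, radii = radius, classes = codes)
  comp$group <- ifelse(grepl("^hot_", comp$point_id), "hotspot", "null")
  dev_codes <- intersect(c(22, 23, 24), codes)
  combined <- comp |>
    dplyr::filter(.data$class_code %in% dev_codes) |>
    dplyr::summarise(proportion = sum(.data$proportion),
                     .by = c("point_id", "group")) |>
    dplyr::mutate(class = "developed_combined")
  per_class <- dplyr::bind_rows(
    dplyr::select(comp, "point_id", "group", "class", "proportion"),
    combined
  )
  per_class |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key) {
      h <- df$proportion[df$group == "hotspot"] * 100
      n <- df$proportion[df$group == "null"] * 100
      mw <- mann_whitney(h, n)
      tibble::tibble(mean_pct_hotspot = mean(h), mean_pct_null = mean(n),
                     sd_pct_hotspot = stats::sd(h), sd_pct_null = stats::sd(n),
                     U = mw$U, z = mw$z, p = mw$p)
    }) |>
    dplyr::ungroup()
}

# uniform-by-length points along a network, optionally excluding a radius
# around given coordinates
sample_network_points <- function(network, n, exclude_xy = NULL,
                                  exclusion = 0, max_tries = 50) {
  lens <- network$routes$length
  out <- list()
  tries <- 0
  while (length(out) < n && tries < max_tries) {
    need <- n - length(out)
    j <- sample.int(nrow(network$routes), need, replace = TRUE,
                    prob = lens / sum(lens))
    ms <- stats::runif(need, 0, lens[j])
    for (i in seq_len(need)) {
      g <- network$routes$geometry[[j[i]]]
      xy <- point_along_polyline(g, ms[i])$xy
      if (!is.null(exclude_xy) && exclusion > 0) {
        d <- sqrt((exclude_xy$x - xy[1])^2 + (exclude_xy$y - xy[2])^2)
        if (any(d <= exclusion)) next
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        route_id = network$routes$route_id[j[i]], measure = ms[i],
        x = xy[1], y = xy[2])
    }
    tries <- tries + 1
  }
  dplyr::bind_rows(out)
}

build_manifest <- function(config, res) {
  list(
    parameters = config[setdiff(names(config), c("synth", "resistance_table"))],
    synth = if (!is.null(config$synth)) unclass(config$synth) else NULL,
    counts = list(
      records = if (!is.null(res$records)) nrow(res$records) else NULL,
      events = if (!is.null(res$events)) nrow(res$events) else NULL,
      null_points = if (!is.null(res$null_points)) nrow(res$null_points) else NULL,
      routes = if (!is.null(res$network)) nrow(res$network$routes) else NULL,
      hotspots = if (!is.null(res$hotspots))
        purrr::map(res$hotspots, nrow) else NULL,
      core_nodes = if (!is.null(res$nodes)) nrow(res$nodes) else NULL,
      lcps = if (!is.null(res$lcps)) nrow(res$lcps) else NULL
    )
  )
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$landscape)) {
    write_raster(res$landscape, file.path(out_dir, "landscape.asc"))
  }
  if (!is.null(res$resistance)) {
    write_raster(res$resistance, file.path(out_dir, "resistance.asc"))
  }
  if (!is.null(res$records)) {
    readr::write_csv(res$records, file.path(out_dir, "records.csv"))
  }
  if (!is.null(res$events)) {
    readr::write_csv(res$events, file.path(out_dir, "events.csv"))
  }
  if (!is.null(res$null_points)) {
    readr::write_csv(res$null_points, file.path(out_dir, "null_points.csv"))
  }
  if (!is.null(res$covariates)) {
    readr::write_csv(res$covariates, file.path(out_dir, "covariates.csv"))
  }
  if (!is.null(res$hotspots)) {
    for (nm in names(res$hotspots)) {
      readr::write_csv(res$hotspots[[nm]],
                       file.path(out_dir, paste0("hotspots_", nm, ".csv")))
    }
  }
  if (!is.null(res$contrast)) {
    readr::write_csv(res$contrast, file.path(out_dir, "hotspot_contrast.csv"))
  }
  if (!is.null(res$stats)) {
    readr::write_csv(tibble::as_tibble(res$stats$models)[
      c("model", "k", "logLik", "aic", "delta_aic", "weight", "supported")],
      file.path(out_dir, "model_table.csv"))
    readr::write_csv(res$stats$group, file.path(out_dir, "group_contrasts.csv"))
    readr::write_csv(res$stats$paired, file.path(out_dir, "paired_contrasts.csv"))
  }
  if (!is.null(res$lcps) && nrow(res$lcps) > 0) {
    lcp_layer <- vector_layer(tibble::tibble(
      geom_type = "polyline",
      geometry = res$lcps$path,
      node_a = res$lcps$node_a, node_b = res$lcps$node_b,
      cost = res$lcps$cost
    ), crs = res$landscape$crs)
    write_vector(lcp_layer, file.path(out_dir, "lcps.geojson"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}
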