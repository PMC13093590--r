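test_that("a single class with proportion 1 yields a uniform raster", {
  cfg <- synth_config(extent = c(900, 900), class_proportions = c(`41` = 1),
                      n_routes = 1, n_encounters = 0, wetland_attraction = 0,
                      seed = 1)
  ls <- generate_landscape(cfg)
  expect_true(all(ls$values == 41))
})

test_that("realized class composition matches the configured proportions", {
  cfg <- synth_config(extent = c(15000, 15000), seed = 1)
  ls <- generate_landscape(cfg)  # 500 x 500 cells
  realized <- table(ls$values) / length(ls$values)
  target <- default_class_proportions()
  for (code in names(target)) {
    expect_lt(abs(realized[[code]] - target[[code]]), 0.02)
  }
  # wetland classes jointly occupy the regional share
  wet <- sum(realized[c("90", "95")])
  expect_lt(abs(wet - 0.1767), 0.02)
})

test_that("generators are deterministic in the seed", {
  cfg <- synth_config(extent = c(3000, 3000), n_routes = 3,
                      n_encounters = 25, n_planted_hotspots = 1,
                      n_occupancy = 5, seed = 9)
  expect_identical(generate_landscape(cfg), generate_landscape(cfg))
  r1 <- generate_road_network(cfg)
  r2 <- generate_road_network(cfg)
  expect_identical(r1$features$geometry, r2$features$geometry)
  ls <- generate_landscape(cfg)
  e1 <- generate_encounters(ls, r1, cfg)
  e2 <- generate_encounters(ls, r1, cfg)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$truth$intervals, e2$truth$intervals)
})

test_that("proportions that do not sum to one are rejected", {
  expect_error(synth_config(class_proportions = c(`41` = 0.6, `90` = 0.3)),
               "sum to 1")
})

test_that("road generator respects route count and the extent", {
  cfg <- synth_config(extent = c(4000, 4000), n_routes = 1, seed = 2)
  roads <- generate_road_network(cfg)
  expect_equal(nrow(roads$features), 1)
  cfg5 <- synth_config(extent = c(4000, 4000), n_routes = 5, seed = 2)
  roads5 <- generate_road_network(cfg5)
  for (g in roads5$features$geometry) {
    expect_true(all(g[, 1] >= 0 & g[, 1] <= 4000))
    expect_true(all(g[, 2] >= 0 & g[, 2] <= 4000))
  }
})

test_that("zero encounters give an empty record set and truth", {
  sc <- small_scene(seed = 3, n_encounters = 0, n_planted = 0)
  expect_equal(nrow(sc$records), 0)
  expect_equal(nrow(sc$truth$intervals), 0)
})

test_that("with no attraction and no planting, records are uniform along
           the road", {
  cfg <- synth_config(extent = c(12000, 300), n_routes = 1,
                      n_encounters = 500, wetland_attraction = 0,
                      n_planted_hotspots = 0, n_occupancy = 0, seed = 11)
  ls <- generate_landscape(cfg)
  roads <- generate_road_network(cfg)
  enc <- generate_encounters(ls, roads, cfg)
  net <- build_routes(roads)
  ks <- stats::ks.test(enc$records$measure, "punif", 0,
                       net$routes$length[1])
  expect_gt(ks$p.value, 0.01)
})

test_that("wetland attraction pulls records toward wetlands", {
  cfg <- synth_config(extent = c(6000, 6000), n_routes = 4,
                      n_encounters = 150, wetland_attraction = 2,
                      n_planted_hotspots = 0, n_occupancy = 0, seed = 5)
  ls <- generate_landscape(cfg)
  roads <- generate_road_network(cfg)
  enc <- generate_encounters(ls, roads, cfg)
  cfg0 <- synth_config(extent = c(6000, 6000), n_routes = 4,
                       n_encounters = 150, wetland_attraction = 0,
                       n_planted_hotspots = 0, n_occupancy = 0, seed = 5)
  unif <- generate_encounters(ls, roads, cfg0)
  patches <- wetland_patches(ls)
  d_of <- function(records) {
    net <- build_routes(roads)
    ev <- tether_points(records, net)
    wetland_distances(ev, net, patches, ls)$nearest
  }
  mw <- mann_whitney(d_of(enc$records), d_of(unif$records),
                     alternative = "less")
  expect_lt(mw$p, 0.01)
})

test_that("all records lie within 10 m of a road and are fully labelled", {
  sc <- small_scene(seed = 7)
  ev <- tether_points(sc$records, sc$network, max_offset = 10)
  expect_equal(nrow(ev), nrow(sc$records))
  expect_true(all(ev$offset <= 10))
  expect_setequal(sc$truth$labels$id, sc$records$id)
  expect_true(all(nzchar(sc$truth$labels$process)))
})

test_that("planted truth intervals lie on the generated network", {
  sc <- small_scene(seed = 13)
  tr <- sc$truth$intervals
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    j <- which(sc$network$routes$route_id == tr$route_id[i])
    expect_length(j, 1)
    expect_gte(tr$start[i], 0)
    expect_lte(tr$end[i], sc$network$routes$length[j])
    expect_lt(tr$start[i], tr$end[i])
  }
})

test_that("attraction without wetlands on the landscape is an error", {
  cfg <- synth_config(extent = c(900, 900), class_proportions = c(`41` = 1),
                      n_routes = 1, n_encounters = 10, n_occupancy = 0,
                      n_planted_hotspots = 0, seed = 1)
  ls <- generate_landscape(cfg)
  roads <- generate_road_network(cfg)
  expect_error(generate_encounters(ls, roads, cfg), "no wetland")
})
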