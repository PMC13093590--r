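test_that("consolidation maps NLCD codes to the five classes", {
  tab <- nlcd_consolidation()
  expect_equal(tab$class[tab$code == 41], "forest")
  expect_equal(tab$class[tab$code == 81], "grassland")
  expect_equal(sort(unique(tab$class)), sort(consolidated_classes()))
  expect_equal(nrow(tab), 15)

  r <- raster_grid(matrix(c(41, 81, 90, NA), 2, 2))
  out <- consolidate(r)
  expect_equal(out$values[1, 1], 3)  # forest
  expect_equal(out$values[2, 1], 4)  # grassland
  expect_equal(out$values[1, 2], 5)  # wetland
  expect_true(is.na(out$values[2, 2]))

  expect_error(consolidate(raster_grid(matrix(99, 1, 1))), "99")
})

test_that("resistance reclassification applies the default table", {
  tab <- default_resistance_table()
  expect_equal(tab$resistance[tab$code == 95], 466)
  expect_equal(tab$resistance[tab$code == 11], 1)
  expect_equal(tab$resistance[tab$code == 22], 117)
  r <- raster_grid(matrix(c(95, 11, 22, 82), 2, 2))
  out <- reclassify_resistance(r)
  expect_equal(as.vector(out$values), c(466, 1, 117, 2))
  expect_error(reclassify_resistance(raster_grid(matrix(7, 1, 1))), "7")
})

# build a raster with wetland cells at given (row, col) positions
wetland_scene <- function(wet_rc, nr = 40, nc = 40, cell = 30) {
  m <- matrix(41, nr, nc)
  m[wet_rc] <- 90
  raster_grid(m, cell_size = cell)
}

test_that("a point inside a wetland patch has nearest distance zero", {
  r <- wetland_scene(cbind(20, 18:22))
  patches <- wetland_patches(r)
  net <- build_routes(straight_road(1200, y = r$origin[2] - 19.5 * 30))
  pt <- cell_center(r, 20, 20)
  ev <- tibble::tibble(record_id = 1, route_id = 1,
                       measure = pt[1], x = pt[1], y = pt[2])
  wd <- wetland_distances(ev, net, patches, r)
  expect_equal(wd$nearest, 0)
})

test_that("side-split distances match the collinear construction", {
  # straight road along y = 600; single-cell wetlands 100 m above and
  # 200 m below the point at x = 600 (cell centers aligned with the point)
  r <- raster_grid(matrix(41, 40, 40), cell_size = 30)
  ctr_row <- 20  # y = 1200 - 19.5*30 = 615
  y_road <- cell_center(r, 20, 20)[2]
  x_pt <- cell_center(r, 20, 20)[1]
  # wetland cells 4 rows above and 7 rows below the point's row: cell
  # edges land 105 m and 195 m from the point (edges sit at 30k - 15 from
  # a cell-center point), 300 m edge-to-edge between the patches
  above <- coord_to_cell(r, x_pt, y_road + 4 * 30)
  below <- coord_to_cell(r, x_pt, y_road - 7 * 30)
  m <- r$values
  m[above] <- 90; m[below] <- 90
  r$values <- m
  patches <- wetland_patches(r)
  net <- build_routes(straight_road(1200, y = y_road))
  ev <- tibble::tibble(record_id = 1, route_id = 1, measure = x_pt,
                       x = x_pt, y = y_road)
  wd <- wetland_distances(ev, net, patches, r)
  expect_equal(wd$nearest, 105, tolerance = 1e-6)
  expect_equal(wd$opposite, 195, tolerance = 1e-6)
  expect_equal(wd$between, 300, tolerance = 1e-6)
  expect_false(wd$censored)
})

test_that("laterally offset wetlands give between < nearest + opposite", {
  r <- raster_grid(matrix(41, 40, 40), cell_size = 30)
  y_road <- cell_center(r, 20, 20)[2]
  x_pt <- cell_center(r, 20, 20)[1]
  above <- coord_to_cell(r, x_pt - 300, y_road + 115)
  below <- coord_to_cell(r, x_pt + 300, y_road - 215)
  m <- r$values; m[above] <- 90; m[below] <- 90; r$values <- m
  patches <- wetland_patches(r)
  net <- build_routes(straight_road(1200, y = y_road))
  ev <- tibble::tibble(record_id = 1, route_id = 1, measure = x_pt,
                       x = x_pt, y = y_road)
  wd <- wetland_distances(ev, net, patches, r)
  expect_lt(wd$between, wd$nearest + wd$opposite)
})

test_that("triangle-type bound holds across random scenes", {
  for (seed in 1:5) {
    sc <- small_scene(seed = seed, n_encounters = 15)
    ev <- tether_points(sc$records, sc$network)
    patches <- wetland_patches(sc$landscape)
    wd <- wetland_distances(ev, sc$network, patches, sc$landscape)
    ok <- !wd$censored & !is.na(wd$between)
    expect_true(all(wd$between[ok] <= wd$nearest[ok] + wd$opposite[ok] + 1e-6))
    expect_true(all(wd$nearest >= 0 & wd$opposite >= 0))
    expect_true(all(wd$nearest <= wd$opposite))
  }
})

test_that("a side with no wetland is censored at the search radius", {
  r <- wetland_scene(cbind(10, 20))  # single wetland, north of the road
  y_road <- cell_center(r, 30, 20)[2]
  net <- build_routes(straight_road(1200, y = y_road))
  x_pt <- cell_center(r, 30, 20)[1]
  ev <- tibble::tibble(record_id = 1, route_id = 1, measure = x_pt,
                       x = x_pt, y = y_road)
  wd <- wetland_distances(ev, net, wetland_patches(r), r,
                          search_radius = 5000)
  expect_true(wd$censored)
  expect_equal(wd$opposite, 5000)
})

test_that("buffer composition matches brute-force cell enumeration", {
  # half-plane split: west half forest, east half grassland
  m <- matrix(41, 50, 50)
  m[, 26:50] <- 81
  r <- raster_grid(m, cell_size = 30)
  cons <- consolidate(r)
  # point on the class boundary
  pt <- tibble::tibble(id = 1, x = 25 * 30, y = r$origin[2] - 25 * 30)
  bc <- buffer_composition(pt, cons, radii = 250)
  # brute force over all cells
  rc <- expand.grid(row = 1:50, col = 1:50)
  ctr <- cell_center(cons, rc$row, rc$col)
  inside <- (ctr[, 1] - pt$x)^2 + (ctr[, 2] - pt$y)^2 <= 250^2
  vals <- cons$values[cbind(rc$row, rc$col)][inside]
  for (k in 1:5) {
    expect_equal(bc$proportion[bc$class_code == k], mean(vals == k))
  }
  half <- bc$proportion[bc$class_code %in% c(3, 4)]
  expect_true(all(abs(half - 0.5) <= 1 / sum(inside) + 1e-9))
  expect_equal(sum(bc$proportion), 1, tolerance = 1e-9)
})

test_that("uniform rasters give proportion one; tiny radii use the
           containing cell", {
  r <- uniform_raster(90)
  cons <- consolidate(r)
  pt <- tibble::tibble(id = 1, x = 155, y = 155)
  bc <- buffer_composition(pt, cons, radii = 100)
  expect_equal(bc$proportion[bc$class_code == 5], 1)
  bc2 <- buffer_composition(pt, cons, radii = 5)
  expect_equal(bc2$proportion[bc2$class_code == 5], 1)
  expect_equal(sum(bc2$proportion), 1)
})

test_that("nodata cells are excluded and reported via valid_fraction", {
  m <- matrix(3, 10, 10)
  m[1:5, ] <- NA
  r <- raster_grid(m, cell_size = 30)
  pt <- tibble::tibble(id = 1, x = 150, y = 150)
  bc <- buffer_composition(pt, r, radii = 100, classes = 3)
  expect_lt(bc$valid_fraction, 1)
  expect_equal(bc$proportion, 1)
})
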