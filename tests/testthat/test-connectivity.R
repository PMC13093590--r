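test_that("core nodes require both the area threshold and an occupant", {
  m <- matrix(41, 20, 20)
  m[2:4, 2:5] <- 90                    # 12 cells = 10,800 m^2 > 1 ha
  m[10, 10:15] <- 90; m[11, 10:14] <- 90  # 11 cells = 9,900 m^2 < 1 ha
  m[16:19, 14:19] <- 90    # 24 cells, large but unoccupied
  r <- raster_grid(m, cell_size = 30)
  in12 <- cell_center(r, 3, 3)
  in11 <- cell_center(r, 10, 12)
  occ <- tibble::tibble(x = c(in12[1], in11[1]), y = c(in12[2], in11[2]))
  nodes <- extract_core_nodes(r, occ, min_area = 10000)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$n_cells, 12L)
  expect_equal(nodes$area, 10800)
})

test_that("no wetland cells give an empty node set", {
  r <- uniform_raster(41)
  nodes <- extract_core_nodes(r, tibble::tibble(x = 10, y = 10))
  expect_equal(nrow(nodes), 0)
})

test_that("cost distance matches closed forms on tiny grids", {
  r13 <- raster_grid(matrix(1, 1, 3), cell_size = 30)
  cd <- cost_distance(r13, cbind(row = 1, col = 1))
  expect_equal(cd$values[1, 3], 60)
  expect_equal(cd$values[1, 1], 0)

  r22 <- raster_grid(matrix(1, 2, 2), cell_size = 30)
  cd2 <- cost_distance(r22, cbind(row = 1, col = 1))
  expect_equal(cd2$values[2, 2], 30 * sqrt(2))
})

test_that("cost distance routes around high-resistance walls like the
           relaxation oracle", {
  m <- matrix(1, 5, 5)
  m[1:4, 3] <- 1000
  r <- raster_grid(m, cell_size = 30)
  cd <- cost_distance(r, cbind(row = 1, col = 1))
  oracle <- oracle_cost_distance(m, 30, cbind(1, 1))
  expect_equal(cd$values, oracle, tolerance = 1e-9)
})

test_that("cost distance equals the independent oracle on random grids", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(sample(c(1, 2, 6, 30, 117, 466), 25, replace = TRUE), 5, 5)
    if (runif(1) < 0.3) m[sample(25, 2)] <- NA
    r <- raster_grid(m, cell_size = 30)
    src <- which(!is.na(m), arr.ind = TRUE)[1, , drop = FALSE]
    cd <- cost_distance(r, src)
    oracle <- oracle_cost_distance(m, 30, src)
    oracle[is.na(m)] <- NA
    expect_equal(cd$values, oracle, tolerance = 1e-9)
  }
})

test_that("nodata sources are an error", {
  m <- matrix(1, 3, 3); m[1, 1] <- NA
  r <- raster_grid(m)
  expect_error(cost_distance(r, cbind(row = 1, col = 1)), "nodata")
})

test_that("least-cost paths are straight on uniform resistance and
           consistent with the cost surface", {
  r <- raster_grid(matrix(2, 7, 9), cell_size = 30)
  a <- cbind(row = 4, col = 1)
  b <- cbind(row = 4, col = 9)
  lcp <- least_cost_path(r, a, b)
  expect_equal(lcp$cost, 8 * 2 * 30)  # straight 8-step chain
  expect_equal(nrow(lcp$path), 9)
  # consistency: path cost equals the accumulated cost at the target
  cd <- cost_distance(r, a)
  expect_equal(lcp$cost, cd$values[4, 9], tolerance = 1e-9)
  # symmetry
  expect_equal(least_cost_path(r, b, a)$cost, lcp$cost, tolerance = 1e-9)
})

test_that("adjacent node sets connect at no more than one edge cost", {
  r <- raster_grid(matrix(1, 4, 4), cell_size = 30)
  a <- cbind(row = c(1, 2), col = c(1, 1))
  b <- cbind(row = c(1, 2), col = c(2, 2))
  lcp <- least_cost_path(r, a, b)
  expect_lte(lcp$cost, 30 + 1e-9)
})

test_that("pair selection follows cost-weighted Voronoi adjacency", {
  # two nodes -> one pair
  r <- raster_grid(matrix(1, 5, 11), cell_size = 30)
  n2 <- tibble::tibble(node_id = 1:2,
                       cells = list(cbind(row = 3, col = 1),
                                    cbind(row = 3, col = 11)))
  expect_equal(nrow(select_pairs(n2, r)), 1)

  # three collinear nodes: adjacent pairs only, never the long pair
  r3 <- raster_grid(matrix(1, 5, 21), cell_size = 30)
  n3 <- tibble::tibble(node_id = 1:3,
                       cells = list(cbind(row = 3, col = 1),
                                    cbind(row = 3, col = 11),
                                    cbind(row = 3, col = 21)))
  pairs <- select_pairs(n3, r3)
  expect_equal(nrow(pairs), 2)
  expect_false(any(pairs$node_a == 1 & pairs$node_b == 3))

  # nodata barrier -> disconnected nodes yield no pair
  m <- matrix(1, 5, 11); m[, 6] <- NA
  rbar <- raster_grid(m, cell_size = 30)
  pairs_bar <- select_pairs(n2, rbar)
  expect_equal(nrow(pairs_bar), 0)
})

test_that("corridor rasters are nonnegative and vanish exactly on the
           least-cost path", {
  set.seed(17)
  m <- matrix(sample(c(1, 6, 30), 49, replace = TRUE), 7, 7)
  r <- raster_grid(m, cell_size = 30)
  a <- cbind(row = 4, col = 1); b <- cbind(row = 4, col = 7)
  corr <- corridor_raster(r, a, b)
  expect_true(all(corr$values >= 0, na.rm = TRUE))
  expect_equal(min(corr$values, na.rm = TRUE), 0, tolerance = 1e-9)
  lcp <- least_cost_path(r, a, b)
  expect_true(all(abs(corr$values[lcp$cells]) < 1e-9))

  # raising one off-path cell's resistance never lowers its corridor value
  off <- which(corr$values > 0, arr.ind = TRUE)[1, , drop = FALSE]
  m2 <- m; m2[off] <- m2[off] * 10
  corr2 <- corridor_raster(raster_grid(m2, cell_size = 30), a, b)
  expect_gte(corr2$values[off] + 1e-9, corr$values[off])
})

test_that("connect_nodes traces one path per adjacent pair", {
  r <- raster_grid(matrix(1, 5, 21), cell_size = 30)
  n3 <- tibble::tibble(node_id = 1:3,
                       cells = list(cbind(row = 3, col = 1),
                                    cbind(row = 3, col = 11),
                                    cbind(row = 3, col = 21)))
  lcps <- connect_nodes(n3, r)
  expect_equal(nrow(lcps), 2)
  expect_true(all(is.finite(lcps$cost)))
  expect_true(all(purrr::map_int(lcps$path, nrow) >= 2))
})
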