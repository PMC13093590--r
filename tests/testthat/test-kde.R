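test_that("kernel profiles conserve unit mass per event", {
  # single mid-route event, route much longer than the kernel support
  prof <- kde_profile(2500, 5000, h = 200)
  expect_equal(profile_mass(prof), 1, tolerance = 1e-6)
  # symmetric about the event
  left <- prof$density[prof$s == 2300]
  right <- prof$density[prof$s == 2700]
  expect_equal(left, right, tolerance = 1e-12)
  expect_equal(which.max(prof$density), which(prof$s == 2500))

  # an event at the route origin keeps unit mass via edge correction
  prof0 <- kde_profile(0, 5000, h = 200)
  expect_equal(profile_mass(prof0), 1, tolerance = 1e-6)

  # two coincident events double the profile exactly
  prof2 <- kde_profile(c(2500, 2500), 5000, h = 200)
  expect_equal(prof2$density, 2 * prof$density, tolerance = 1e-12)

  expect_error(kde_profile(1, 2, h = 200, step = 5), "shorter")
})

test_that("total profile mass equals the event count on random inputs", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(1:40, 1)
    len <- runif(1, 1000, 8000)
    ms <- runif(n, 0, len)
    h <- sample(c(100, 200), 1)
    # relative tolerance reflects quadrature error at the 5 m profile step
    expect_equal(profile_mass(kde_profile(ms, len, h = h)), n,
                 tolerance = 1e-3)
  }
})

test_that("the Monte-Carlo threshold is deterministic, flat in the
           interior, and zero without events", {
  thr0 <- significance_threshold(3000, 0, seed = 1)
  expect_true(all(thr0$threshold == 0))

  thr1 <- significance_threshold(5000, 20, n_sim = 199, seed = 5)
  thr2 <- significance_threshold(5000, 20, n_sim = 199, seed = 5)
  expect_identical(thr1$threshold, thr2$threshold)

  thr <- significance_threshold(5000, 20, n_sim = 999, seed = 3)
  interior <- thr$threshold[thr$s > 400 & thr$s < 4600]
  expect_lt(sd(interior) / mean(interior), 0.10)
})

test_that("cluster extraction finds planted clusters and nothing below
           threshold", {
  # all below threshold -> nothing
  prof <- kde_profile(2500, 5000, h = 200)
  none <- extract_clusters(prof, max(prof$density) + 1, 2500)
  expect_equal(nrow(none), 0)

  # a 10-point cluster within 50 m on a 5 km route -> exactly one hotspot
  # containing all measures
  set.seed(8)
  ms <- runif(10, 2475, 2525)
  prof <- kde_profile(ms, 5000, h = 200)
  thr <- significance_threshold(5000, 10, h = 200, n_sim = 199, seed = 8)
  hs <- extract_clusters(prof, thr, ms)
  expect_equal(nrow(hs), 1)
  expect_true(all(ms >= hs$start & ms <= hs$end))
  expect_equal(hs$n_events, 10)

  # two clusters 2 km apart -> two hotspots
  ms2 <- c(runif(10, 1475, 1525), runif(10, 3475, 3525))
  prof2 <- kde_profile(ms2, 5000, h = 200)
  thr2 <- significance_threshold(5000, 20, h = 200, n_sim = 199, seed = 9)
  hs2 <- extract_clusters(prof2, thr2, ms2)
  expect_equal(nrow(hs2), 2)
})

test_that("cluster strength ranks by excess mass with a unit top score", {
  hs <- tibble::tibble(excess_mass = c(0.4))
  expect_equal(cluster_strength(hs)$strength, 1)
  hs3 <- tibble::tibble(excess_mass = c(0.4, 0.2, 0))
  st <- cluster_strength(hs3)$strength
  expect_equal(st, c(1, 0.5, 0))

  # adding events to a cluster does not decrease its strength
  set.seed(10)
  base_ms <- c(runif(8, 990, 1010), runif(8, 3990, 4010))
  more_ms <- c(base_ms, runif(8, 990, 1010))
  thr <- significance_threshold(5000, length(base_ms), h = 200,
                                n_sim = 199, seed = 10)
  thr_more <- significance_threshold(5000, length(more_ms), h = 200,
                                     n_sim = 199, seed = 10)
  hs_base <- cluster_strength(extract_clusters(
    kde_profile(base_ms, 5000, h = 200), thr, base_ms))
  hs_more <- cluster_strength(extract_clusters(
    kde_profile(more_ms, 5000, h = 200), thr_more, more_ms))
  s_base <- hs_base$strength[which.min(abs(hs_base$centroid_measure - 1000))]
  s_more <- hs_more$strength[which.min(abs(hs_more$centroid_measure - 1000))]
  expect_gte(s_more, s_base)
})

test_that("network-level hotspot detection recovers planted clusters with
           centroids on the route", {
  roads <- straight_road(6000)
  net <- build_routes(roads)
  set.seed(12)
  ms <- c(runif(10, 1480, 1520), runif(30, 0, 6000))
  ev <- tibble::tibble(record_id = seq_along(ms), route_id = 1L,
                       measure = ms, offset = 0, x = ms, y = 0)
  hs <- find_hotspots(ev, net, h = 200, n_sim = 199, alpha = 0.005,
                      seed = 4)
  expect_gt(nrow(hs), 0)
  top <- hs[which.max(hs$strength), ]
  expect_lt(abs(top$centroid_measure - 1500), 200)
  expect_equal(top$centroid_y, 0, tolerance = 1e-9)
  expect_equal(max(hs$strength), 1)
})

test_that("hotspot sets at the two bandwidths overlap on planted data", {
  set.seed(20)
  ms <- c(runif(10, 1480, 1520), runif(10, 3980, 4020), runif(20, 0, 6000))
  ev <- tibble::tibble(record_id = seq_along(ms), route_id = 1L,
                       measure = ms, offset = 0, x = ms, y = 0)
  net <- build_routes(straight_road(6000))
  flagged <- function(h) {
    hs <- find_hotspots(ev, net, h = h, n_sim = 199, alpha = 0.05, seed = 6)
    covered <- rep(FALSE, 6001)
    for (i in seq_len(nrow(hs))) {
      covered[round(hs$start[i]):round(hs$end[i]) + 1] <- TRUE
    }
    covered
  }
  f100 <- flagged(100); f200 <- flagged(200)
  jaccard <- sum(f100 & f200) / sum(f100 | f200)
  expect_gt(jaccard, 0.3)
})
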