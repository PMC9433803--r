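fake_burst <- function(electrodes, first_spike, t0 = 0, t1 = 500) {
  fs <- first_spike
  names(fs) <- as.character(electrodes)
  structure(list(t_start = t0, t_end = t1, duration = t1 - t0,
                 electrodes = as.integer(electrodes), first_spike = fs,
                 peak_bin_count = length(electrodes)),
            class = "network_burst")
}

test_that("rank_order_map ranks by first spike with (row, col) tie-break", {
  g <- electrode_grid(4, 4)
  m <- rank_order_map(fake_burst(c(6, 1, 11), c(5, 0, 9)), g)
  expect_identical(m$electrode, c(1L, 6L, 11L))
  expect_identical(m$rank, 1:3)
  # tie: electrode 2 is (1,2), electrode 5 is (2,1): row wins
  m2 <- rank_order_map(fake_burst(c(5, 2), c(7, 7)), g)
  expect_identical(m2$electrode[1], 2L)
  expect_identical(m2$rank, 1:2)
})

test_that("noise-free radial bursts have rank increasing with distance", {
  g <- electrode_grid(10, 10)
  cfg <- sim_config(seed = 13, duration = 60000, background_rate = 0,
                    latency_jitter_sd = 0, burst_rate = 4,
                    burst_sites = matrix(c(5, 5), ncol = 2))
  sim <- simulate_spontaneous(cfg, g)
  b <- annotated_bursts(sim)[[1]]
  m <- rank_order_map(b, g)
  d <- electrode_distance(m$electrode,
                          rep(sim$bursts$site[1], nrow(m)), g)
  expect_true(all(diff(d) >= -1e-9))       # sorted by rank -> by distance
})

test_that("initiation_site averages the onset electrode centers", {
  g <- electrode_grid(5, 5)
  # symmetric cross around (3,3): centroid = center
  e <- electrode_id(c(3, 3, 2, 4), c(2, 4, 3, 3), g)
  m <- rank_order_map(fake_burst(e, c(1, 2, 3, 4)), g)
  site <- initiation_site(m, g)
  expect_equal(unname(site), c(2 * 81, 2 * 81))
  m1 <- rank_order_map(fake_burst(7, 1), g)
  expect_equal(unname(initiation_site(m1, g)),
               unname(electrode_position(7, g)[1, ]))
  # only the 10 earliest ranks enter the centroid
  g2 <- electrode_grid(5, 12)
  e11 <- c(electrode_id(rep(1, 10), 1:10, g2), electrode_id(5, 5, g2))
  m3 <- rank_order_map(fake_burst(e11, seq_along(e11)), g2)
  expect_equal(unname(initiation_site(m3, g2)["y"]), 0)
})

test_that("distance_latency_fit recovers exact propagation", {
  g <- electrode_grid(8, 8)
  v <- 25
  site_e <- electrode_id(4, 4, g)
  e <- seq_len(64)
  d <- electrode_distance(e, rep(site_e, 64), g)
  m <- rank_order_map(fake_burst(e, 100 + d / v), g)
  f <- distance_latency_fit(m, g, site = electrode_position(site_e, g)[1, ])
  expect_equal(f$slope, 1 / v, tolerance = 1e-12)
  expect_equal(f$speed, v, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  # latencies independent of distance -> r near 0
  set.seed(15)
  mr <- rank_order_map(fake_burst(e, runif(64, 0, 50)), g)
  fr <- distance_latency_fit(mr, g, site = electrode_position(site_e, g)[1, ])
  expect_lt(abs(fr$r), 0.35)
  # degenerate: all electrodes at same distance from the site
  ring <- electrode_id(c(3, 5, 4, 4), c(4, 4, 3, 5), g)
  md <- rank_order_map(fake_burst(ring, 1:4), g)
  fd <- distance_latency_fit(md, g, site = electrode_position(
    electrode_id(4, 4, g), g)[1, ])
  expect_true(fd$degenerate)
  expect_error(distance_latency_fit(rank_order_map(fake_burst(1, 1), g), g),
               "at least 3")
})

test_that("nearest_learning_distance and distance_distribution", {
  g <- electrode_grid(6, 6)
  learning <- electrode_id(c(2, 2), c(2, 3), g)
  on_site <- electrode_position(learning[1], g)[1, ]
  expect_equal(nearest_learning_distance(on_site, learning, g), 0)
  lateral <- electrode_position(electrode_id(2, 4, g), g)[1, ]
  expect_equal(nearest_learning_distance(lateral, learning, g), 81)
  expect_error(nearest_learning_distance(on_site, integer(), g), "empty")
  # constructed offsets: 0, 1, sqrt(2) and 2 pitches -> known fractions
  sites <- rbind(on_site,
                 lateral,
                 electrode_position(electrode_id(3, 4, g), g)[1, ],
                 electrode_position(electrode_id(2, 5, g), g)[1, ])
  fr <- distance_distribution(sites, learning, g)
  expect_equal(unname(fr), c(0.5, 0.75, 1))
  expect_true(all(diff(fr) >= 0))          # monotone in threshold
})

test_that("cluster_onsets single-linkage with radius", {
  one <- matrix(rep(c(100, 200), each = 5), ncol = 2)
  cl <- cluster_onsets(one)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$burst_count, 5L)
  expect_equal(cl$x, 100)
  two <- rbind(c(0, 0), c(500, 0))
  expect_identical(nrow(cluster_onsets(two, radius = 81)), 2L)
  # chain: a-b within radius, b-c within radius -> single cluster
  chain <- rbind(c(0, 0), c(70, 0), c(140, 0))
  expect_identical(nrow(cluster_onsets(chain, radius = 81)), 1L)
  # three planted centers with small scatter
  set.seed(16)
  centers <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  sites <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(runif(14, -20, 20), ncol = 2), 2, centers[k, ], "+")))
  cl3 <- cluster_onsets(sites, radius = 81)
  expect_identical(nrow(cl3), 3L)
  expect_identical(cl3$burst_count, rep(7L, 3))
  expect_error(cluster_onsets(matrix(numeric(0), ncol = 2)), "at least one")
})

test_that("propagation_table flattens the per-burst analysis", {
  g <- electrode_grid(10, 10)
  cfg <- sim_config(seed = 18, duration = 120000, background_rate = 0,
                    burst_rate = 5, burst_sites = matrix(c(5, 5), ncol = 2))
  sim <- simulate_spontaneous(cfg, g)
  learning <- learning_disc(g, c(5, 5), 120)
  pt <- propagation_table(annotated_bursts(sim), g, learning)
  expect_identical(nrow(pt), nrow(sim$bursts))
  expect_true(all(pt$nearest_learning_um < 200))
  expect_true(all(pt$cluster_id == 1L))    # single planted site
  expect_identical(nrow(propagation_table(list(), g, learning)), 0L)
})
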