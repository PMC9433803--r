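test_that("identical seed and config give byte-identical spike files", {
  g <- electrode_grid(8, 8)
  cfg <- sim_config(seed = 21, duration = 60000)
  p1 <- file.path(tempdir(), "det_a.csv")
  p2 <- file.path(tempdir(), "det_b.csv")
  write_spike_trains(simulate_spontaneous(cfg, g)$spikes, p1)
  write_spike_trains(simulate_spontaneous(cfg, g)$spikes, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("noise-free bursts place first spikes at distance / speed", {
  g <- electrode_grid(10, 10)
  cfg <- sim_config(seed = 2, duration = 60000, background_rate = 0,
                    latency_jitter_sd = 0, burst_rate = 3,
                    burst_sites = matrix(c(5, 5), ncol = 2))
  sim <- simulate_spontaneous(cfg, g)
  expect_gt(nrow(sim$bursts), 0)
  for (b in seq_len(nrow(sim$bursts))) {
    fs <- sim$first_spikes[[b]]
    e <- as.integer(names(fs))
    d <- electrode_distance(e, rep(sim$bursts$site[b], length(e)), g)
    expect_equal(unname(fs) - sim$bursts$t0[b], d / cfg$propagation_speed,
                 tolerance = 1e-12)
  }
})

test_that("burst_rate = 0 gives pure Poisson background", {
  g <- electrode_grid(8, 8)
  cfg <- sim_config(seed = 9, duration = 300000, burst_rate = 0,
                    background_rate = 0.5)
  sim <- simulate_spontaneous(cfg, g)
  expect_identical(nrow(sim$bursts), 0L)
  lambda <- 0.5 * 300    # rate * seconds
  n <- spike_counts(sim$spikes)
  expect_true(all(abs(n - lambda) <= 3 * sqrt(lambda)))
  # total count within a tight Poisson bound
  expect_lt(abs(sum(n) - 64 * lambda), 4 * sqrt(64 * lambda))
})

test_that("annotated burst count falls in the Poisson 99% interval", {
  g <- electrode_grid(8, 8)
  cfg <- sim_config(seed = 14, duration = 300000, burst_rate = 4,
                    min_burst_separation = 0)
  sim <- simulate_spontaneous(cfg, g)
  expect_gte(nrow(sim$bursts), qpois(0.005, 20))
  expect_lte(nrow(sim$bursts), qpois(0.995, 20))
})

test_that("deterministic learning phase: full response, flat RT", {
  g <- electrode_grid(6, 6)
  p <- stim_protocol(rest_after_trial = 2, rest_after_cycle = 5)
  cfg <- sim_config(seed = 3, learning_set = c(8L, 9L),
                    rs_start = 1, rs_end = 1, latency_jitter_sd = 0,
                    rt_start = 100, rt_end = 99.999,
                    background_rate = 0, nonlearning_response_prob = 0)
  lp <- simulate_learning_phase(cfg, p, g)
  expect_identical(lp$learning_mask, seq_len(36) %in% c(8L, 9L))
  ev <- evoked_spikes(lp$spikes, lp$log, response_window(), 8L)
  expect_true(all(lengths(ev) == 3))      # responds to all 320 stimuli
  # near-flat planted RT -> near-zero fitted slope
  tbl <- response_table(lp$spikes, lp$log,
                        active = active_electrodes(lp$spikes))
  f <- fit_trial_trend(tbl$rt_trial[8, ])
  expect_lt(abs(f$slope), 1e-3)
})

test_that("planted R/S and RT trends are recovered by the trend fits", {
  g <- electrode_grid(6, 6)
  p <- stim_protocol(rest_after_trial = 2, rest_after_cycle = 5)
  cfg <- sim_config(seed = 5, learning_set = 1:6, background_rate = 0,
                    nonlearning_response_prob = 0)
  lp <- simulate_learning_phase(cfg, p, g)
  tbl <- response_table(lp$spikes, lp$log,
                        active = active_electrodes(lp$spikes))
  rs_slopes <- sapply(1:6, function(e) fit_trial_trend(tbl$rs_trial[e, ])$slope)
  rt_slopes <- sapply(1:6, function(e) fit_trial_trend(tbl$rt_trial[e, ])$slope)
  expect_equal(mean(rs_slopes), 0.7 / 31, tolerance = 0.25)
  expect_equal(mean(rt_slopes), -110 / 31, tolerance = 0.25)
})

test_that("post-learning doubles the burst rate and marks new patterns", {
  g <- electrode_grid(8, 8)
  mk <- function(seed) {
    cfg <- sim_config(seed = seed, duration = 300000, burst_rate = 4,
                      burst_rate_post = 8, min_burst_separation = 0,
                      learning_set = 1:4)
    c(pre = nrow(simulate_spontaneous(cfg, g)$bursts),
      post = nrow(simulate_post_learning(cfg, g, hub_sites = 1:2)$bursts))
  }
  n <- rowSums(sapply(1:6, mk))           # pool seeds: ~120 pre, ~240 post
  expect_gt(n["post"] / n["pre"], 1.5)
  expect_lt(n["post"] / n["pre"], 2.5)
  cfg <- sim_config(seed = 4, duration = 300000, learning_set = 1:4)
  post <- simulate_post_learning(cfg, g, hub_sites = 1:2)
  expect_true(any(post$bursts$new_pattern))
  expect_true(all(post$bursts$site[post$bursts$new_pattern] %in% 1:2))
  expect_warning(simulate_post_learning(cfg, g, integer()), "falling back")
})

test_that("bicuculline mode lengthens bursts and recruits more electrodes", {
  g <- electrode_grid(8, 8)
  base <- list(seed = 6, duration = 300000, burst_rate = 4)
  off <- do.call(sim_config, base)
  on <- do.call(sim_config, c(base, bicuculline_mode = TRUE))
  soff <- simulate_spontaneous(off, g)
  son <- simulate_spontaneous(on, g)
  dur_off <- soff$bursts$t_end - soff$bursts$t0
  dur_on <- son$bursts$t_end - son$bursts$t0
  expect_gt(nrow(son$bursts), nrow(soff$bursts))
  expect_gt(mean(dur_on), mean(dur_off))
  expect_gt(mean(son$bursts$n_recruited), mean(soff$bursts$n_recruited))
})

test_that("generated sets always satisfy the spike-train invariants", {
  g <- electrode_grid(6, 6)
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, duration = 60000, burst_rate = 10,
                      min_burst_separation = 0)
    s <- simulate_spontaneous(cfg, g)$spikes
    expect_s3_class(s, "spike_train_set")   # constructor validates
    expect_true(all(unlist(s$spikes) >= 0))
    expect_true(all(unlist(s$spikes) < s$duration))
  }
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(background_rate = -1), ">= 0")
  expect_error(sim_config(propagation_speed = 0), "positive")
  expect_error(sim_config(rs_start = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(rt_start = 40, rt_end = 150), "rt_start")
  expect_error(simulate_learning_phase(sim_config(), stim_protocol(),
                                       electrode_grid(4, 4)),
               "non-empty")
})
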