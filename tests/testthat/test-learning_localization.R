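test_that("response_flag is a strict comparison to the network mean", {
  expect_true(response_flag(5, 2.0))
  expect_false(response_flag(2, 2.0))
  expect_identical(response_flag(c(0, 3), c(1, 1)), c(FALSE, TRUE))
})

test_that("response_time averages the first three latencies", {
  expect_equal(response_time(c(25, 40, 70, 90)), 45)
  expect_equal(response_time(120), 120)
  expect_true(is.na(response_time(numeric(0))))
})

test_that("fit_trial_trend recovers exact and degenerate trends", {
  f <- fit_trial_trend(1:32)
  expect_equal(f$slope, 1)
  expect_equal(f$r, 1)
  expect_equal(f$p_value, 0)
  f0 <- fit_trial_trend(rep(3, 32))
  expect_equal(f0$slope, 0)
  # undefined trials are skipped; too few defined -> undefined fit
  v <- c(2 * (1:10), rep(NA, 22))
  expect_equal(fit_trial_trend(v)$slope, 2)
  expect_true(is.na(fit_trial_trend(v, min_defined = 11)$slope))
  # noise-free planted slope recovered to machine precision
  v2 <- 0.1 + 0.7 / 31 * (0:31)
  expect_equal(fit_trial_trend(v2)$slope, 0.7 / 31, tolerance = 1e-12)
})

test_that("response_table computes counts, flags and RT per stimulus", {
  g <- electrode_grid(2, 2)
  p <- stim_protocol(n_cycles = 1, trials_per_cycle = 2,
                     stimuli_per_trial = 2, rest_after_trial = 1,
                     rest_after_cycle = 1)
  log <- build_schedule(p)
  # electrode 1 responds to stimulus 1 with 3 spikes; electrode 2 with 1
  s <- make_sts(list(`1` = c(20, 30, 40), `2` = 50,
                     `3` = 3500, `4` = 3600), 5000, g)
  tbl <- response_table(s, log, active = active_electrodes(s))
  expect_equal(tbl$counts[1, 1], 3L)
  expect_equal(tbl$counts[2, 1], 1L)
  expect_equal(tbl$network_mean[1], 1)     # (3+1+0+0)/4
  expect_true(tbl$flags[1, 1])             # 3 > 1
  expect_false(tbl$flags[2, 1])            # 1 == 1, strict
  expect_equal(tbl$rt[1, 1], 30)
  expect_equal(tbl$rs_trial[1, 1], 0.5)    # 1 response / 2 stimuli
  expect_true(all(tbl$rs_trial >= 0 & tbl$rs_trial <= 1))
  rtv <- tbl$rt[!is.na(tbl$rt)]
  expect_true(all(rtv > 10 & rtv <= 200))
})

test_that("localize intersects rising R/S with falling RT", {
  # hand-built table: 4 electrodes x 32 trials
  nt <- 32
  mk <- function(rs, rt) {
    tbl <- list(rs_trial = do.call(rbind, rs),
                rt_trial = do.call(rbind, rt), trials = seq_len(nt))
    class(tbl) <- "trial_response_table"
    tbl
  }
  up <- seq(0.2, 0.9, length.out = nt)
  down <- seq(150, 40, length.out = nt)
  flat <- rep(0.5, nt)
  tbl <- mk(list(up, up, flat, up),
            list(down, rev(down), down, c(down[1:6], rep(NA, nt - 6))))
  lmap <- localize(tbl, electrode_grid(2, 2))
  expect_identical(lmap$is_learning, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(lmap$rs_positive[2])          # rising R/S but rising RT
  expect_false(lmap$rt_negative[2])
  expect_true(lmap$rt_negative[3])          # falling RT but flat R/S
  expect_false(lmap$rs_positive[3])
  expect_lt(lmap$n_rt_trials[4], 8)         # too few defined RT trials
  expect_false(lmap$is_learning[4])
  # all-flat table -> empty mask
  tbl0 <- mk(rep(list(flat), 4), rep(list(rep(100, nt)), 4))
  expect_false(any(localize(tbl0, electrode_grid(2, 2))$is_learning))
})

test_that("localization is equivariant under electrode relabeling", {
  nt <- 32
  set.seed(77)
  rs <- matrix(runif(6 * nt), 6, nt)
  rt <- matrix(runif(6 * nt, 50, 150), 6, nt)
  mk <- function(rs, rt) {
    tbl <- list(rs_trial = rs, rt_trial = rt, trials = seq_len(nt))
    class(tbl) <- "trial_response_table"
    tbl
  }
  g <- electrode_grid(2, 3)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  a <- localize(mk(rs, rt), g)
  b <- localize(mk(rs[perm, ], rt[perm, ]), g)
  expect_identical(b$is_learning, a$is_learning[perm])
  expect_equal(b$rs_slope, a$rs_slope[perm])
})

test_that("isi_entropy matches closed forms", {
  # ISIs uniformly over 4 bins -> 2 bits
  spikes <- cumsum(c(0, 5, 15, 25, 35))    # ISIs 5, 15, 25, 35
  expect_equal(isi_entropy(spikes)$entropy, 2)
  # all ISIs in one bin -> 0 bits
  expect_equal(isi_entropy(c(0, 12, 24, 36))$entropy, 0)
  # bin mass {0.5, 0.25, 0.25} -> 1.5 bits
  spikes <- cumsum(c(0, 5, 5, 15, 25))
  expect_equal(isi_entropy(spikes)$entropy, 1.5)
  # overflow bin collects ISIs >= max_isi
  e <- isi_entropy(c(0, 2000, 4000))
  expect_equal(e$entropy, 0)
  expect_equal(e$counts[e$n_bins], 2)
  # fewer than 2 spikes -> undefined
  expect_false(isi_entropy(5)$defined)
  # probabilities sum to one; E <= log2(n bins)
  set.seed(3)
  t <- random_train(200, 60000)
  e2 <- isi_entropy(t)
  expect_equal(sum(e2$p), 1)
  expect_lte(e2$entropy, log2(e2$n_bins))
})

test_that("entropy_ratio aggregates learning over global entropy", {
  ent <- c(2, 1, 1, NA)
  expect_equal(entropy_ratio(c(TRUE, TRUE, TRUE, TRUE), ent), 1)
  expect_equal(entropy_ratio(rep(FALSE, 4), ent), 0)
  expect_equal(entropy_ratio(c(TRUE, FALSE, FALSE, FALSE), ent), 0.5)
  expect_equal(entropy_ratio(c(TRUE, FALSE, FALSE, FALSE), ent,
                             aggregate = "mean"), 2 / (4 / 3))
  expect_warning(r <- entropy_ratio(c(TRUE, FALSE), c(0, 0)), "zero")
  expect_true(is.na(r))
})
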