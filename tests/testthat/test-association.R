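make_metrics <- function(electrodes, betweenness,
                         degree = seq_along(electrodes)) {
  data.frame(electrode = electrodes, degree = degree,
             betweenness = betweenness)
}

test_that("metric_burst_regression recovers exact proportionality", {
  g <- electrode_grid(8, 10)
  nodes <- electrode_id(rep(2, 5), seq(1, 9, by = 2), g)  # 162 um apart
  metrics <- make_metrics(nodes, betweenness = c(0.1, 0.2, 0.3, 0.4, 0.5))
  pos <- electrode_position(nodes, g)
  clusters <- data.frame(x = pos[, "x"], y = pos[, "y"],
                         burst_count = 10 * metrics$betweenness)
  reg <- metric_burst_regression(clusters, metrics, "betweenness", g,
                                 link_radius = 80)
  expect_equal(reg$r, 1, tolerance = 1e-12)
  expect_equal(reg$slope, 10, tolerance = 1e-12)
  expect_identical(reg$n, 5L)
  # constant metric -> degenerate, flagged
  regc <- metric_burst_regression(clusters,
                                  make_metrics(nodes, rep(0.3, 5)),
                                  "betweenness", g, link_radius = 80)
  expect_true(regc$degenerate)
  expect_true(is.na(regc$r))
  # clusters with no linked electrode are excluded and counted
  far <- rbind(clusters, data.frame(x = 5000, y = 5000, burst_count = 1))
  regf <- metric_burst_regression(far, metrics, "betweenness", g,
                                  link_radius = 80)
  expect_identical(regf$n_excluded, 1L)
  expect_identical(regf$n, 5L)
  all_far <- data.frame(x = 5000, y = 5000, burst_count = 1)
  expect_error(metric_burst_regression(all_far, metrics, "betweenness", g,
                                       link_radius = 80), "no cluster")
})

test_that("regression is invariant to cluster ordering", {
  g <- electrode_grid(8, 10)
  nodes <- electrode_id(rep(2, 5), seq(1, 9, by = 2), g)
  metrics <- make_metrics(nodes, betweenness = c(0.5, 0.1, 0.4, 0.2, 0.3))
  pos <- electrode_position(nodes, g)
  clusters <- data.frame(x = pos[, "x"], y = pos[, "y"],
                         burst_count = c(9, 2, 7, 3, 5))
  a <- metric_burst_regression(clusters, metrics, "betweenness", g, 80)
  b <- metric_burst_regression(clusters[c(3, 1, 5, 2, 4), ], metrics,
                               "betweenness", g, 80)
  expect_equal(a$r, b$r)
  expect_equal(a$slope, b$slope)
})

test_that("top_percentile_overlap handles the planted cases", {
  g <- electrode_grid(8, 10)
  nodes <- electrode_id(rep(4, 6), 1:6, g)
  metrics <- make_metrics(nodes, betweenness = c(6, 5, 4, 3, 2, 1) / 10)
  # onset on the k highest-betweenness learning electrodes -> overlap 1
  expect_equal(top_percentile_overlap(nodes[1:3], metrics, "betweenness",
                                      g, percentile_keep = 0.5), 1)
  # onset disjoint and out of reach -> 0
  far <- electrode_id(8, 8, g)
  expect_equal(top_percentile_overlap(far, metrics, "betweenness", g,
                                      link_radius = 115), 0)
  # onset on the lowest-ranked electrode, keep top 50% -> 0
  expect_equal(top_percentile_overlap(nodes[6], metrics, "betweenness",
                                      g, percentile_keep = 0.5), 0)
  # non-learning onset maps to its nearest learning electrode within radius
  nb <- electrode_id(5, 1, g)              # 81 um from nodes[1] (top)
  expect_equal(top_percentile_overlap(nb, metrics, "betweenness", g,
                                      percentile_keep = 0.5,
                                      link_radius = 115), 1)
  # overlap is monotone non-decreasing in percentile_keep
  onset <- nodes[c(1, 4, 6)]
  ov <- sapply(c(0.2, 0.5, 0.8, 1), function(pk)
    top_percentile_overlap(onset, metrics, "betweenness", g,
                           percentile_keep = pk))
  expect_true(all(diff(ov) >= 0))
  expect_equal(ov[4], 1)
})

test_that("pre_post_compare reports Welch t and degenerate fallbacks", {
  x <- c(1, 2, 3, 4, 5)
  same <- pre_post_compare(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  cmp <- pre_post_compare(c(0, 0, 0), c(1, 1, 1))
  expect_true(cmp$degenerate)
  expect_equal(cmp$diff, 1)
  # against stats::t.test directly
  set.seed(90)
  a <- rnorm(12); b <- rnorm(15, 1)
  ref <- stats::t.test(b, a)
  out <- pre_post_compare(a, b, "x")
  expect_equal(out$p_value, ref$p.value)
  expect_equal(out$t, unname(ref$statistic))
  expect_error(pre_post_compare(1, c(1, 2)), "n >= 2")
})

test_that("planted burst-rate doubling is detected with high power", {
  # 20 paired recordings; post rate double the pre rate
  pvals <- sapply(1:10, function(seed) {
    set.seed(seed)
    pre <- rpois(20, 8)
    post <- rpois(20, 16)
    pre_post_compare(pre, post)$p_value
  })
  expect_gte(mean(pvals < 0.01), 0.9)
})
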