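#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()] and the command-line entry
#' point. The defaults describe a desk-scale run: a 16 x 16 grid (the
#' full-array geometry is obtained with `grid = list(n_rows = 64,
#' n_cols = 64)`), the standard 8 x 4 x 10 stimulation protocol, and
#' two-minute spontaneous recordings before and after learning. Unknown
#' keys anywhere in the override list are rejected.
#'
#' @param ... Named overrides, nested lists matching the default
#'   structure (e.g. `sim = list(burst_rate = 6)`).
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    grid = list(n_rows = 16L, n_cols = 16L, pitch = 81,
                electrode_size = 21),
    protocol = list(n_cycles = 8L, trials_per_cycle = 4L,
                    stimuli_per_trial = 10L, stimulus_frequency = 1,
                    rest_after_trial = 20, rest_after_cycle = 60),
    window = list(artifact_blank = 10, window_end = 200),
    sim = list(duration_pre = 120000, duration_post = 120000,
               background_rate = 0.5, burst_rate = 4, burst_rate_post = 8,
               propagation_speed = 20, latency_jitter_sd = 3,
               participation_fraction = 0.6, spikes_per_burst_mean = 4,
               learning_center = c(5L, 5L), learning_radius_um = 203,
               burst_site = c(12L, 12L), n_hubs = 3L,
               bicuculline_mode = FALSE),
    localize = list(min_defined_trials = 8L, significance_level = 0.05),
    burst = list(bin_width = 25, fraction_threshold = 0.25,
                 merge_gap = 100, min_duration = 25),
    connectivity = list(bin = 1, tau_max = 50, delta_tau = 5,
                        sd_multiplier = 3, normalization = "product",
                        max_nodes = 40L),
    metrics = list(n_nulls = 20L),
    propagation = list(n_onset = 10L, cluster_radius = 81),
    association = list(link_radius = 115, percentile_keep = 0.9)
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "config")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s) under %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste(path, k, sep = "$"))
    else defaults[[k]] <- overrides[[k]]
  }
  defaults
}

#' Learning-population disc
#'
#' Planted learning set: all electrodes within `radius_um` of the center
#' electrode's position. Used by the pipeline and convenient for
#' simulations.
#'
#' @param grid An `electrode_grid`.
#' @param center `(row, col)` of the disc center.
#' @param radius_um Disc radius, um.
#' @return Integer electrode ids.
#' @export
learning_disc <- function(grid, center, radius_um) {
  ce <- electrode_id(center[1], center[2], grid)
  pos <- electrode_position(seq_len(n_electrodes(grid)), grid)
  cp <- electrode_position(ce, grid)
  d <- sqrt((pos[, "x"] - cp[, "x"])^2 + (pos[, "y"] - cp[, "y"])^2)
  which(d <= radius_um)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> localize -> connect -> metrics -> detect-bursts
#' (pre/post) -> propagate -> associate under a single master seed and
#' writes a CSV/JSON report bundle to `out_dir`. Every output is
#' deterministic given `(seed, config)`; the effective configuration and
#' its MD5 hash are written next to the results.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   all file output.
#' @param config A [pipeline_config()] (or overrides list passed to it).
#' @return Report list (invisibly if `out_dir` is set).
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  cf <- config
  grid <- electrode_grid(cf$grid$n_rows, cf$grid$n_cols, cf$grid$pitch,
                         cf$grid$electrode_size)
  protocol <- do.call(stim_protocol, cf$protocol)
  w <- response_window(cf$window$artifact_blank, cf$window$window_end)
  bcfg <- do.call(burst_config, cf$burst)
  seeds <- stream_seeds(seed, 4L)
  learning_true <- learning_disc(grid, cf$sim$learning_center,
                                 cf$sim$learning_radius_um)
  base_sim <- function(s, ...) {
    sim_config(seed = s, background_rate = cf$sim$background_rate,
               burst_rate = cf$sim$burst_rate,
               burst_rate_post = cf$sim$burst_rate_post,
               propagation_speed = cf$sim$propagation_speed,
               latency_jitter_sd = cf$sim$latency_jitter_sd,
               participation_fraction = cf$sim$participation_fraction,
               spikes_per_burst_mean = cf$sim$spikes_per_burst_mean,
               burst_sites = matrix(cf$sim$burst_site, ncol = 2),
               learning_set = learning_true,
               bicuculline_mode = cf$sim$bicuculline_mode, ...)
  }

  message("[1/7] simulating learning phase")
  lp <- simulate_learning_phase(base_sim(seeds[1], duration = 60000),
                                protocol, grid)
  message("[2/7] localizing learning population")
  tbl <- response_table(lp$spikes, lp$log, w)
  lmap <- localize(tbl, grid,
                   min_defined_trials = cf$localize$min_defined_trials,
                   significance_level = cf$localize$significance_level)
  learning <- lmap$electrode[lmap$is_learning]
  if (length(learning) < 2L)
    stop("fewer than 2 learning electrodes localized; nothing to connect",
         call. = FALSE)
  ent <- entropy_map(lp$spikes)
  ent_ratio <- entropy_ratio(seq_len(n_electrodes(grid)) %in% learning, ent)

  message("[3/7] simulating spontaneous recordings (pre)")
  pre <- simulate_spontaneous(base_sim(seeds[2],
                                       duration = cf$sim$duration_pre),
                              grid, phase = "before")
  bursts_pre <- detect_bursts(pre$spikes, cfg = bcfg)

  message("[4/7] functional graph and metrics")
  nodes <- learning
  if (length(nodes) > cf$connectivity$max_nodes) {
    counts <- spike_counts(pre$spikes)[nodes]
    nodes <- nodes[order(-counts, nodes)][seq_len(cf$connectivity$max_nodes)]
    nodes <- sort(nodes)
  }
  g_pre <- build_functional_graph(
    pre$spikes, nodes, bin = cf$connectivity$bin,
    tau_max = cf$connectivity$tau_max,
    delta_tau = cf$connectivity$delta_tau,
    sd_multiplier = cf$connectivity$sd_multiplier,
    normalization = cf$connectivity$normalization)
  m_pre <- graph_metrics(g_pre, seed = seeds[3],
                         n_nulls = cf$metrics$n_nulls)
  hubs <- m_pre$nodes$electrode[
    order(-m_pre$nodes$betweenness,
          m_pre$nodes$electrode)][seq_len(min(cf$sim$n_hubs,
                                              nrow(m_pre$nodes)))]

  message("[5/7] simulating spontaneous recordings (post)")
  post <- simulate_post_learning(base_sim(seeds[4],
                                          duration = cf$sim$duration_post),
                                 grid, hub_sites = hubs, phase = "after")
  bursts_post <- detect_bursts(post$spikes, cfg = bcfg)
  g_post <- build_functional_graph(
    post$spikes, nodes, bin = cf$connectivity$bin,
    tau_max = cf$connectivity$tau_max,
    delta_tau = cf$connectivity$delta_tau,
    sd_multiplier = cf$connectivity$sd_multiplier,
    normalization = cf$connectivity$normalization)
  m_post <- graph_metrics(g_post, seed = seeds[3],
                          n_nulls = cf$metrics$n_nulls)

  message("[6/7] burst propagation")
  prop <- propagation_table(bursts_post, grid, learning,
                            n_onset = cf$propagation$n_onset,
                            cluster_radius = cf$propagation$cluster_radius)
  dist_frac <- if (nrow(prop))
    distance_distribution(cbind(prop$site_x_um, prop$site_y_um),
                          learning, grid) else NULL
  clusters <- if (nrow(prop))
    cluster_onsets(cbind(prop$site_x_um, prop$site_y_um),
                   cf$propagation$cluster_radius) else NULL

  message("[7/7] association analyses")
  onset_e <- unique(unlist(lapply(bursts_post, function(b) {
    m <- rank_order_map(b, grid)
    m$electrode[m$rank <= cf$propagation$n_onset]
  })))
  assoc <- list()
  if (!is.null(clusters) && nrow(clusters) >= 3) {
    for (mn in c("degree", "betweenness")) {
      reg <- tryCatch(
        metric_burst_regression(clusters, m_post, mn, grid,
                                cf$association$link_radius),
        error = function(e) list(error = conditionMessage(e)))
      reg$x <- reg$y <- NULL
      assoc[[paste0("regression_", mn)]] <- reg
    }
  }
  if (length(onset_e)) {
    for (mn in c("degree", "betweenness"))
      assoc[[paste0("overlap_", mn)]] <- top_percentile_overlap(
        onset_e, m_post, mn, grid, cf$association$percentile_keep,
        cf$association$link_radius)
  }

  per_minute <- function(bursts, duration) {
    edges <- seq(0, duration, by = 60000)
    t0s <- vapply(bursts, `[[`, 1, "t_start")
    tabulate(findInterval(t0s, edges), length(edges) - 1)
  }
  comparisons <- list(
    pre_post_compare(per_minute(bursts_pre, cf$sim$duration_pre),
                     per_minute(bursts_post, cf$sim$duration_post),
                     "bursts_per_min"),
    pre_post_compare(
      vapply(bursts_pre, function(b) length(b$electrodes), 1L),
      vapply(bursts_post, function(b) length(b$electrodes), 1L),
      "electrodes_per_burst"),
    pre_post_compare(vapply(bursts_pre, `[[`, 1, "duration"),
                     vapply(bursts_post, `[[`, 1, "duration"),
                     "burst_duration_ms")
  )
  comparison_df <- do.call(rbind, lapply(comparisons, function(x)
    as.data.frame(x[c("label", "n_pre", "n_post", "mean_pre", "mean_post",
                      "se_pre", "se_post", "diff", "t", "p_value",
                      "degenerate")])))

  report <- list(
    seed = seed,
    grid = cf$grid,
    learning = list(
      n_planted = length(learning_true), n_localized = length(learning),
      recall = mean(learning_true %in% learning),
      precision = if (length(learning))
        mean(learning %in% learning_true) else NA,
      entropy_ratio = ent_ratio),
    graph = list(
      n_nodes = length(nodes),
      threshold_pre = g_pre$threshold, threshold_post = g_post$threshold,
      network_pre = m_pre$network[c("n_links", "density", "efficiency",
                                    "modularity")],
      network_post = m_post$network[c("n_links", "density", "efficiency",
                                      "modularity")],
      hubs = hubs),
    bursts = list(
      rate_pre = burst_rate(bursts_pre, cf$sim$duration_pre),
      rate_post = burst_rate(bursts_post, cf$sim$duration_post),
      summary_pre = burst_summary(bursts_pre),
      summary_post = burst_summary(bursts_post)),
    propagation = list(
      n_bursts = nrow(prop),
      distance_distribution = as.list(dist_frac),
      median_speed = if (nrow(prop)) stats::median(1 / prop$slope,
                                                   na.rm = TRUE) else NA),
    association = assoc,
    comparisons = comparison_df
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_json_report(unclass(cf), p("config.json"))
    report$config_md5 <- unname(tools::md5sum(p("config.json")))
    utils::write.csv(lmap, p("learning_map.csv"), row.names = FALSE)
    utils::write.csv(edge_list(g_post), p("edges.csv"), row.names = FALSE)
    utils::write.csv(m_post$nodes, p("node_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(burst_table(bursts_pre), p("bursts_pre.csv"),
                     row.names = FALSE)
    utils::write.csv(burst_table(bursts_post), p("bursts_post.csv"),
                     row.names = FALSE)
    utils::write.csv(prop, p("propagation.csv"), row.names = FALSE)
    utils::write.csv(comparison_df, p("comparisons.csv"),
                     row.names = FALSE)
    write_json_report(report, p("report.json"))
    return(invisible(report))
  }
  report
}
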