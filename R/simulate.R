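#' Simulation configuration
#'
#' Parameters of the phenomenological spike-train generator. The generator
#' emulates the statistical structure the downstream analyses assume:
#' independent Poisson background firing, synchronized network bursts with
#' spatially localized initiation and radial propagation at a finite
#' speed, stimulus-evoked responses in a designated learning subset whose
#' response probability rises and latency falls linearly across trials,
#' and a disinhibited ("bicuculline-like") regime with more, longer and
#' wider bursts. It is not a biophysical model.
#'
#' @param seed Master RNG seed. Three named streams (background, burst
#'   skeleton, burst/response spikes) are derived from it so that enabling
#'   one component does not shift another's draws.
#' @param duration Recording length, ms (default 5 min).
#' @param background_rate Background Poisson rate per electrode, Hz.
#' @param burst_rate Network-burst rate, bursts/min (pre-learning default 4).
#' @param burst_rate_post Burst rate after learning, bursts/min (default 8).
#' @param burst_sites Initiation centers: integer electrode ids or a
#'   two-column (row, col) matrix. Default: single site near the grid
#'   center.
#' @param propagation_speed Radial recruitment speed, um/ms (default 20).
#' @param latency_jitter_sd Gaussian jitter on first-spike latencies and
#'   evoked latencies, ms (default 3).
#' @param participation_fraction Fraction of electrodes recruited per
#'   burst (distance quantile from the site; default 0.6).
#' @param spikes_per_burst_mean Mean spikes per burst per recruited
#'   electrode (Poisson; the first spike always occurs; default 4).
#' @param burst_spread Range (ms) of the within-burst spiking envelope
#'   after an electrode's first spike (default 100-300 ms).
#' @param min_burst_separation Minimum onset-to-onset spacing, ms; closer
#'   Poisson onsets are thinned, mimicking post-burst network
#'   refractoriness (default 1000).
#' @param learning_set Integer electrode ids of the planted learning
#'   population.
#' @param rs_start,rs_end Per-stimulus response probability of learning
#'   electrodes on the first and last trial (linear interpolation across
#'   trials; defaults 0.2 -> 0.9).
#' @param rt_start,rt_end Mean evoked latency (ms) on the first and last
#'   trial (defaults 150 -> 40; must satisfy `rt_start > rt_end >= 10`).
#' @param nonlearning_response_prob Constant response probability of
#'   non-learning electrodes (default 0.15).
#' @param nonlearning_rt Constant mean evoked latency of non-learning
#'   electrodes, ms (default 100).
#' @param bicuculline_mode When TRUE, scales burst rate x2, within-burst
#'   envelope x1.5, participation x1.3 (capped at 1).
#' @param n_neurons Neurons on the active area (metadata; default 90,000,
#'   i.e. ~22 neurons per electrode on the default grid).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration = 300000, background_rate = 0.5,
                       burst_rate = 4, burst_rate_post = 8,
                       burst_sites = NULL, propagation_speed = 20,
                       latency_jitter_sd = 3, participation_fraction = 0.6,
                       spikes_per_burst_mean = 4,
                       burst_spread = c(100, 300),
                       min_burst_separation = 1000,
                       learning_set = integer(),
                       rs_start = 0.2, rs_end = 0.9,
                       rt_start = 150, rt_end = 40,
                       nonlearning_response_prob = 0.15,
                       nonlearning_rt = 100,
                       bicuculline_mode = FALSE,
                       n_neurons = 90000) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (burst_rate < 0 || burst_rate_post < 0)
    stop("burst rates must be >= 0", call. = FALSE)
  if (propagation_speed <= 0)
    stop("propagation_speed must be positive", call. = FALSE)
  if (latency_jitter_sd < 0)
    stop("latency_jitter_sd must be >= 0", call. = FALSE)
  probs <- c(rs_start, rs_end, nonlearning_response_prob,
             participation_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities/fractions must lie in [0, 1]", call. = FALSE)
  if (!(rt_start > rt_end && rt_end >= 10))
    stop("need rt_start > rt_end >= 10 ms", call. = FALSE)
  structure(
    list(seed = as.integer(seed), duration = duration,
         background_rate = background_rate, burst_rate = burst_rate,
         burst_rate_post = burst_rate_post, burst_sites = burst_sites,
         propagation_speed = propagation_speed,
         latency_jitter_sd = latency_jitter_sd,
         participation_fraction = participation_fraction,
         spikes_per_burst_mean = spikes_per_burst_mean,
         burst_spread = burst_spread,
         min_burst_separation = min_burst_separation,
         learning_set = as.integer(learning_set),
         rs_start = rs_start, rs_end = rs_end,
         rt_start = rt_start, rt_end = rt_end,
         nonlearning_response_prob = nonlearning_response_prob,
         nonlearning_rt = nonlearning_rt,
         bicuculline_mode = isTRUE(bicuculline_mode),
         n_neurons = n_neurons),
    class = "sim_config"
  )
}

# Derive independent per-stream seeds from the master seed.
stream_seeds <- function(seed, n = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

normalize_sites <- function(sites, grid) {
  if (is.null(sites))
    return(electrode_id(ceiling(grid$n_rows / 2), ceiling(grid$n_cols / 2),
                        grid))
  if (is.matrix(sites) || is.data.frame(sites)) {
    sites <- as.matrix(sites)
    return(electrode_id(sites[, 1], sites[, 2], grid))
  }
  check_electrode_index(as.integer(sites), grid)
}

# Poisson background trains for all electrodes; returns list of sorted times.
background_trains <- function(rate_hz, duration, ne) {
  if (rate_hz == 0) return(rep(list(numeric(0)), ne))
  counts <- stats::rpois(ne, rate_hz * duration / 1000)
  lapply(counts, function(k) sort(stats::runif(k, 0, duration)))
}

# Combine spike sources per electrode into strictly increasing trains.
merge_trains <- function(trains_list, duration) {
  ne <- length(trains_list[[1]])
  lapply(seq_len(ne), function(e) {
    t <- sort(unlist(lapply(trains_list, `[[`, e), use.names = FALSE))
    t <- t[t >= 0 & t < duration]
    unique(t)
  })
}

# Core burst engine shared by the spontaneous and post-learning regimes.
generate_bursts <- function(cfg, grid, sites, rate_per_min, seeds,
                            new_pattern_sites = integer()) {
  ne <- n_electrodes(grid)
  rate <- rate_per_min
  spread <- cfg$burst_spread
  part <- cfg$participation_fraction
  if (cfg$bicuculline_mode) {
    rate <- rate * 2
    spread <- spread * 1.5
    part <- min(1, part * 1.3)
  }
  margin <- max(spread) + 200
  # -- skeleton stream: onset count, times, site assignment
  set.seed(seeds[1])
  n_raw <- stats::rpois(1, rate * cfg$duration / 60000)
  t0 <- sort(stats::runif(n_raw, 0, max(cfg$duration - margin, 1)))
  if (length(t0) > 1) {        # thin onsets closer than the refractory gap
    keep <- rep(TRUE, length(t0))
    last <- t0[1]
    for (i in seq_along(t0)[-1]) {
      if (t0[i] - last < cfg$min_burst_separation) keep[i] <- FALSE
      else last <- t0[i]
    }
    t0 <- t0[keep]
  }
  nb <- length(t0)
  site <- if (nb) sites[sample.int(length(sites), nb, replace = TRUE)]
          else integer(0)
  # -- spike stream: recruitment latencies and within-burst spikes
  set.seed(seeds[2])
  all_pos <- electrode_position(seq_len(ne), grid)
  burst_trains <- rep(list(numeric(0)), ne)
  recruited <- vector("list", nb)
  first_spikes <- vector("list", nb)
  t_end <- numeric(nb)
  for (b in seq_len(nb)) {
    sp <- all_pos[site[b], , drop = FALSE]
    d <- sqrt((all_pos[, "x"] - sp[, "x"])^2 + (all_pos[, "y"] - sp[, "y"])^2)
    rec <- which(d <= stats::quantile(d, part))
    lat <- d[rec] / cfg$propagation_speed
    if (cfg$latency_jitter_sd > 0)
      lat <- pmax(0, lat + stats::rnorm(length(rec), 0,
                                        cfg$latency_jitter_sd))
    first <- t0[b] + lat
    env <- stats::runif(1, spread[1], spread[2])
    n_extra <- stats::rpois(length(rec),
                            max(0, cfg$spikes_per_burst_mean - 1))
    extras <- stats::runif(sum(n_extra), 0, env)
    idx <- rep.int(seq_along(rec), n_extra)
    for (j in seq_along(rec)) {
      e <- rec[j]
      ts <- c(first[j], first[j] + extras[idx == j])
      burst_trains[[e]] <- c(burst_trains[[e]], ts)
    }
    recruited[[b]] <- rec
    fs <- first
    names(fs) <- as.character(rec)
    first_spikes[[b]] <- fs
    t_end[b] <- max(first) + env
  }
  bursts <- data.frame(
    burst_id = seq_len(nb), t0 = t0, site = site,
    site_row = if (nb) electrode_rc(site, grid)[, "row"] else integer(0),
    site_col = if (nb) electrode_rc(site, grid)[, "col"] else integer(0),
    n_recruited = vapply(recruited, length, 1L),
    t_end = t_end,
    new_pattern = site %in% new_pattern_sites
  )
  list(trains = burst_trains, bursts = bursts, recruited = recruited,
       first_spikes = first_spikes)
}

#' Simulate spontaneous activity with network bursts
#'
#' Superposes independent per-electrode Poisson background firing and
#' synchronized network bursts. Burst onsets follow a thinned Poisson
#' process at `burst_rate`; each burst picks a site from
#' `cfg$burst_sites`, recruits the electrodes within the
#' `participation_fraction` distance quantile of the site, gives each
#' recruited electrode a first spike at
#' `distance / propagation_speed + N(0, latency_jitter_sd)` after onset,
#' and adds further within-burst spikes over a 100-300 ms envelope.
#' Ground-truth annotations (onsets, sites, recruited electrodes) are
#' returned alongside and never inferred.
#'
#' @param cfg A [sim_config()].
#' @param grid An [electrode_grid()].
#' @param phase Phase label stored in the metadata.
#' @return Object of class `mea_simulation`: list with `spikes`
#'   (a `spike_train_set`), `bursts` (annotation data frame with columns
#'   `burst_id,t0,site,site_row,site_col,n_recruited,t_end,new_pattern`),
#'   `recruited` (list of electrode-id vectors), `first_spikes` (list of
#'   named latency vectors) and `config`.
#' @export
simulate_spontaneous <- function(cfg, grid = electrode_grid(),
                                 phase = "before") {
  stopifnot(inherits(cfg, "sim_config"), inherits(grid, "electrode_grid"))
  sites <- normalize_sites(cfg$burst_sites, grid)
  seeds <- stream_seeds(cfg$seed, 3L)
  ne <- n_electrodes(grid)
  set.seed(seeds[1])
  bg <- background_trains(cfg$background_rate, cfg$duration, ne)
  gb <- generate_bursts(cfg, grid, sites, cfg$burst_rate, seeds[2:3])
  spikes <- merge_trains(list(bg, gb$trains), cfg$duration)
  s <- spike_train_set(spikes, cfg$duration, grid,
                       metadata = list(phase = phase, seed = cfg$seed))
  structure(list(spikes = s, bursts = gb$bursts, recruited = gb$recruited,
                 first_spikes = gb$first_spikes, config = cfg),
            class = "mea_simulation")
}

#' Simulate spontaneous activity after learning
#'
#' Like [simulate_spontaneous()], but the burst-site pool is augmented
#' with `hub_sites` (typically high-betweenness learning electrodes) and
#' the burst rate is `cfg$burst_rate_post`. Bursts initiated at a hub
#' site are annotated `new_pattern = TRUE`.
#'
#' @inheritParams simulate_spontaneous
#' @param hub_sites Integer electrode ids (normally a subset of
#'   `cfg$learning_set`). Empty: falls back to the pre-learning sites
#'   with a warning.
#' @return An `mea_simulation` (see [simulate_spontaneous()]).
#' @export
simulate_post_learning <- function(cfg, grid = electrode_grid(),
                                   hub_sites = integer(), phase = "after") {
  stopifnot(inherits(cfg, "sim_config"))
  hub_sites <- as.integer(hub_sites)
  if (length(hub_sites) == 0L) {
    warning("empty hub_sites; falling back to pre-learning burst sites",
            call. = FALSE)
    sites <- normalize_sites(cfg$burst_sites, grid)
  } else {
    check_electrode_index(hub_sites, grid)
    sites <- unique(c(normalize_sites(cfg$burst_sites, grid), hub_sites))
  }
  seeds <- stream_seeds(cfg$seed, 3L)
  ne <- n_electrodes(grid)
  set.seed(seeds[1])
  bg <- background_trains(cfg$background_rate, cfg$duration, ne)
  gb <- generate_bursts(cfg, grid, sites, cfg$burst_rate_post, seeds[2:3],
                        new_pattern_sites = hub_sites)
  spikes <- merge_trains(list(bg, gb$trains), cfg$duration)
  s <- spike_train_set(spikes, cfg$duration, grid,
                       metadata = list(phase = phase, seed = cfg$seed))
  structure(list(spikes = s, bursts = gb$bursts, recruited = gb$recruited,
                 first_spikes = gb$first_spikes, config = cfg),
            class = "mea_simulation")
}

#' Simulate the learning phase (evoked responses to a stimulation schedule)
#'
#' For every stimulus in the schedule, each planted learning electrode
#' responds with a probability interpolated linearly from `rs_start`
#' (first trial) to `rs_end` (last trial); a response is a three-spike
#' volley whose leading latency is drawn around the trial-interpolated
#' mean latency (`rt_start` -> `rt_end`), truncated into the 10-200 ms
#' analysis window. Non-learning electrodes respond with constant
#' probability `nonlearning_response_prob` at constant mean latency.
#' Poisson background activity is superimposed.
#'
#' @param cfg A [sim_config()] with non-empty `learning_set`.
#' @param protocol A [stim_protocol()].
#' @param grid An [electrode_grid()].
#' @return List with `spikes` (a `spike_train_set` spanning the
#'   schedule), `log` (the `stimulus_log`), `learning_mask` (logical,
#'   ground truth) and `config`.
#' @export
simulate_learning_phase <- function(cfg, protocol = stim_protocol(),
                                    grid = electrode_grid()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(protocol, "stim_protocol"))
  if (length(cfg$learning_set) == 0L)
    stop("cfg$learning_set must be non-empty for the learning phase",
         call. = FALSE)
  learning <- check_electrode_index(cfg$learning_set, grid)
  ne <- n_electrodes(grid)
  log <- build_schedule(protocol)
  duration <- schedule_duration(protocol)
  n_trials <- protocol$n_cycles * protocol$trials_per_cycle
  frac <- if (n_trials > 1) (log$trial_global - 1) / (n_trials - 1) else 0
  p_stim <- cfg$rs_start + (cfg$rs_end - cfg$rs_start) * frac
  rt_stim <- cfg$rt_start + (cfg$rt_end - cfg$rt_start) * frac

  seeds <- stream_seeds(cfg$seed, 3L)
  set.seed(seeds[1])
  bg <- background_trains(cfg$background_rate, duration, ne)

  set.seed(seeds[3])
  ns <- nrow(log)
  resp <- rep(list(numeric(0)), ne)
  volley <- function(n_resp, stim_times, rt_mean, jitter) {
    lat <- stats::rnorm(n_resp, rt_mean, jitter)
    lat <- pmin(pmax(lat, 10.5), 193)   # keep the 3-spike volley in-window
    as.numeric(rbind(stim_times + lat, stim_times + lat + 3,
                     stim_times + lat + 6))
  }
  is_learning <- seq_len(ne) %in% learning
  for (e in seq_len(ne)) {
    if (is_learning[e]) {
      hit <- stats::runif(ns) < p_stim
      if (!any(hit)) next
      resp[[e]] <- volley(sum(hit), log$time_ms[hit], rt_stim[hit],
                          cfg$latency_jitter_sd)
    } else {
      hit <- stats::runif(ns) < cfg$nonlearning_response_prob
      if (!any(hit)) next
      resp[[e]] <- volley(sum(hit), log$time_ms[hit], cfg$nonlearning_rt,
                          cfg$latency_jitter_sd)
    }
  }
  spikes <- merge_trains(list(bg, resp), duration)
  s <- spike_train_set(spikes, duration, grid,
                       metadata = list(phase = "learning", seed = cfg$seed))
  list(spikes = s, log = log, learning_mask = is_learning, config = cfg)
}

#' Simulate onset clusters coupled to a node metric
#'
#' Builds burst-onset clusters whose burst counts are (optionally)
#' coupled to a per-node graph metric: cluster k sits on the position of
#' node k and its count is `base + gain * rank(metric) + N(0, noise_sd)`
#' (rounded, floored at 0). With `coupling = "none"` the counts are pure
#' noise around `base`. Used to validate the sign recovery of
#' [metric_burst_regression()].
#'
#' @param metric Named or plain numeric vector of node metric values; the
#'   names (or positions) index `electrodes`.
#' @param electrodes Integer electrode ids of the nodes.
#' @param grid An [electrode_grid()].
#' @param coupling `"positive"` or `"none"`.
#' @param base Baseline burst count (default 5).
#' @param gain Count increment per metric rank (default 2).
#' @param noise_sd Gaussian noise SD on counts (default 3).
#' @param seed RNG seed.
#' @return Data frame with columns `x`, `y` (cluster centroid, um) and
#'   `burst_count`.
#' @export
simulate_onset_coupling <- function(metric, electrodes,
                                    grid = electrode_grid(),
                                    coupling = c("positive", "none"),
                                    base = 5, gain = 2, noise_sd = 3,
                                    seed = 1L) {
  coupling <- match.arg(coupling)
  electrodes <- check_electrode_index(electrodes, grid)
  stopifnot(length(metric) == length(electrodes))
  set.seed(seed)
  mu <- if (coupling == "positive") base + gain * rank(metric,
                                                       ties.method = "average")
        else rep(base + gain * (length(metric) + 1) / 2, length(metric))
  counts <- pmax(0, round(mu + stats::rnorm(length(metric), 0, noise_sd)))
  pos <- electrode_position(electrodes, grid)
  data.frame(x = pos[, "x"], y = pos[, "y"], burst_count = counts)
}

#' Ground-truth bursts as `network_burst` objects
#'
#' Converts a simulation's burst annotations into the same structure
#' that [detect_bursts()] produces, so the propagation and association
#' stages can be run on noise-free ground truth (each electrode's first
#' spike is its annotated recruitment time, uncontaminated by background
#' spikes or bin snapping).
#'
#' @param sim An `mea_simulation`.
#' @return List of `network_burst` objects.
#' @export
annotated_bursts <- function(sim) {
  stopifnot(inherits(sim, "mea_simulation"))
  lapply(seq_len(nrow(sim$bursts)), function(b) {
    fs <- sim$first_spikes[[b]]
    structure(
      list(t_start = sim$bursts$t0[b], t_end = sim$bursts$t_end[b],
           duration = sim$bursts$t_end[b] - sim$bursts$t0[b],
           electrodes = sim$recruited[[b]], first_spike = fs,
           peak_bin_count = NA_integer_),
      class = "network_burst"
    )
  })
}

#' Write simulation ground truth as JSON
#'
#' @param sim An `mea_simulation`.
#' @param path Output JSON path.
#' @param learning_mask Optional logical ground-truth learning mask.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path, learning_mask = NULL) {
  stopifnot(inherits(sim, "mea_simulation"))
  gt <- list(
    bursts = lapply(seq_len(nrow(sim$bursts)), function(b) {
      list(t0 = sim$bursts$t0[b], site = sim$bursts$site[b],
           new_pattern = sim$bursts$new_pattern[b],
           electrodes = sim$recruited[[b]])
    }),
    seed = sim$config$seed
  )
  if (!is.null(learning_mask)) gt$learning_mask <- learning_mask
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
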