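#' Network-burst detection configuration
#'
#' A network burst is a run of time bins in which strictly more than
#' `fraction_threshold` of the active electrodes fire at least one spike
#' ("synchronously in the same bin"). On a fully active default grid the
#' 25% threshold is 1,024 electrodes and a bin must exceed it strictly.
#' The bin width is not dictated by the burst definition itself; 25 ms
#' resolves onset order while keeping counts stable for bursts lasting a
#' few hundred milliseconds.
#'
#' @param bin_width Bin width, ms (default 25).
#' @param fraction_threshold Fraction of active electrodes that must be
#'   exceeded (strictly) for a supra-threshold bin (default 0.25).
#' @param merge_gap Runs of supra-threshold bins separated by at most
#'   this many ms are merged (default 100).
#' @param min_duration Bursts shorter than this are discarded, ms
#'   (default 25).
#' @return Object of class `burst_config`.
#' @export
burst_config <- function(bin_width = 25, fraction_threshold = 0.25,
                         merge_gap = 100, min_duration = 25) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (!(fraction_threshold > 0 && fraction_threshold < 1))
    stop("fraction_threshold must be in (0, 1)", call. = FALSE)
  structure(list(bin_width = bin_width,
                 fraction_threshold = fraction_threshold,
                 merge_gap = merge_gap, min_duration = min_duration),
            class = "burst_config")
}

#' Detect network bursts
#'
#' Bins the recording at `cfg$bin_width` ms, counts the distinct active
#' electrodes spiking in each bin, marks bins where the count strictly
#' exceeds `fraction_threshold * |active|`, merges supra-threshold runs
#' separated by at most `merge_gap` ms, and drops bursts shorter than
#' `min_duration`. Burst windows snap to bin edges; each participant's
#' first spike inside the window is recorded as a raw timestamp. Spikes
#' on non-active electrodes never influence detection.
#'
#' @param s A `spike_train_set`.
#' @param active An [active_electrodes()] result (default: all electrodes
#'   with at least one spike).
#' @param cfg A [burst_config()].
#' @return List of `network_burst` objects, each a list with `t_start`,
#'   `t_end`, `duration`, `electrodes` (participants), `first_spike`
#'   (named vector, ms) and `peak_bin_count`.
#' @export
detect_bursts <- function(s, active = NULL, cfg = burst_config()) {
  stopifnot(inherits(s, "spike_train_set"), inherits(cfg, "burst_config"))
  if (cfg$bin_width >= s$duration)
    stop("bin_width must be smaller than the recording duration",
         call. = FALSE)
  if (is.null(active)) active <- active_electrodes(s)
  idx <- active$indices
  if (length(idx) < 1L) return(list())
  threshold <- cfg$fraction_threshold * length(idx)

  ns <- lengths(s$spikes[idx])
  elec <- rep.int(idx, ns)
  t <- unlist(s$spikes[idx], use.names = FALSE)
  if (length(t) == 0L) return(list())
  bin <- floor(t / cfg$bin_width)
  # distinct electrodes per bin
  u <- !duplicated(cbind(bin, elec))
  cnt <- table(bin[u])
  supra <- as.numeric(names(cnt))[as.numeric(cnt) > threshold]
  if (length(supra) == 0L) return(list())
  supra <- sort(supra)
  peak_of <- function(b0, b1) {
    sel <- as.numeric(names(cnt)) >= b0 & as.numeric(names(cnt)) <= b1
    max(as.numeric(cnt)[sel])
  }
  # group supra bins into runs, merging gaps <= merge_gap ms
  max_gap_bins <- floor(cfg$merge_gap / cfg$bin_width)
  run_id <- cumsum(c(1, diff(supra) > max_gap_bins + 1))
  bursts <- list()
  for (r in unique(run_id)) {
    b <- supra[run_id == r]
    t_start <- min(b) * cfg$bin_width
    t_end <- (max(b) + 1) * cfg$bin_width
    if (t_end - t_start < cfg$min_duration) next
    inside <- t >= t_start & t < t_end
    if (!any(inside)) next
    fe <- elec[inside]
    ft <- t[inside]
    first <- tapply(ft, fe, min)
    participants <- as.integer(names(first))
    fs <- as.numeric(first)
    names(fs) <- names(first)
    bursts[[length(bursts) + 1L]] <- structure(
      list(t_start = t_start, t_end = t_end, duration = t_end - t_start,
           electrodes = participants, first_spike = fs,
           peak_bin_count = peak_of(min(b), max(b))),
      class = "network_burst"
    )
  }
  bursts
}

#' @export
print.network_burst <- function(x, ...) {
  cat(sprintf("<network_burst> [%g, %g) ms, %d electrodes, peak %d\n",
              x$t_start, x$t_end, length(x$electrodes), x$peak_bin_count))
  invisible(x)
}

#' Burst-rate and burst-shape summaries
#'
#' @param bursts List of `network_burst` objects.
#' @param duration Recording duration, ms.
#' @return `burst_rate()`: bursts per minute. `burst_summary()`: list
#'   with `n`, `mean_electrodes`, `mean_duration` (the means are `NA`
#'   with a `degenerate` flag when the list is empty).
#' @export
burst_rate <- function(bursts, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  length(bursts) / duration * 60000
}

#' @rdname burst_rate
#' @export
burst_summary <- function(bursts) {
  if (length(bursts) == 0L)
    return(list(n = 0L, mean_electrodes = NA_real_,
                mean_duration = NA_real_, degenerate = TRUE))
  list(n = length(bursts),
       mean_electrodes = mean(vapply(bursts,
                                     function(b) length(b$electrodes), 1L)),
       mean_duration = mean(vapply(bursts, `[[`, 1, "duration")),
       degenerate = FALSE)
}

#' Burst table
#'
#' Flattens a burst list into the on-disk table format
#' `burst_id,t_start_ms,t_end_ms,duration_ms,n_electrodes,peak_count`.
#' @param bursts List of `network_burst` objects.
#' @return Data frame (zero rows for an empty list).
#' @export
burst_table <- function(bursts) {
  data.frame(
    burst_id = seq_along(bursts),
    t_start_ms = vapply(bursts, `[[`, 1, "t_start"),
    t_end_ms = vapply(bursts, `[[`, 1, "t_end"),
    duration_ms = vapply(bursts, `[[`, 1, "duration"),
    n_electrodes = vapply(bursts, function(b) length(b$electrodes), 1L),
    peak_count = vapply(bursts, function(b) as.integer(b$peak_bin_count), 1L)
  )
}
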