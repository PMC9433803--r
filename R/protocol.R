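#' Stimulation protocol for the learning phase
#'
#' The learning paradigm delivers biphasic current pulses through one
#' electrode pair, organized as cycles of trials: by default 8 cycles x
#' 4 trials x 10 stimuli at 1 Hz (320 stimuli, 32 trials), with 20 s of
#' rest after each trial and 60 s after each cycle. The pulse description
#' (negative-first biphasic, 200 us per phase, +/-15 uA) is carried as
#' metadata only.
#'
#' @param n_cycles,trials_per_cycle,stimuli_per_trial Protocol counts
#'   (all >= 1).
#' @param stimulus_frequency Within-trial stimulation rate, Hz.
#' @param rest_after_trial,rest_after_cycle Rest durations, seconds.
#' @param stim_electrode_pair Labels of the two stimulation sites.
#' @param pulse Pulse metadata list.
#' @return Object of class `stim_protocol`.
#' @export
stim_protocol <- function(n_cycles = 8L, trials_per_cycle = 4L,
                          stimuli_per_trial = 10L, stimulus_frequency = 1,
                          rest_after_trial = 20, rest_after_cycle = 60,
                          stim_electrode_pair = c("(2,2)", "(3,3)"),
                          pulse = list(shape = "biphasic negative-first",
                                       phase_duration_us = 200,
                                       amplitude_ua = 15)) {
  counts <- c(n_cycles, trials_per_cycle, stimuli_per_trial)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("protocol counts must all be >= 1", call. = FALSE)
  if (stimulus_frequency <= 0)
    stop("stimulus_frequency must be positive", call. = FALSE)
  structure(
    list(n_cycles = as.integer(n_cycles),
         trials_per_cycle = as.integer(trials_per_cycle),
         stimuli_per_trial = as.integer(stimuli_per_trial),
         stimulus_frequency = stimulus_frequency,
         rest_after_trial = rest_after_trial,
         rest_after_cycle = rest_after_cycle,
         stim_electrode_pair = stim_electrode_pair,
         pulse = pulse),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d cycles x %d trials x %d stimuli @ %g Hz (%d total)\n",
    x$n_cycles, x$trials_per_cycle, x$stimuli_per_trial,
    x$stimulus_frequency,
    x$n_cycles * x$trials_per_cycle * x$stimuli_per_trial))
  invisible(x)
}

#' Post-stimulus analysis window
#'
#' Spikes in the first `artifact_blank` ms after a stimulus are discarded
#' (stimulation artifact); the analysis interval is
#' `(artifact_blank, window_end]` ms, by default 10-200 ms.
#'
#' @param artifact_blank Blanking period, ms.
#' @param window_end End of the analysis window, ms.
#' @return Object of class `response_window`.
#' @export
response_window <- function(artifact_blank = 10, window_end = 200) {
  if (!(artifact_blank > 0 && artifact_blank < window_end))
    stop("need 0 < artifact_blank < window_end", call. = FALSE)
  structure(list(artifact_blank = artifact_blank, window_end = window_end),
            class = "response_window")
}

#' Build the deterministic stimulation schedule
#'
#' Stimuli within a trial are spaced `1000 / stimulus_frequency` ms apart;
#' `rest_after_trial` seconds separate trials and an additional
#' `rest_after_cycle` seconds follow each cycle. Event times start at
#' `t0`. The total event count is always
#' `n_cycles * trials_per_cycle * stimuli_per_trial`, independent of the
#' rest durations.
#'
#' @param p A [stim_protocol()].
#' @param t0 Time of the first stimulus, ms.
#' @return A `stimulus_log`: data frame with columns `time_ms`, `cycle`,
#'   `trial` (within cycle), `stim` (within trial) and `trial_global`
#'   (1..`n_cycles * trials_per_cycle`).
#' @export
build_schedule <- function(p, t0 = 0) {
  stopifnot(inherits(p, "stim_protocol"))
  isi <- 1000 / p$stimulus_frequency
  rows <- vector("list", p$n_cycles * p$trials_per_cycle)
  t <- t0
  k <- 0L
  for (cy in seq_len(p$n_cycles)) {
    for (tr in seq_len(p$trials_per_cycle)) {
      k <- k + 1L
      times <- t + (seq_len(p$stimuli_per_trial) - 1L) * isi
      rows[[k]] <- data.frame(
        time_ms = times, cycle = cy, trial = tr,
        stim = seq_len(p$stimuli_per_trial),
        trial_global = (cy - 1L) * p$trials_per_cycle + tr
      )
      t <- times[length(times)] + isi + p$rest_after_trial * 1000
    }
    t <- t + p$rest_after_cycle * 1000
  }
  log <- do.call(rbind, rows)
  class(log) <- c("stimulus_log", "data.frame")
  log
}

#' Total span of a schedule in ms
#'
#' Time from `t0 = 0` to the end of the last cycle's rest period, a
#' convenient recording duration for simulated learning phases.
#' @param p A [stim_protocol()].
#' @return Duration in ms.
#' @export
schedule_duration <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  isi <- 1000 / p$stimulus_frequency
  per_trial <- p$stimuli_per_trial * isi + p$rest_after_trial * 1000
  p$n_cycles * (p$trials_per_cycle * per_trial + p$rest_after_cycle * 1000)
}

#' Stimulus-evoked spikes of one electrode
#'
#' For each stimulus, returns the latencies (ms relative to the stimulus)
#' of the electrode's spikes inside the analysis window
#' `(artifact_blank, window_end]`. When stimuli are spaced more closely
#' than `window_end`, windows are truncated at the next stimulus and a
#' warning is issued.
#'
#' @param s A `spike_train_set`.
#' @param log A `stimulus_log` from [build_schedule()].
#' @param w A [response_window()].
#' @param electrode Linear electrode index.
#' @return List (one element per stimulus, in log order) of numeric
#'   latency vectors.
#' @export
evoked_spikes <- function(s, log, w = response_window(), electrode) {
  stopifnot(inherits(s, "spike_train_set"), inherits(w, "response_window"))
  electrode <- check_electrode_index(electrode, s$grid)
  times <- log$time_ms
  ends <- times + w$window_end
  nxt <- c(times[-1], Inf)
  if (any(nxt < ends)) {
    warning("stimulus spacing shorter than window_end; windows truncated",
            call. = FALSE)
    ends <- pmin(ends, nxt)
  }
  tr <- s$spikes[[electrode]]
  lapply(seq_along(times), function(i) {
    lat <- tr[tr > times[i] + w$artifact_blank & tr <= ends[i]] - times[i]
    as.numeric(lat)
  })
}
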