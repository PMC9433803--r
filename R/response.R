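#' Stimulus-evoked response flag
#'
#' An electrode's response to one stimulus is "evoked" when its spike
#' count in the analysis window strictly exceeds the network-average
#' spike count (over active electrodes) for that stimulus.
#'
#' @param spike_count Spike count(s) in the window.
#' @param network_mean_count Network mean count for the same stimulus.
#' @return Logical.
#' @export
response_flag <- function(spike_count, network_mean_count) {
  spike_count > network_mean_count
}

#' Response time of one stimulus window
#'
#' Mean latency of the first (up to) three post-stimulus spikes inside
#' the analysis window; `NA` when the window holds no spike.
#'
#' @param latencies Sorted latencies, ms.
#' @return Mean of the first `min(3, k)` latencies, or `NA_real_`.
#' @export
response_time <- function(latencies) {
  if (length(latencies) == 0L) return(NA_real_)
  mean(latencies[seq_len(min(3L, length(latencies)))])
}

#' Tabulate evoked responses over the whole array
#'
#' For every (electrode, stimulus) pair: the spike count in the analysis
#' window, the per-stimulus response flag (count strictly above the
#' network mean over active electrodes), and the response time (mean of
#' the first three latencies). Aggregated per (electrode, trial): the
#' R/S ratio (responses / stimuli per trial, in \[0, 1\]) and the mean
#' response time over the trial's defined stimuli.
#'
#' @param s A `spike_train_set`.
#' @param log A `stimulus_log`.
#' @param w A [response_window()].
#' @param active An [active_electrodes()] result (default: all with >= 1
#'   spike); defines the population over which the network mean count is
#'   taken.
#' @return Object of class `trial_response_table`: list of matrices
#'   `counts`, `flags`, `rt` (electrodes x stimuli), `rs_trial`,
#'   `rt_trial`, `rt_trial_n` (electrodes x trials), plus `network_mean`
#'   (per stimulus), `trials`, `log`, `window`, `active`.
#' @export
response_table <- function(s, log, w = response_window(), active = NULL) {
  stopifnot(inherits(s, "spike_train_set"), inherits(w, "response_window"))
  if (is.null(active)) active <- active_electrodes(s)
  ne <- length(s$spikes)
  st <- log$time_ms
  ns <- length(st)
  ends <- pmin(st + w$window_end, c(st[-1], Inf))

  elec <- rep.int(seq_len(ne), lengths(s$spikes))
  t <- unlist(s$spikes, use.names = FALSE)
  i <- findInterval(t, st)
  ok <- i >= 1L
  lat <- t[ok] - st[i[ok]]
  e_ok <- elec[ok]; i_ok <- i[ok]
  keep <- lat > w$artifact_blank & lat <= (ends[i_ok] - st[i_ok])
  e_ok <- e_ok[keep]; i_ok <- i_ok[keep]; lat <- lat[keep]

  counts <- matrix(0L, ne, ns)
  if (length(e_ok)) {
    tab <- table(factor(e_ok, levels = seq_len(ne)),
                 factor(i_ok, levels = seq_len(ns)))
    counts <- matrix(as.integer(tab), ne, ns)
  }
  network_mean <- colMeans(counts[active$indices, , drop = FALSE])
  flags <- sweep(counts, 2, network_mean, ">")

  rt <- matrix(NA_real_, ne, ns)
  if (length(e_ok)) {
    key <- (i_ok - 1) * ne + e_ok
    ord <- order(key, lat)
    k <- key[ord]; l <- lat[ord]
    pos <- sequence(rle(k)$lengths)
    sel <- pos <= 3L
    sums <- rowsum(l[sel], k[sel])
    nsel <- rowsum(rep(1, sum(sel)), k[sel])
    kk <- as.numeric(rownames(sums))
    rt[kk] <- sums / nsel
  }

  nt <- max(log$trial_global)
  trial_of <- log$trial_global
  rs_trial <- t(rowsum(t(flags) * 1, trial_of) /
                  as.vector(table(trial_of)))
  rt_def <- !is.na(rt)
  rt0 <- rt; rt0[!rt_def] <- 0
  rt_sum <- t(rowsum(t(rt0), trial_of))
  rt_n <- t(rowsum(t(rt_def) * 1, trial_of))
  rt_trial <- rt_sum / rt_n
  rt_trial[rt_n == 0] <- NA_real_
  dimnames(rs_trial) <- dimnames(rt_trial) <- dimnames(rt_n) <- NULL

  structure(
    list(counts = counts, flags = flags, rt = rt,
         rs_trial = rs_trial, rt_trial = rt_trial, rt_trial_n = rt_n,
         network_mean = network_mean, trials = seq_len(nt), log = log,
         window = w, active = active),
    class = "trial_response_table"
  )
}

#' First-order linear trend across trials
#'
#' Ordinary least-squares fit of a per-trial series against the trial
#' index; undefined trials (`NA`) are skipped. With fewer than
#' `min_defined` defined values the fit is undefined.
#'
#' @param values Per-trial values (may contain `NA`).
#' @param trials Trial indices (default `seq_along(values)`).
#' @param min_defined Minimum number of defined values (default 8).
#' @return List `slope`, `intercept`, `r`, `r_squared`, `p_value`, `n`.
#'   All statistics `NA` when the fit is undefined.
#' @export
fit_trial_trend <- function(values, trials = seq_along(values),
                            min_defined = 8L) {
  ok <- !is.na(values)
  n <- sum(ok)
  und <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
              r_squared = NA_real_, p_value = NA_real_, n = n)
  if (n < max(2L, min_defined)) return(und)
  x <- trials[ok]; y <- values[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(und)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    return(list(slope = 0, intercept = mean(y), r = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n = n))
  }
  r <- slope * sqrt(sxx / syy)
  r2 <- r^2
  p <- if (n > 2 && r2 < 1) {
    tt <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tt), n - 2)
  } else if (r2 >= 1) 0 else NA_real_
  list(slope = slope, intercept = intercept, r = r, r_squared = r2,
       p_value = p, n = n)
}

#' Localize the learning population
#'
#' Fits per-electrode first-order trends of the R/S ratio and of the mean
#' response time across trials and intersects the two criteria: an
#' electrode belongs to the learning population when its R/S slope is
#' positive AND its RT slope is negative AND it had at least
#' `min_defined_trials` trials with a defined RT. Optionally both slopes
#' must also be significant at `significance_level` (two-sided OLS
#' t-test); the default (`NULL`) is the sign-only rule.
#'
#' @param tbl A [response_table()].
#' @param grid The `electrode_grid` (for the row/col columns).
#' @param min_defined_trials Minimum defined-RT trials (default 8).
#' @param significance_level Optional slope p-value cutoff (e.g. 0.05);
#'   `NULL` disables the filter.
#' @return A `learning_map` data frame, one row per electrode:
#'   `electrode,row,col,rs_slope,rs_r,rs_r2,rs_p,rt_slope,rt_r,rt_r2,
#'   rt_p,n_rt_trials,rs_positive,rt_negative,is_learning`.
#' @export
localize <- function(tbl, grid, min_defined_trials = 8L,
                     significance_level = NULL) {
  stopifnot(inherits(tbl, "trial_response_table"))
  ne <- nrow(tbl$rs_trial)
  rs_fit <- apply_fits(tbl$rs_trial, tbl$trials, min_defined = 2L)
  rt_fit <- apply_fits(tbl$rt_trial, tbl$trials,
                       min_defined = min_defined_trials)
  rc <- electrode_rc(seq_len(ne), grid)
  n_rt <- rowSums(!is.na(tbl$rt_trial))
  rs_pos <- !is.na(rs_fit$slope) & rs_fit$slope > 0
  rt_neg <- !is.na(rt_fit$slope) & rt_fit$slope < 0
  if (!is.null(significance_level)) {
    rs_pos <- rs_pos & !is.na(rs_fit$p) & rs_fit$p <= significance_level
    rt_neg <- rt_neg & !is.na(rt_fit$p) & rt_fit$p <= significance_level
  }
  out <- data.frame(
    electrode = seq_len(ne), row = rc[, "row"], col = rc[, "col"],
    rs_slope = rs_fit$slope, rs_r = rs_fit$r, rs_r2 = rs_fit$r2,
    rs_p = rs_fit$p,
    rt_slope = rt_fit$slope, rt_r = rt_fit$r, rt_r2 = rt_fit$r2,
    rt_p = rt_fit$p,
    n_rt_trials = n_rt,
    rs_positive = rs_pos, rt_negative = rt_neg,
    is_learning = rs_pos & rt_neg & (n_rt >= min_defined_trials)
  )
  class(out) <- c("learning_map", "data.frame")
  out
}

# Row-wise OLS trend fits of a (electrodes x trials) matrix.
apply_fits <- function(m, trials, min_defined) {
  ne <- nrow(m)
  slope <- r <- r2 <- p <- rep(NA_real_, ne)
  complete <- !anyNA(m)
  if (complete) {
    x <- trials
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    ym <- rowMeans(m)
    sxy <- as.vector((m - ym) %*% xc)
    slope <- sxy / sxx
    syy <- rowSums((m - ym)^2)
    pos <- syy > 0
    r[pos] <- slope[pos] * sqrt(sxx / syy[pos])
    slope[!pos] <- 0
    r2 <- r^2
    n <- length(x)
    ok <- pos & r2 < 1
    tt <- r[ok] * sqrt((n - 2) / (1 - r2[ok]))
    p[ok] <- 2 * stats::pt(-abs(tt), n - 2)
    p[pos & r2 >= 1] <- 0
  } else {
    for (e in seq_len(ne)) {
      f <- fit_trial_trend(m[e, ], trials, min_defined)
      slope[e] <- f$slope; r[e] <- f$r; r2[e] <- f$r_squared
      p[e] <- f$p_value
    }
  }
  list(slope = slope, r = r, r2 = r2, p = p)
}

#' Inter-spike-interval Shannon entropy
#'
#' Bins the ISI distribution of one spike train on `[0, max_isi)` at
#' `bin_width` ms with one overflow bin for ISIs `>= max_isi`, and
#' returns `E = -sum(P_i * log2(P_i))` with the convention
#' `0 * log2(0) = 0`. Undefined for trains with fewer than two spikes.
#'
#' @param spikes Sorted spike times, ms.
#' @param bin_width ISI bin width, ms (default 10).
#' @param max_isi Start of the overflow bin, ms (default 1000).
#' @return List `entropy` (bits, `NA` if undefined), `p` (bin
#'   probabilities), `counts`, `n_bins`, `defined`.
#' @export
isi_entropy <- function(spikes, bin_width = 10, max_isi = 1000) {
  n_bins <- as.integer(ceiling(max_isi / bin_width)) + 1L  # + overflow
  if (length(spikes) < 2L)
    return(list(entropy = NA_real_, p = rep(0, n_bins),
                counts = rep(0L, n_bins), n_bins = n_bins,
                defined = FALSE))
  isi <- diff(spikes)
  b <- pmin(floor(isi / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(b, n_bins)
  p <- counts / sum(counts)
  nz <- p > 0
  list(entropy = -sum(p[nz] * log2(p[nz])), p = p, counts = counts,
       n_bins = n_bins, defined = TRUE)
}

#' Per-electrode ISI entropies
#'
#' @param s A `spike_train_set`.
#' @inheritParams isi_entropy
#' @return Numeric vector of entropies (bits), `NA` where undefined
#'   (fewer than two spikes).
#' @export
entropy_map <- function(s, bin_width = 10, max_isi = 1000) {
  stopifnot(inherits(s, "spike_train_set"))
  vapply(s$spikes,
         function(t) isi_entropy(t, bin_width, max_isi)$entropy, 1)
}

#' Entropy share of the learning population
#'
#' Fraction of the network's total ISI information entropy carried by
#' the learning electrodes: aggregate (sum by default, optionally mean)
#' over learning electrodes divided by the same aggregate over all
#' electrodes with a defined entropy.
#'
#' @param learning_mask Logical vector (length = electrodes).
#' @param entropies Per-electrode entropies from [entropy_map()].
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return Fraction; `NA` with a warning when the global aggregate is 0.
#' @export
entropy_ratio <- function(learning_mask, entropies,
                          aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "sum") function(x) sum(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  total <- agg(entropies)
  if (!is.finite(total) || total == 0) {
    warning("global entropy aggregate is zero; ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (!any(learning_mask)) return(0)
  agg(entropies[learning_mask]) / total
}
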