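#' Cross-correlogram of two spike trains
#'
#' For every lag bin `tau` on `[-tau_max, +tau_max]` (1-ms bins by
#' default), counts the spike pairs whose lag `t_y - t_x` falls within
#' `tau +/- delta_tau / 2`, scaled by the normalization mode:
#' `"product"` (default) divides by `N_x * N_y`; `"sqrt"` divides by
#' `sqrt(N_x * N_y)`. The correlogram computed on (x, y) equals the one
#' on (y, x) mirrored in `tau`. The peak holds the maximum value, its
#' lag, and the lag polarity.
#'
#' @param x,y Sorted spike trains, ms (both non-empty).
#' @param bin Lag-bin width, ms (default 1).
#' @param tau_max Maximum lag, ms (default 50).
#' @param delta_tau Coincidence window around each lag, ms (default 5).
#' @param normalization `"product"` or `"sqrt"`.
#' @return Object of class `cross_correlogram`: list `lags`, `values`,
#'   `n_x`, `n_y`, `delta_tau`, `normalization` and `peak`
#'   (`lag`, `value`, `polarity` in -1/0/+1).
#' @export
cross_correlogram <- function(x, y, bin = 1, tau_max = 50, delta_tau = 5,
                              normalization = c("product", "sqrt")) {
  normalization <- match.arg(normalization)
  if (length(x) == 0L || length(y) == 0L)
    stop("cross_correlogram undefined for empty spike trains",
         call. = FALSE)
  lags <- seq(-tau_max, tau_max, by = bin)
  # all pairwise lags within reach of any lag bin, via a sorted sweep
  reach <- tau_max + delta_tau / 2
  d <- sort(unlist(lapply(x, function(t) {
    lo <- findInterval(t - reach, y) + 1L
    hi <- findInterval(t + reach, y)
    if (hi >= lo) y[lo:hi] - t else numeric(0)
  }), use.names = FALSE))
  # count(tau) = #{d <= tau + dt/2} - #{d < tau - dt/2}
  hi <- findInterval(lags + delta_tau / 2, d)
  lo <- findInterval(lags - delta_tau / 2, d, left.open = TRUE)
  counts <- hi - lo
  denom <- switch(normalization,
                  product = length(x) * length(y),
                  sqrt = sqrt(length(x) * length(y)))
  values <- counts / denom
  # with delta_tau > bin the maximum is a plateau; take its central lag
  ties <- which(values == max(values))
  ip <- ties[(length(ties) + 1L) %/% 2L]
  structure(
    list(lags = lags, values = values, n_x = length(x), n_y = length(y),
         delta_tau = delta_tau, normalization = normalization,
         peak = list(lag = lags[ip], value = values[ip],
                     polarity = sign(lags[ip]))),
    class = "cross_correlogram"
  )
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf(
    "<cross_correlogram> %d lags, peak %.4g at %+g ms (N_x=%d, N_y=%d)\n",
    length(x$lags), x$peak$value, x$peak$lag, x$n_x, x$n_y))
  invisible(x)
}

#' Build the functional graph over learning-population nodes
#'
#' Computes the cross-correlogram for every node pair, takes each pair's
#' peak value as the (symmetric) edge weight, sets the detection
#' threshold at `mean(peaks) + sd_multiplier * sd(peaks)`, and keeps
#' pairs whose weight reaches it. Edge direction follows the
#' peak-lag polarity: a peak at positive lag means the second train
#' follows the first (edge x -> y); a negative-lag peak gives y -> x; a
#' zero-lag peak yields reciprocal edges. Nodes with empty trains are
#' kept but isolated.
#'
#' @param s A `spike_train_set`.
#' @param nodes Node electrodes: integer ids or a logical mask over the
#'   grid (e.g. `learning_map$is_learning`).
#' @param bin,tau_max,delta_tau,normalization Passed to
#'   [cross_correlogram()].
#' @param sd_multiplier Threshold SD multiplier (default 3).
#' @return Object of class `functional_graph`: list with `nodes`
#'   (electrode ids), `weights` and `peak_lag` (node x node matrices),
#'   `adjacency` (directed 0/1), `threshold`, and the correlogram
#'   settings.
#' @export
build_functional_graph <- function(s, nodes, bin = 1, tau_max = 50,
                                   delta_tau = 5, sd_multiplier = 3,
                                   normalization = "product") {
  stopifnot(inherits(s, "spike_train_set"))
  if (is.logical(nodes)) nodes <- which(nodes)
  nodes <- check_electrode_index(nodes, s$grid)
  n <- length(nodes)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  weights <- matrix(0, n, n)
  peak_lag <- matrix(NA_real_, n, n)
  trains <- s$spikes[nodes]
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (length(trains[[i]]) == 0L || length(trains[[j]]) == 0L) next
      cc <- cross_correlogram(trains[[i]], trains[[j]], bin, tau_max,
                              delta_tau, normalization)
      weights[i, j] <- weights[j, i] <- cc$peak$value
      peak_lag[i, j] <- cc$peak$lag
      peak_lag[j, i] <- -cc$peak$lag
    }
  }
  ut <- weights[upper.tri(weights)]
  threshold <- mean(ut) + sd_multiplier * stats::sd(ut)
  adjacency <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # >= so the degenerate all-equal-weights case (sd = 0) keeps its
      # edges; indistinguishable from > for continuous weights
      if (!(weights[i, j] >= threshold)) next
      lag <- peak_lag[i, j]
      if (is.na(lag)) next
      if (lag > 0) adjacency[i, j] <- 1L
      else if (lag < 0) adjacency[j, i] <- 1L
      else adjacency[i, j] <- adjacency[j, i] <- 1L
    }
  }
  if (all(adjacency == 0L))
    warning("all node pairs sub-threshold; functional graph is empty",
            call. = FALSE)
  dimnames(weights) <- dimnames(adjacency) <- dimnames(peak_lag) <-
    list(nodes, nodes)
  structure(
    list(nodes = nodes, weights = weights, peak_lag = peak_lag,
         adjacency = adjacency, threshold = threshold, bin = bin,
         tau_max = tau_max, delta_tau = delta_tau,
         sd_multiplier = sd_multiplier, normalization = normalization),
    class = "functional_graph"
  )
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf(
    "<functional_graph> %d nodes, %d directed edges, threshold %.4g\n",
    length(x$nodes), sum(x$adjacency), x$threshold))
  invisible(x)
}

#' Edge list of a functional graph
#' @param g A `functional_graph`.
#' @return Data frame `src,dst,weight,peak_lag_ms` (electrode ids).
#' @export
edge_list <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  idx <- which(g$adjacency == 1L, arr.ind = TRUE)
  data.frame(
    src = g$nodes[idx[, 1]], dst = g$nodes[idx[, 2]],
    weight = g$weights[idx],
    peak_lag_ms = g$peak_lag[idx]
  )
}

#' Pearson correlation of binned firing rates
#'
#' Bins both trains into common `bin`-ms count vectors over
#' `[0, duration)` and returns their Pearson correlation.
#'
#' @param x,y Spike trains, ms.
#' @param duration Recording duration, ms.
#' @param bin Bin width, ms (default 100).
#' @return Pearson r; `NA` with a warning when either count vector has
#'   zero variance.
#' @export
rate_correlation <- function(x, y, duration, bin = 100) {
  nb <- ceiling(duration / bin)
  if (nb < 2) stop("need at least 2 bins", call. = FALSE)
  cx <- tabulate(pmin(floor(x / bin), nb - 1) + 1L, nb)
  cy <- tabulate(pmin(floor(y / bin), nb - 1) + 1L, nb)
  if (stats::sd(cx) == 0 || stats::sd(cy) == 0) {
    warning("zero-variance rate vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(cx, cy)
}

#' Spike-train synchrony score
#'
#' For each spike of one train, the distance to the nearest spike of the
#' other train is inverted through `1 / (1 + dt / tau_s)` so that close
#' spikes score near 1; the score is averaged over spikes and
#' symmetrized by averaging both directions. Lies in (0, 1], with 1 for
#' identical trains.
#'
#' @param x,y Sorted spike trains, ms (both non-empty).
#' @param tau_s Softening timescale, ms (default 10).
#' @return Synchrony score in (0, 1].
#' @export
synchrony <- function(x, y, tau_s = 10) {
  if (length(x) == 0L || length(y) == 0L)
    stop("synchrony undefined for empty spike trains", call. = FALSE)
  one_way <- function(a, b) {
    i <- findInterval(a, b)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(b))
    dt <- pmin(abs(a - b[lo]), abs(a - b[hi]))
    mean(1 / (1 + dt / tau_s))
  }
  (one_way(x, y) + one_way(y, x)) / 2
}
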