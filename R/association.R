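#' Regression of cluster burst counts on a local node metric
#'
#' For each onset cluster, the predictor is the mean of a node metric
#' (degree or betweenness) over the learning electrodes within
#' `link_radius` of the cluster centroid; the response is the cluster's
#' burst count. Clusters with no linked learning electrode are excluded
#' (and counted). Requires at least 3 linked clusters and a
#' non-degenerate predictor for a defined correlation.
#'
#' @param clusters Data frame with `x`, `y` (centroid, um) and
#'   `burst_count` (e.g. from [cluster_onsets()]).
#' @param metrics A `graph_metrics` object (or its `nodes` data frame
#'   with columns `electrode` and the metric).
#' @param metric_name `"betweenness"` or `"degree"`.
#' @param grid The `electrode_grid`.
#' @param link_radius Linking radius around the centroid, um
#'   (default 115).
#' @return List `slope,intercept,r,r_squared,n,n_excluded,metric`,
#'   plus `x`, `y` vectors used in the fit. `r` is `NA` (flagged) for a
#'   constant predictor; errors if every cluster is unlinked.
#' @export
metric_burst_regression <- function(clusters, metrics,
                                    metric_name = c("betweenness", "degree"),
                                    grid, link_radius = 115) {
  metric_name <- match.arg(metric_name)
  nodes <- if (inherits(metrics, "graph_metrics")) metrics$nodes else metrics
  stopifnot(all(c("electrode", metric_name) %in% names(nodes)))
  pos <- electrode_position(nodes$electrode, grid)
  xbar <- rep(NA_real_, nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    d <- sqrt((pos[, "x"] - clusters$x[k])^2 +
                (pos[, "y"] - clusters$y[k])^2)
    linked <- d <= link_radius
    if (any(linked)) xbar[k] <- mean(nodes[[metric_name]][linked])
  }
  ok <- !is.na(xbar)
  n_excluded <- sum(!ok)
  if (!any(ok))
    stop("no cluster has a linked learning electrode within link_radius",
         call. = FALSE)
  x <- xbar[ok]
  y <- clusters$burst_count[ok]
  out <- list(metric = metric_name, n = length(x),
              n_excluded = n_excluded, x = x, y = y)
  if (length(x) < 3L || stats::sd(x) == 0) {
    out$slope <- out$intercept <- out$r <- out$r_squared <- NA_real_
    out$degenerate <- TRUE
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  out$slope <- unname(fit$coefficients[2])
  out$intercept <- unname(fit$coefficients[1])
  out$r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  out$r_squared <- if (is.na(out$r)) NA_real_ else out$r^2
  out$degenerate <- FALSE
  out
}

#' Overlap of burst-onset electrodes with top-metric learning electrodes
#'
#' The "top set" keeps the learning electrodes whose metric rank lies in
#' the highest `percentile_keep` fraction (default 0.9, i.e. everything
#' above the bottom 10%; ties at the cut are kept). Each onset electrode
#' maps to itself if it belongs to the learning set, otherwise to its
#' nearest learning electrode within `link_radius` (onsets with no such
#' electrode count as non-overlap). The overlap is the fraction of onset
#' electrodes mapping into the top set.
#'
#' @param onset_electrodes Integer electrode ids involved in burst onsets
#'   (non-empty; duplicates allowed and counted once).
#' @param metrics A `graph_metrics` (or its `nodes` data frame) over the
#'   learning electrodes.
#' @param metric_name `"betweenness"` or `"degree"`.
#' @param grid The `electrode_grid`.
#' @param percentile_keep Fraction of top-ranked learning electrodes kept
#'   (default 0.9; set 0.1 for the strict "top decile" reading).
#' @param link_radius Mapping radius for onsets outside the learning
#'   set, um (default 115).
#' @return Overlap fraction in \[0, 1\].
#' @export
top_percentile_overlap <- function(onset_electrodes, metrics,
                                   metric_name = c("betweenness", "degree"),
                                   grid, percentile_keep = 0.9,
                                   link_radius = 115) {
  metric_name <- match.arg(metric_name)
  nodes <- if (inherits(metrics, "graph_metrics")) metrics$nodes else metrics
  onset <- unique(as.integer(onset_electrodes))
  if (length(onset) == 0L) stop("empty onset set", call. = FALSE)
  v <- nodes[[metric_name]]
  cut <- stats::quantile(v, 1 - percentile_keep, names = FALSE, type = 1)
  top <- nodes$electrode[v >= cut]
  if (length(top) == 0L) {
    warning("empty top set", call. = FALSE)
    return(0)
  }
  lpos <- electrode_position(nodes$electrode, grid)
  opos <- electrode_position(onset, grid)
  mapped <- vapply(seq_along(onset), function(i) {
    if (onset[i] %in% nodes$electrode) return(onset[i])
    d <- sqrt((lpos[, "x"] - opos[i, "x"])^2 +
                (lpos[, "y"] - opos[i, "y"])^2)
    j <- which.min(d)
    if (d[j] <= link_radius) nodes$electrode[j] else NA_integer_
  }, 1L)
  mean(!is.na(mapped) & mapped %in% top)
}

#' Pre/post comparison of a summary statistic
#'
#' Means, standard errors and a Welch (unequal-variance) two-sided
#' t-test. When both samples are degenerate (zero variance) the row
#' falls back to an exact-equality report with a flag.
#'
#' @param series_pre,series_post Numeric samples (each n >= 2).
#' @param label Statistic name carried into the row.
#' @return List
#'   `label,n_pre,n_post,mean_pre,mean_post,se_pre,se_post,diff,t,df,
#'   p_value,degenerate`.
#' @export
pre_post_compare <- function(series_pre, series_post, label = "") {
  series_pre <- series_pre[!is.na(series_pre)]
  series_post <- series_post[!is.na(series_post)]
  if (length(series_pre) < 2L || length(series_post) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(label = label,
              n_pre = length(series_pre), n_post = length(series_post),
              mean_pre = mean(series_pre), mean_post = mean(series_post),
              se_pre = se(series_pre), se_post = se(series_post),
              diff = mean(series_post) - mean(series_pre))
  if (stats::sd(series_pre) == 0 && stats::sd(series_post) == 0) {
    out$t <- if (out$diff == 0) 0 else NA_real_
    out$df <- NA_real_
    out$p_value <- if (out$diff == 0) 1 else NA_real_
    out$degenerate <- TRUE
    return(out)
  }
  tt <- stats::t.test(series_post, series_pre, var.equal = FALSE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out$degenerate <- FALSE
  out
}
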