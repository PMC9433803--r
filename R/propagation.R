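#' First-spike rank-order map of a burst
#'
#' Ranks a burst's participating electrodes by first-spike time (rank 1 =
#' earliest); ties are broken by (row, col) lexicographic order, so the
#' map is deterministic.
#'
#' @param b A `network_burst`.
#' @param grid The `electrode_grid`.
#' @return Data frame `electrode,row,col,first_spike,rank`, sorted by
#'   rank.
#' @export
rank_order_map <- function(b, grid) {
  stopifnot(inherits(b, "network_burst"))
  if (length(b$electrodes) < 1L)
    stop("burst has no participating electrodes", call. = FALSE)
  rc <- electrode_rc(b$electrodes, grid)
  ord <- order(b$first_spike, rc[, "row"], rc[, "col"])
  out <- data.frame(
    electrode = b$electrodes[ord],
    row = rc[ord, "row"], col = rc[ord, "col"],
    first_spike = as.numeric(b$first_spike)[ord],
    rank = seq_along(ord)
  )
  class(out) <- c("rank_map", "data.frame")
  out
}

#' Burst initiation site
#'
#' The onset electrodes of a burst are its `n_onset` earliest first-spike
#' ranks (10 by default, fewer if the burst is smaller); the initiation
#' site is the arithmetic mean of their center positions.
#'
#' @param map A [rank_order_map()].
#' @param grid The `electrode_grid`.
#' @param n_onset Number of onset electrodes (default 10).
#' @return Named numeric `c(x, y)` in um.
#' @export
initiation_site <- function(map, grid, n_onset = 10L) {
  onset <- map$electrode[map$rank <= n_onset]
  pos <- electrode_position(onset, grid)
  c(x = mean(pos[, "x"]), y = mean(pos[, "y"]))
}

#' Distance-latency regression of burst propagation
#'
#' OLS of each participating electrode's first-spike latency (relative to
#' the burst's earliest first spike) on its distance from the initiation
#' site. For radial propagation at speed `v` the slope is `1/v` ms/um.
#'
#' @param map A [rank_order_map()] with at least 3 electrodes.
#' @param grid The `electrode_grid`.
#' @param site Initiation site; default recomputed by
#'   [initiation_site()].
#' @return List `slope` (ms/um), `intercept`, `r`, `r_squared`, `speed`
#'   (`1/slope`, um/ms), `n`; all `NA` (flagged `degenerate`) when all
#'   distances coincide.
#' @export
distance_latency_fit <- function(map, grid, site = NULL) {
  if (nrow(map) < 3L)
    stop("need at least 3 participating electrodes", call. = FALSE)
  if (is.null(site)) site <- initiation_site(map, grid)
  pos <- electrode_position(map$electrode, grid)
  d <- sqrt((pos[, "x"] - site["x"])^2 + (pos[, "y"] - site["y"])^2)
  lat <- map$first_spike - min(map$first_spike)
  if (stats::sd(d) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, speed = NA_real_, n = nrow(map),
                degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, d), lat)
  slope <- fit$coefficients[2]
  r <- if (stats::sd(lat) == 0) NA_real_ else stats::cor(d, lat)
  list(slope = unname(slope), intercept = unname(fit$coefficients[1]),
       r = r, r_squared = if (is.na(r)) NA_real_ else r^2,
       speed = unname(1 / slope), n = nrow(map), degenerate = FALSE)
}

#' Distance from a site to the nearest learning electrode
#'
#' @param site Numeric `c(x, y)` in um.
#' @param learning Integer electrode ids of the learning population
#'   (non-empty).
#' @param grid The `electrode_grid`.
#' @return Minimum Euclidean distance, um.
#' @export
nearest_learning_distance <- function(site, learning, grid) {
  if (length(learning) == 0L)
    stop("learning population is empty", call. = FALSE)
  pos <- electrode_position(learning, grid)
  min(sqrt((pos[, "x"] - site[1])^2 + (pos[, "y"] - site[2])^2))
}

#' Cumulative distance distribution of initiation sites
#'
#' Fraction of initiation sites whose nearest-learning-electrode distance
#' is at most each threshold (inclusive). The default thresholds are one
#' pitch, one diagonal and two pitches of the default grid (81, 115,
#' 162 um).
#'
#' @param sites Two-column matrix of initiation sites (x, y), um.
#' @param learning Integer electrode ids of the learning population.
#' @param grid The `electrode_grid`.
#' @param thresholds Distance thresholds, um.
#' @return Named numeric vector of cumulative fractions (monotone
#'   non-decreasing).
#' @export
distance_distribution <- function(sites, learning, grid,
                                  thresholds = c(81, 115, 162)) {
  sites <- matrix(as.numeric(sites), ncol = 2)
  d <- apply(sites, 1, nearest_learning_distance, learning = learning,
             grid = grid)
  out <- vapply(thresholds, function(th) mean(d <= th), 1)
  names(out) <- paste0("within_", thresholds, "_um")
  out
}

#' Cluster burst-initiation sites
#'
#' Single-linkage agglomeration: sites within `radius` of any member of
#' a cluster join that cluster. Deterministic given the input (sites are
#' processed in (x, y) sorted order). The default radius is one
#' electrode pitch.
#'
#' @param sites Two-column matrix of initiation sites (x, y), um.
#' @param radius Linkage radius, um (default 81).
#' @return Data frame with one row per cluster:
#'   `cluster_id,x,y,burst_count` (centroid = mean of member sites), and
#'   attribute `membership` mapping each input site to its cluster.
#' @export
cluster_onsets <- function(sites, radius = 81) {
  sites <- matrix(as.numeric(sites), ncol = 2)
  n <- nrow(sites)
  if (n < 1L) stop("need at least one site", call. = FALSE)
  memb <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::dist(sites), method = "single")
    stats::cutree(hc, h = radius)
  }
  # renumber clusters by order of first appearance in (x, y) sorted order
  ord <- order(sites[, 1], sites[, 2])
  relabel <- integer(max(memb))
  nxt <- 0L
  for (i in ord) {
    if (relabel[memb[i]] == 0L) {
      nxt <- nxt + 1L
      relabel[memb[i]] <- nxt
    }
  }
  memb <- relabel[memb]
  out <- data.frame(
    cluster_id = seq_len(max(memb)),
    x = tapply(sites[, 1], memb, mean),
    y = tapply(sites[, 2], memb, mean),
    burst_count = as.integer(table(factor(memb, levels = seq_len(max(memb)))))
  )
  rownames(out) <- NULL
  attr(out, "membership") <- memb
  out
}

#' Per-burst propagation table
#'
#' Runs the full propagation analysis over a burst list: rank map,
#' initiation site, distance-latency fit, nearest learning distance and
#' onset cluster, flattened to the on-disk format
#' `burst_id,site_x_um,site_y_um,slope,r2,nearest_learning_um,cluster_id`.
#'
#' @param bursts List of `network_burst` objects.
#' @param grid The `electrode_grid`.
#' @param learning Integer learning-electrode ids (or NULL to skip the
#'   distance column).
#' @param n_onset Onset electrodes per burst (default 10).
#' @param cluster_radius Linkage radius for [cluster_onsets()], um.
#' @return Data frame, one row per burst (zero rows for empty input).
#' @export
propagation_table <- function(bursts, grid, learning = NULL,
                              n_onset = 10L, cluster_radius = 81) {
  if (length(bursts) == 0L)
    return(data.frame(burst_id = integer(0), site_x_um = numeric(0),
                      site_y_um = numeric(0), slope = numeric(0),
                      r2 = numeric(0), nearest_learning_um = numeric(0),
                      cluster_id = integer(0)))
  maps <- lapply(bursts, rank_order_map, grid = grid)
  sites <- t(vapply(maps, initiation_site, c(x = 0, y = 0),
                    grid = grid, n_onset = n_onset))
  fits <- lapply(maps, function(m) {
    if (nrow(m) >= 3L) distance_latency_fit(m, grid)
    else list(slope = NA_real_, r_squared = NA_real_)
  })
  nld <- if (is.null(learning)) rep(NA_real_, length(bursts))
         else apply(sites, 1, nearest_learning_distance,
                    learning = learning, grid = grid)
  cl <- cluster_onsets(sites, cluster_radius)
  data.frame(
    burst_id = seq_along(bursts),
    site_x_um = sites[, 1], site_y_um = sites[, 2],
    slope = vapply(fits, `[[`, 1, "slope"),
    r2 = vapply(fits, `[[`, 1, "r_squared"),
    nearest_learning_um = nld,
    cluster_id = attr(cl, "membership")
  )
}
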