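# Brute-force oracles, fully independent of the package implementations.

# Cross-correlogram by explicit double loop over all spike pairs.
bf_correlogram <- function(x, y, bin = 1, tau_max = 50, delta_tau = 5,
                           normalization = "product") {
  lags <- seq(-tau_max, tau_max, by = bin)
  counts <- numeric(length(lags))
  for (k in seq_along(lags)) {
    lo <- lags[k] - delta_tau / 2
    hi <- lags[k] + delta_tau / 2
    n <- 0L
    for (tx in x) for (ty in y) {
      d <- ty - tx
      if (d >= lo && d <= hi) n <- n + 1L
    }
    counts[k] <- n
  }
  denom <- if (normalization == "product") length(x) * length(y)
           else sqrt(length(x) * length(y))
  counts / denom
}

# Synchrony by O(n^2) nearest-neighbour scans.
bf_synchrony <- function(x, y, tau_s = 10) {
  one <- function(a, b) {
    mean(sapply(a, function(t) {
      dt <- min(abs(b - t))
      1 / (1 + dt / tau_s)
    }))
  }
  (one(x, y) + one(y, x)) / 2
}

# Pearson correlation of binned counts, formula evaluated directly.
bf_rate_correlation <- function(x, y, duration, bin = 100) {
  nb <- ceiling(duration / bin)
  cx <- cy <- numeric(nb)
  for (t in x) cx[min(floor(t / bin), nb - 1) + 1] <- cx[min(floor(t / bin), nb - 1) + 1] + 1
  for (t in y) cy[min(floor(t / bin), nb - 1) + 1] <- cy[min(floor(t / bin), nb - 1) + 1] + 1
  num <- sum((cx - mean(cx)) * (cy - mean(cy)))
  num / sqrt(sum((cx - mean(cx))^2) * sum((cy - mean(cy))^2))
}

# All-pairs hop distances by pure-R BFS.
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(a[v, ] == 1)) {
          if (is.infinite(d[s, w])) {
            d[s, w] <- lev
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_degree <- function(a) as.integer(colSums(a))

bf_density <- function(a) {
  n <- nrow(a)
  sum(a) / (n * (n - 1))
}

bf_efficiency <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  acc <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    acc <- acc + s / (n - 1)
  }
  acc / n
}

# Shortest-path counts by DP over BFS distances; normalized betweenness
# over unordered pairs.
bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (lev in sort(unique(d[s, is.finite(d[s, ])]))) {
      if (lev == 0) next
      for (v in which(d[s, ] == lev)) {
        preds <- which(a[, v] == 1 & d[s, ] == lev - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (h in seq_len(n - 1)) for (j in seq((h + 1), n)) {
      if (h == i || j == i || !is.finite(d[h, j])) next
      if (is.finite(d[h, i]) && is.finite(d[i, j]) &&
          d[h, i] + d[i, j] == d[h, j]) {
        tot <- tot + sigma[h, i] * sigma[i, j] / sigma[h, j]
      }
    }
    b[i] <- tot / ((n - 1) * (n - 2))
  }
  b
}

# Modularity by explicit edge-endpoint bookkeeping (Eq.-style mixing matrix).
bf_modularity <- function(a, memb) {
  l <- sum(a) / 2
  if (l == 0) return(NA_real_)
  mods <- sort(unique(memb))
  q <- 0
  for (u in mods) {
    euu <- 0
    au <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
      if (a[i, j] != 1 || i >= j) next
      if (memb[i] == u && memb[j] == u) {
        euu <- euu + 1 / l
        au <- au + 2 / (2 * l)
      } else if (memb[i] == u || memb[j] == u) {
        au <- au + 1 / (2 * l)
      }
    }
    q <- q + euu - au^2
  }
  q
}

# Random undirected simple graph as adjacency matrix.
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (runif(1) < p) a[i, j] <- a[j, i] <- 1L
  }
  a
}

# Random sorted spike train on [0, duration).
random_train <- function(n, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(runif(n, 0, duration))
}
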