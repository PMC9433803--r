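# Fixture builders shared across test files.

# Spike-train set from a sparse list: spikes_at = list(`3` = c(...), ...)
make_sts <- function(spikes_at, duration, grid = electrode_grid(4, 4)) {
  spikes <- rep(list(numeric(0)), n_electrodes(grid))
  for (nm in names(spikes_at)) {
    spikes[[as.integer(nm)]] <- sort(as.numeric(spikes_at[[nm]]))
  }
  spike_train_set(spikes, duration, grid)
}

# A set where the given electrodes all spike once inside one 25-ms bin
# and every electrode also spikes once in a round-robin background bin
# (so all are active but no background bin holds more than 1/8 of them).
make_bin_burst_sts <- function(in_bin, grid, duration = 1000,
                               bin_start = 500) {
  ne <- n_electrodes(grid)
  spikes <- vector("list", ne)
  for (e in seq_len(ne)) {
    base <- (e %% 8) * 25 + 3 + 0.001 * e
    spikes[[e]] <- if (e %in% in_bin) c(base, bin_start + 5 + 0.001 * e)
                   else base
  }
  spike_train_set(spikes, duration, grid)
}

path3_adj <- function() {
  a <- matrix(0L, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  a
}

two_triangles_adj <- function() {
  a <- matrix(0L, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    a[p[1], p[2]] <- a[p[2], p[1]] <- 1L
  }
  a
}

star_adj <- function(n_leaves) {
  a <- matrix(0L, n_leaves + 1, n_leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}
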