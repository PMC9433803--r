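#' Spike-train set
#'
#' Container for a full-array recording: one sorted spike-time vector per
#' electrode, a recording duration, the grid geometry, and free-form
#' metadata (culture id, phase label, generator seed, ...).
#'
#' Timestamps are milliseconds on the half-open window `[0, duration)`.
#' Per-electrode timestamps must be strictly increasing; exact duplicates
#' on one electrode are forbidden.
#'
#' @param spikes List of numeric vectors, one per electrode (length
#'   `n_electrodes(grid)`), each strictly increasing, in ms.
#' @param duration Recording length in ms.
#' @param grid An [electrode_grid()].
#' @param metadata Named list of free-form metadata.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, duration, grid = electrode_grid(),
                            metadata = list()) {
  stopifnot(inherits(grid, "electrode_grid"))
  ne <- n_electrodes(grid)
  if (!is.list(spikes) || length(spikes) != ne)
    stop(sprintf("`spikes` must be a list of length %d (one per electrode)",
                 ne), call. = FALSE)
  spikes <- lapply(spikes, as.numeric)
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be a positive number of ms", call. = FALSE)
  s <- structure(
    list(spikes = spikes, duration = duration, grid = grid,
         metadata = metadata),
    class = "spike_train_set"
  )
  validate_spike_train_set(s)
  s
}

validate_spike_train_set <- function(s) {
  for (e in seq_along(s$spikes)) {
    t <- s$spikes[[e]]
    if (length(t) == 0L) next
    if (anyNA(t))
      stop(sprintf("electrode %d: NA timestamp", e), call. = FALSE)
    if (t[1] < 0 || t[length(t)] >= s$duration)
      stop(sprintf("electrode %d: timestamp outside [0, duration)", e),
           call. = FALSE)
    if (length(t) > 1L && any(diff(t) <= 0))
      stop(sprintf("electrode %d: timestamps not strictly increasing", e),
           call. = FALSE)
  }
  invisible(s)
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$spikes)
  cat(sprintf(
    "<spike_train_set> %d electrodes, %.1f s, %d spikes (%d active)\n",
    length(x$spikes), x$duration / 1000, sum(ns), sum(ns > 0L)))
  if (!is.null(x$metadata$phase))
    cat(sprintf("  phase: %s\n", x$metadata$phase))
  invisible(x)
}

#' Per-electrode spike counts
#' @param s A `spike_train_set`.
#' @return Integer vector of spike counts, one per electrode.
#' @export
spike_counts <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  lengths(s$spikes)
}

#' Active electrodes
#'
#' An electrode is "active" when it fired at least `min_spikes` spikes over
#' the analyzed recording. The permissive default (`min_spikes = 1`)
#' reproduces the near-full-array activity regime under which the
#' network-burst participation threshold (25% of active electrodes) equals
#' 1,024 electrodes on the default 4,096-electrode grid.
#'
#' @param s A `spike_train_set`.
#' @param min_spikes Minimum spike count (>= 1).
#' @return Object of class `active_electrode_set`: list with integer
#'   `indices` and a `criterion` description string.
#' @export
active_electrodes <- function(s, min_spikes = 1L) {
  stopifnot(inherits(s, "spike_train_set"))
  min_spikes <- as.integer(min_spikes)
  if (is.na(min_spikes) || min_spikes < 1L)
    stop("min_spikes must be >= 1", call. = FALSE)
  idx <- which(spike_counts(s) >= min_spikes)
  structure(
    list(indices = idx,
         criterion = sprintf(">= %d spikes in full recording", min_spikes)),
    class = "active_electrode_set"
  )
}

#' @export
print.active_electrode_set <- function(x, ...) {
  cat(sprintf("<active_electrode_set> %d electrodes (%s)\n",
              length(x$indices), x$criterion))
  invisible(x)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write spike-event files
#'
#' The on-disk format is a UTF-8 CSV with header
#' `electrode,row,col,time_ms` (1-based indices, one spike per row, sorted
#' by electrode then time) plus a JSON sidecar (same basename, `.json`)
#' carrying `duration_ms`, `n_rows`, `n_cols`, `pitch_um`,
#' `electrode_size_um` and any further metadata (e.g. `phase`, `seed`).
#' The round trip `read_spike_trains(write_spike_trains(s, path))`
#' reproduces every timestamp exactly.
#'
#' @param s A `spike_train_set`.
#' @param path Path of the CSV file (sidecar written next to it).
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns a `spike_train_set`.
#' @export
write_spike_trains <- function(s, path) {
  stopifnot(inherits(s, "spike_train_set"))
  ns <- lengths(s$spikes)
  e <- rep.int(seq_along(s$spikes), ns)
  rc <- electrode_rc(if (length(e)) e else 1L, s$grid)
  df <- data.frame(
    electrode = e,
    row = if (length(e)) rc[, "row"] else integer(0),
    col = if (length(e)) rc[, "col"] else integer(0),
    # 17 significant digits: doubles survive the round trip bit-exactly
    time_ms = sprintf("%.17g", unlist(s$spikes, use.names = FALSE))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(duration_ms = s$duration,
                 n_rows = s$grid$n_rows, n_cols = s$grid$n_cols,
                 pitch_um = s$grid$pitch,
                 electrode_size_um = s$grid$electrode_size),
            s$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path))
    stop(sprintf("spike file not found: %s", path), call. = FALSE)
  mpath <- sidecar_path(path)
  if (!file.exists(mpath))
    stop(sprintf("metadata sidecar not found: %s", mpath), call. = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  needed <- c("duration_ms", "n_rows", "n_cols", "pitch_um")
  miss <- setdiff(needed, names(meta))
  if (length(miss))
    stop(sprintf("sidecar %s missing field(s): %s", mpath,
                 paste(miss, collapse = ", ")), call. = FALSE)
  grid <- electrode_grid(meta$n_rows, meta$n_cols, meta$pitch_um,
                         if (is.null(meta$electrode_size_um)) 21
                         else meta$electrode_size_um)
  df <- utils::read.csv(path)
  req <- c("electrode", "row", "col", "time_ms")
  if (!all(req %in% names(df)))
    stop(sprintf("%s: expected header `electrode,row,col,time_ms`", path),
         call. = FALSE)
  ne <- n_electrodes(grid)
  bad <- which(is.na(df$electrode) | df$electrode < 1 | df$electrode > ne)
  if (length(bad))
    stop(sprintf("%s: electrode index out of range at data row %d",
                 path, bad[1]), call. = FALSE)
  bad <- which(df$electrode != (df$row - 1) * grid$n_cols + df$col)
  if (length(bad))
    stop(sprintf("%s: (row,col) inconsistent with electrode at data row %d",
                 path, bad[1]), call. = FALSE)
  bad <- which(is.na(df$time_ms) | df$time_ms < 0 |
                 df$time_ms >= meta$duration_ms)
  if (length(bad))
    stop(sprintf("%s: time_ms outside [0, duration) at data row %d",
                 path, bad[1]), call. = FALSE)
  spikes <- rep(list(numeric(0)), ne)
  if (nrow(df)) {
    ord <- order(df$electrode, df$time_ms)
    df <- df[ord, ]
    dup <- which(duplicated(df[, c("electrode", "time_ms")]))
    if (length(dup))
      stop(sprintf("%s: duplicate timestamp on electrode %d",
                   path, df$electrode[dup[1]]), call. = FALSE)
    spl <- split(df$time_ms, factor(df$electrode, levels = seq_len(ne)))
    spikes <- unname(lapply(spl, as.numeric))
  }
  extra <- meta[setdiff(names(meta), c(needed, "electrode_size_um"))]
  spike_train_set(spikes, meta$duration_ms, grid, metadata = extra)
}
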