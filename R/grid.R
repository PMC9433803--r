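#' Electrode grid geometry
#'
#' Describes the rectangular recording lattice of a high-density
#' microelectrode array (HD-MEA). The default matches a 4,096-electrode
#' CMOS biochip: a 64 x 64 lattice with 81 um pitch and 21 um square
#' electrodes. Electrode centers define all positions; the center of
#' electrode (row 1, col 1) sits at the origin, and the center of
#' electrode (r, c) is at ((c - 1) * pitch, (r - 1) * pitch) um.
#'
#' @param n_rows,n_cols Lattice dimensions (default 64 x 64).
#' @param pitch Center-to-center distance between laterally adjacent
#'   electrodes, in micrometers (default 81).
#' @param electrode_size Electrode side length in micrometers (default 21;
#'   metadata only, no computation depends on it).
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid()
#' n_electrodes(g)
#' @export
electrode_grid <- function(n_rows = 64L, n_cols = 64L, pitch = 81,
                           electrode_size = 21) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(pitch) || pitch <= 0)
    stop("pitch must be a positive length in um", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = as.numeric(pitch),
         electrode_size = as.numeric(electrode_size)),
    class = "electrode_grid"
  )
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d (%d electrodes), pitch %g um\n",
              x$n_rows, x$n_cols, n_electrodes(x), x$pitch))
  invisible(x)
}

#' Number of electrodes on a grid
#' @param grid An `electrode_grid`.
#' @return Integer electrode count (`n_rows * n_cols`).
#' @export
n_electrodes <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  grid$n_rows * grid$n_cols
}

check_electrode_index <- function(e, grid) {
  e <- as.integer(e)
  if (any(is.na(e)) || any(e < 1L) || any(e > n_electrodes(grid)))
    stop(sprintf("electrode index out of range [1, %d]", n_electrodes(grid)),
         call. = FALSE)
  e
}

#' Convert between linear electrode indices and (row, col) pairs
#'
#' Electrodes are numbered 1..n_rows*n_cols in row-major order:
#' `e = (row - 1) * n_cols + col`.
#'
#' @param e Linear electrode indices (1-based).
#' @param row,col 1-based lattice coordinates.
#' @param grid An `electrode_grid`.
#' @return `electrode_rc()` returns a two-column integer matrix
#'   (`row`, `col`); `electrode_id()` returns linear indices.
#' @export
electrode_rc <- function(e, grid) {
  e <- check_electrode_index(e, grid)
  cbind(row = ((e - 1L) %/% grid$n_cols) + 1L,
        col = ((e - 1L) %% grid$n_cols) + 1L)
}

#' @rdname electrode_rc
#' @export
electrode_id <- function(row, col, grid) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(is.na(row)) || any(row < 1L) || any(row > grid$n_rows) ||
      any(is.na(col)) || any(col < 1L) || any(col > grid$n_cols))
    stop("(row, col) out of grid range", call. = FALSE)
  (row - 1L) * grid$n_cols + col
}

#' Electrode center positions in micrometers
#'
#' @inheritParams electrode_rc
#' @return Two-column numeric matrix (`x`, `y`) of electrode centers, um.
#' @export
electrode_position <- function(e, grid) {
  rc <- electrode_rc(e, grid)
  cbind(x = (rc[, "col"] - 1) * grid$pitch,
        y = (rc[, "row"] - 1) * grid$pitch)
}

#' Euclidean distance between electrode centers
#'
#' Laterally adjacent electrodes are one pitch apart (81 um on the default
#' grid); diagonal neighbours are `pitch * sqrt(2)`.
#'
#' @param a,b Linear electrode indices (vectorized, recycled).
#' @param grid An `electrode_grid`.
#' @return Distance(s) in micrometers.
#' @examples
#' g <- electrode_grid()
#' electrode_distance(1, 2, g) # 81
#' @export
electrode_distance <- function(a, b, grid) {
  pa <- electrode_position(a, grid)
  pb <- electrode_position(b, grid)
  sqrt((pa[, "x"] - pb[, "x"])^2 + (pa[, "y"] - pb[, "y"])^2)
}

#' Neuron-to-electrode sampling ratio
#'
#' Cultures plated on the active area at the densities used for this kind
#' of preparation carry on the order of 90,000 neurons over 4,096
#' electrodes, i.e. roughly 22 neurons per electrode.
#'
#' @param grid An `electrode_grid`.
#' @param n_neurons Number of neurons on the active area (default 90,000).
#' @return Neurons per electrode (numeric).
#' @export
sampling_ratio <- function(grid, n_neurons = 90000) {
  stopifnot(inherits(grid, "electrode_grid"), n_neurons > 0)
  n_neurons / n_electrodes(grid)
}
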