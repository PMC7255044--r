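#' TCSPC decay cube
#'
#' A `decay_cube` holds the raw data of a FLIM measurement: one photon-count
#' decay histogram per image pixel, i.e. a non-negative integer array indexed
#' `(row, col, channel)`, together with the time calibration of the TCSPC
#' channels. The instrument default is 1024 channels of 19.97 ps.
#'
#' Time channel `k` (1-based) spans the half-open interval
#' `[(k-1) * dt, k * dt)` picoseconds after the start of the recording window.
#'
#' @param counts Non-negative integer array with `dim` of length 3
#'   (`row`, `col`, `channel`).
#' @param channel_width_ps Width of one time channel in picoseconds.
#' @param meta Named list of free-form acquisition metadata (e.g. excitation
#'   wavelength, acquisition time, repetition rate).
#' @return An object of class `decay_cube`.
#' @examples
#' cube <- decay_cube(array(1L, dim = c(2, 2, 8)))
#' total_photons(cube)
#' @export
decay_cube <- function(counts, channel_width_ps = 19.97, meta = list()) {
  if (!is.array(counts) || length(dim(counts)) != 3) {
    abort("`counts` must be a 3D array (row, col, channel).", class = "clusterflim_format_error")
  }
  if (dim(counts)[3] < 1) {
    abort("A decay cube needs at least 1 time channel.", class = "clusterflim_validation_error")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be non-negative integers.", class = "clusterflim_validation_error")
  }
  if (!is.numeric(channel_width_ps) || length(channel_width_ps) != 1 || channel_width_ps <= 0) {
    abort("`channel_width_ps` must be a single positive number.", class = "clusterflim_validation_error")
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, channel_width_ps = as.numeric(channel_width_ps), meta = meta),
    class = "decay_cube"
  )
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_cube> %d x %d pixels, %d time channels of %.4g ps (%d photons)\n",
    d[1], d[2], d[3], x$channel_width_ps, total_photons(x)
  ))
  invisible(x)
}

#' @export
dim.decay_cube <- function(x) dim(x$counts)

#' Total photon count of a decay cube
#'
#' @param cube A [decay_cube()].
#' @return Total number of photons (numeric, exact for integer counts).
#' @export
total_photons <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  sum(as.numeric(cube$counts))
}

#' Per-pixel intensity image
#'
#' Sums each pixel's decay histogram over all time channels. Photons are
#' conserved: `sum(intensity_image(cube)) == total_photons(cube)`.
#'
#' @param cube A [decay_cube()].
#' @return Integer matrix `(row, col)` of per-pixel photon totals.
#' @export
intensity_image <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  d <- dim(cube$counts)
  img <- rowSums(matrix(cube$counts, d[1] * d[2], d[3]))
  matrix(as.integer(img), d[1], d[2])
}

# contiguous rebin groups: n channels -> b bins, last bin absorbs remainder
rebin_groups <- function(n, b) {
  size <- n %/% b
  grp <- rep(seq_len(b), times = c(rep(size, b - 1), n - size * (b - 1)))
  grp
}

#' Rebin the time axis of a decay cube
#'
#' Aggregates the time channels into `b` contiguous bins. When the channel
#' count is not divisible by `b`, the last bin absorbs the remainder so that
#' no photon is dropped. The nominal channel width is scaled by the regular
#' bin size `floor(n_channels / b)`.
#'
#' @param cube A [decay_cube()].
#' @param b Number of output time bins, `1 <= b <= n_channels`.
#' @return A rebinned [decay_cube()] with the same total photon count.
#' @export
rebin_time <- function(cube, b) {
  stopifnot(inherits(cube, "decay_cube"))
  n <- dim(cube$counts)[3]
  if (length(b) != 1 || b < 1 || b > n || b != floor(b)) {
    abort(sprintf("`b` must be an integer in [1, %d].", n), class = "clusterflim_argument_error")
  }
  if (b == n) return(cube)
  d <- dim(cube$counts)
  grp <- rebin_groups(n, b)
  flat <- matrix(cube$counts, d[1] * d[2], d[3])
  out <- t(rowsum(t(flat), grp))
  decay_cube(
    array(as.integer(out), dim = c(d[1], d[2], b)),
    channel_width_ps = cube$channel_width_ps * (n %/% b),
    meta = cube$meta
  )
}
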