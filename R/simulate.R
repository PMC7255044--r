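#' Expected decay curve of a species under the instrument model
#'
#' Samples the multi-exponential decay at channel midpoints, linearly
#' convolves it with the IRF (no repetition-period wrap-around), rescales the
#' decay photons to `total`, and adds a constant background per channel.
#'
#' @param species A [species_def()].
#' @param irf An `irf_model` with `n_channels` entries.
#' @param channel_width_ps Channel width in ps.
#' @param n_channels Number of time channels.
#' @param total Expected number of decay photons (background excluded).
#' @param background Expected background photons per channel.
#' @return Numeric vector of expected counts per channel.
#' @export
expected_curve <- function(species, irf, channel_width_ps = 19.97,
                           n_channels = 1024, total = 1, background = 0) {
  stopifnot(inherits(species, "species_def"), inherits(irf, "irf_model"))
  if (total < 0 || background < 0) {
    abort("`total` and `background` must be non-negative.", class = "clusterflim_argument_error")
  }
  if (length(irf$vector) != n_channels) {
    abort("IRF length must equal `n_channels`.", class = "clusterflim_argument_error")
  }
  t_ns <- (seq_len(n_channels) - 0.5) * channel_width_ps / 1000
  d <- colSums(species$amplitudes *
                 exp(-outer(species$lifetimes_ns, t_ns, function(tau, t) t / tau)))
  conv <- convolve(irf$vector, rev(d), type = "open")[seq_len(n_channels)]
  conv[conv < 0] <- 0 # clip fft round-off
  if (total > 0 && sum(conv) > 0) conv <- conv / sum(conv) * total else conv <- conv * 0
  conv + background
}

#' Draw one pixel's Poisson photon histogram
#'
#' Independent Poisson draw per channel with the expected curve as mean.
#'
#' @param curve Non-negative expected counts per channel.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses the
#'   current RNG stream.
#' @return Integer histogram of the same length.
#' @export
simulate_pixel <- function(curve, seed = NULL) {
  if (any(curve < 0)) abort("`curve` must be non-negative.", class = "clusterflim_argument_error")
  if (!is.null(seed)) set.seed(seed)
  rpois(length(curve), curve)
}

#' Scene layout for a simulated FLIM image
#'
#' @param label_map Integer matrix of species indices (1-based); `NA` marks an
#'   empty pixel containing background only.
#' @param mean_counts Target mean decay photons per occupied pixel.
#' @param background_rate Expected background photons per channel per pixel.
#' @return A `scene_layout`.
#' @export
scene_layout <- function(label_map, mean_counts, background_rate = 0) {
  if (mean_counts < 0 || background_rate < 0) {
    abort("`mean_counts` and `background_rate` must be non-negative.",
          class = "clusterflim_argument_error")
  }
  structure(list(label_map = label_map, mean_counts = mean_counts,
                 background_rate = background_rate),
            class = "scene_layout")
}

#' Equal-area block layout
#'
#' Splits the image into `k` contiguous horizontal bands of (as near as
#' possible) equal area, one species per band - the balanced design used for
#' in-silico sensitivity/specificity validation.
#'
#' @param n_rows,n_cols Image size in pixels.
#' @param k Number of species.
#' @return Integer `label_map` matrix for [scene_layout()].
#' @export
block_layout <- function(n_rows, n_cols, k) {
  band <- rep(seq_len(k), times = diff(floor(seq(0, n_rows, length.out = k + 1))))
  matrix(band, n_rows, n_cols)
}

#' Simulate a ground-truth FLIM image
#'
#' Each occupied pixel is an independent Poisson realization of its species'
#' expected curve at `mean_counts` photons (plus background); empty pixels
#' contain background only. Deterministic for a fixed seed.
#'
#' @param species List of [species_def()].
#' @param layout A [scene_layout()].
#' @param irf An `irf_model`; defaults to a Gaussian IRF with 100 ps FWHM.
#' @param channel_width_ps Channel width in ps.
#' @param n_channels Number of time channels.
#' @param seed Integer seed.
#' @return List with elements `cube` (a [decay_cube()]) and `truth` (the
#'   layout's label map).
#' @export
simulate_image <- function(species, layout, irf = NULL, channel_width_ps = 19.97,
                           n_channels = 1024, seed = 1) {
  stopifnot(inherits(layout, "scene_layout"))
  lm <- layout$label_map
  idx_used <- unique(lm[!is.na(lm)])
  if (length(idx_used) && (min(idx_used) < 1 || max(idx_used) > length(species))) {
    abort("Layout references a species index outside the species list.",
          class = "clusterflim_validation_error")
  }
  if (is.null(irf)) irf <- gaussian_irf(n_channels, channel_width_ps)
  set.seed(seed)
  nr <- nrow(lm); nc <- ncol(lm)
  truth <- as.vector(lm)
  counts <- matrix(0L, nr * nc, n_channels)
  bg <- layout$background_rate
  for (s in seq_along(species)) {
    idx <- which(!is.na(truth) & truth == s)
    if (!length(idx)) next
    mu <- expected_curve(species[[s]], irf, channel_width_ps, n_channels,
                         total = layout$mean_counts, background = bg)
    counts[idx, ] <- matrix(
      rpois(length(idx) * n_channels, rep(mu, each = length(idx))),
      length(idx), n_channels
    )
  }
  empty <- which(is.na(truth))
  if (length(empty) && bg > 0) {
    counts[empty, ] <- rpois(length(empty) * n_channels, bg)
  }
  cube <- decay_cube(array(counts, dim = c(nr, nc, n_channels)),
                     channel_width_ps = channel_width_ps)
  list(cube = cube, truth = lm)
}
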