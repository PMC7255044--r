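#' Gaussian instrument response function
#'
#' Discretizes a Gaussian IRF onto the TCSPC channel grid by integrating the
#' density over each half-open channel `[(k-1) dt, k dt)`, then normalizing to
#' unit sum. `sigma = fwhm / (2 sqrt(2 ln 2))`. The instrument the package
#' emulates has an IRF narrower than 100 ps (FWHM), which is the default.
#'
#' @param n_channels Number of time channels.
#' @param channel_width_ps Channel width in ps.
#' @param t0_ps Peak position in ps (must lie inside the recording window).
#' @param fwhm_ps Full width at half maximum in ps.
#' @return An `irf_model` (list with `kind`, `fwhm_ps`, `t0_ps`, `vector`).
#' @export
gaussian_irf <- function(n_channels, channel_width_ps = 19.97, t0_ps = 1000,
                         fwhm_ps = 100) {
  if (fwhm_ps <= 0) abort("`fwhm_ps` must be positive.", class = "clusterflim_argument_error")
  if (t0_ps < 0 || t0_ps >= n_channels * channel_width_ps) {
    abort("`t0_ps` must lie within the recording window.", class = "clusterflim_argument_error")
  }
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  edges <- seq(0, n_channels) * channel_width_ps
  v <- diff(pnorm(edges, mean = t0_ps, sd = sigma))
  if (sum(v) <= 0) {
    # fwhm far below channel width: all mass in the channel containing t0
    v <- numeric(n_channels)
    v[floor(t0_ps / channel_width_ps) + 1] <- 1
  }
  irf_model(v / sum(v), kind = "gaussian", fwhm_ps = fwhm_ps, t0_ps = t0_ps)
}

#' Construct an IRF model from a measured per-channel vector
#'
#' @param vector Non-negative per-channel weights; normalized to unit sum.
#' @param kind `"measured"` or `"gaussian"`.
#' @param fwhm_ps,t0_ps Optional descriptive parameters.
#' @return An `irf_model`.
#' @export
irf_model <- function(vector, kind = "measured", fwhm_ps = NA_real_, t0_ps = NA_real_) {
  if (any(vector < 0) || sum(vector) <= 0) {
    abort("IRF vector must be non-negative with positive sum.", class = "clusterflim_argument_error")
  }
  structure(
    list(kind = kind, fwhm_ps = fwhm_ps, t0_ps = t0_ps, vector = vector / sum(vector)),
    class = "irf_model"
  )
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("<irf_model> %s, %d channels, fwhm %.3g ps, t0 %.4g ps\n",
              x$kind, length(x$vector), x$fwhm_ps, x$t0_ps))
  invisible(x)
}
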