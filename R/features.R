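#' Build per-pixel decay features for clustering
#'
#' Pixels with fewer than `min_counts` total photons are masked and do not
#' contribute (default 10 counts/px). Remaining decay histograms are rebinned
#' to `b` contiguous time bins and normalized to unit area, so that clustering
#' is driven by decay shape, not pixel brightness.
#'
#' @param cube A [decay_cube()].
#' @param b Number of feature time bins (default 16; see the methods vignette
#'   for the shot-noise rationale).
#' @param min_counts Minimum photons per pixel to enter the analysis.
#' @param normalize Normalize each feature row to unit area (default `TRUE`);
#'   `FALSE` clusters raw rebinned counts.
#' @return A `feature_matrix`: list with `features` (rows = unmasked pixels),
#'   `pixel_index` (row/col per feature row), `keep` (logical mask in pixel
#'   order), `b`, `min_counts`.
#' @export
build_features <- function(cube, b = 16, min_counts = 10, normalize = TRUE) {
  stopifnot(inherits(cube, "decay_cube"))
  d <- dim(cube$counts)
  n <- d[3]
  if (b > n) abort("`b` must not exceed the number of time channels.", class = "clusterflim_argument_error")
  if (min_counts < 0) abort("`min_counts` must be >= 0.", class = "clusterflim_argument_error")
  flat <- matrix(cube$counts, d[1] * d[2], n)
  tot <- rowSums(flat)
  keep <- tot >= min_counts & tot > 0
  if (!any(keep)) {
    abort("All pixels fall below `min_counts`; lower the threshold.",
          class = "clusterflim_empty_feature_error")
  }
  grp <- rebin_groups(n, b)
  feat <- t(rowsum(t(flat[keep, , drop = FALSE]), grp))
  if (normalize) feat <- feat / tot[keep]
  pix <- arrayInd(which(keep), .dim = c(d[1], d[2]))
  structure(
    list(features = feat, pixel_index = pix, keep = keep,
         dim = c(d[1], d[2]), b = b, min_counts = min_counts,
         normalized = normalize),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d bins (min_counts %d, %d masked)\n",
              nrow(x$features), x$b, x$min_counts, sum(!x$keep)))
  invisible(x)
}

#' Euclidean distance between two feature vectors
#'
#' The similarity measure of the clustering:
#' `D = sqrt(sum_j (x_j - c_j)^2)`.
#'
#' @param x,c_vec Numeric vectors of equal length.
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(x, c_vec) {
  if (length(x) != length(c_vec)) {
    abort("Vectors must have equal dimension.", class = "clusterflim_argument_error")
  }
  sqrt(sum((x - c_vec)^2))
}
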