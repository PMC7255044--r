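#' Automatic colocalization threshold search
#'
#' Costes-style threshold search for a two-channel intensity pair: an
#' orthogonal (major-axis) regression `B ~ a * A + b` is fitted through the
#' joint intensity distribution, then the candidate threshold `T_A` is walked
#' down the intensity quantiles of channel A (with `T_B = a * T_A + b`) until
#' the Pearson correlation of the pixels below both thresholds drops to or
#' below zero.
#'
#' @param img_a,img_b Non-negative intensity matrices of equal shape.
#' @param steps Number of quantile steps walked (default 100).
#' @return List with `t_a`, `t_b`, `slope`, `intercept`, and `pearson_below`
#'   (the sub-threshold correlation at acceptance).
#' @export
costes_threshold <- function(img_a, img_b, steps = 100) {
  a <- as.numeric(img_a); b <- as.numeric(img_b)
  if (length(a) != length(b)) abort("Images must have equal shape.", class = "clusterflim_argument_error")
  if (any(a < 0) || any(b < 0)) abort("Intensities must be non-negative.", class = "clusterflim_argument_error")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Constant image: the orthogonal regression is undefined.",
          class = "clusterflim_threshold_error")
  }
  # major-axis (orthogonal) regression via the covariance eigenvector
  cv <- cov(cbind(a, b))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  slope <- ev[2] / ev[1]
  intercept <- mean(b) - slope * mean(a)
  # walk thresholds down one intensity quantile per step
  cand <- rev(quantile(a, probs = seq(0, 1, length.out = steps + 1), names = FALSE))
  t_a <- min(a); t_b <- slope * t_a + intercept
  r_below <- NA_real_
  for (ta in cand) {
    tb <- slope * ta + intercept
    below <- a < ta & b < tb
    if (sum(below) < 3) next
    if (sd(a[below]) == 0 || sd(b[below]) == 0) next
    r <- cor(a[below], b[below])
    t_a <- ta; t_b <- tb; r_below <- r
    if (!is.na(r) && r <= 0) break
  }
  list(t_a = t_a, t_b = t_b, slope = slope, intercept = intercept,
       pearson_below = r_below)
}

#' Manders colocalization coefficients
#'
#' Thresholded Manders coefficients between two spectral channels. With
#' above-threshold masks `A+ = {A > T_A}` and `B+ = {B > T_B}`:
#' `M1 = sum(A over A+ & B+) / sum(A over A+)` (the fraction of channel A's
#' above-threshold intensity that overlaps channel B), and `M2` with the
#' roles swapped. Both lie in \[0, 1\]; swapping the channels swaps M1 and
#' M2; multiplying either channel by a positive scalar leaves both unchanged.
#'
#' @param img_a,img_b Non-negative intensity matrices of equal shape.
#' @param t_a,t_b Channel thresholds; `NULL` runs [costes_threshold()].
#' @return A `coloc_result`: list with `m1`, `m2`, `t_a`, `t_b`,
#'   `pearson_below`.
#' @export
manders <- function(img_a, img_b, t_a = NULL, t_b = NULL) {
  a <- as.numeric(img_a); b <- as.numeric(img_b)
  if (length(a) != length(b)) abort("Images must have equal shape.", class = "clusterflim_argument_error")
  pearson_below <- NA_real_
  if (is.null(t_a) || is.null(t_b)) {
    th <- costes_threshold(img_a, img_b)
    t_a <- th$t_a; t_b <- th$t_b; pearson_below <- th$pearson_below
  }
  if (t_a > max(a) || t_b > max(b)) {
    abort("Thresholds exceed the image intensity range.", class = "clusterflim_argument_error")
  }
  a_mask <- a > t_a
  b_mask <- b > t_b
  den1 <- sum(a[a_mask]); den2 <- sum(b[b_mask])
  if (den1 <= 0 || den2 <= 0) {
    abort("No above-threshold signal in one channel; Manders coefficients undefined.",
          class = "clusterflim_undefined_result_error")
  }
  structure(
    list(m1 = sum(a[a_mask & b_mask]) / den1,
         m2 = sum(b[a_mask & b_mask]) / den2,
         t_a = t_a, t_b = t_b, pearson_below = pearson_below),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> M1 = %.3f, M2 = %.3f (T_A = %.4g, T_B = %.4g)\n",
              x$m1, x$m2, x$t_a, x$t_b))
  invisible(x)
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(m1 = x$m1, m2 = x$m2, t_a = x$t_a, t_b = x$t_b,
         pearson_below = x$pearson_below)
}
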