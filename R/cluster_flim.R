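#' Default cluster palette
#'
#' Cyan, yellow, red for the first three clusters (ascending mean lifetime),
#' then further distinct colors.
#'
#' @param k Number of clusters.
#' @return Character vector of `k` colors.
#' @export
default_palette <- function(k) {
  base <- c("#00FFFF", "#FFFF00", "#FF0000", "#00FF00", "#FF00FF",
            "#0000FF", "#FF8000", "#8000FF")
  if (k <= length(base)) base[seq_len(k)] else grDevices::rainbow(k)
}

#' Accumulate per-cluster fluorescence lifetime signatures
#'
#' The FLS of a cluster is the channel-wise integer sum of the decay
#' histograms of all pixels belonging to that cluster, at full (unrebinned)
#' channel resolution. Summing the FLS over all clusters reproduces the total
#' photon count of the unmasked pixels exactly.
#'
#' @param cube A [decay_cube()].
#' @param labels Integer cluster label per unmasked pixel.
#' @param keep Logical mask in pixel (column-major) order; `sum(keep)` must
#'   equal `length(labels)`.
#' @param k Number of clusters (defaults to `max(labels)`).
#' @return Integer matrix `k x n_channels`; row `j` is cluster `j`'s FLS.
#' @export
accumulate_fls <- function(cube, labels, keep = NULL, k = max(labels)) {
  stopifnot(inherits(cube, "decay_cube"))
  d <- dim(cube$counts)
  flat <- matrix(cube$counts, d[1] * d[2], d[3])
  if (is.null(keep)) keep <- rep(TRUE, nrow(flat))
  if (sum(keep) != length(labels)) {
    abort("`labels` must have one entry per unmasked pixel.", class = "clusterflim_argument_error")
  }
  fls <- matrix(0, k, d[3])
  got <- rowsum(flat[keep, , drop = FALSE], labels)
  fls[as.integer(rownames(got)), ] <- got
  storage.mode(fls) <- "double" # may exceed .Machine$integer.max in theory
  fls
}

# fast moment estimate of the mean lifetime of an FLS (ns): background from
# the pre-pulse window, then first moment of background-subtracted counts
# after the peak channel. Used only to rank clusters for palette assignment.
tau_moment <- function(fls, channel_width_ps) {
  n <- length(fls)
  bg <- mean(fls[seq_len(max(1, floor(0.03 * n)))])
  y <- pmax(fls - bg, 0)
  peak <- which.max(y)
  idx <- peak:n
  w <- y[idx]
  if (sum(w) <= 0) return(0)
  sum((idx - peak) * w) / sum(w) * channel_width_ps / 1000
}

#' Cluster a FLIM image into fluorescence lifetime signatures
#'
#' The full fitting-free pipeline: per-pixel features ([build_features()]),
#' k-means partitioning ([kmeans_partition()]), and photon accumulation into
#' per-cluster FLSs ([accumulate_fls()]). Clusters are re-indexed by ascending
#' mean lifetime of their FLS (fast moment estimate) before palette
#' assignment, so cluster 1 is always the fastest decay (cyan by default).
#'
#' @param cube A [decay_cube()].
#' @param k Number of clusters.
#' @param b Feature time bins (default 16).
#' @param min_counts Pixel mask threshold in photons (default 10).
#' @param seed Integer seed for the k-means restarts.
#' @param restarts k-means restarts (default 10).
#' @param normalize Cluster unit-area decay shapes (default `TRUE`).
#' @param palette Colors per cluster, ascending lifetime order.
#' @return A `cluster_flim` object: `labels` (matrix, `NA` = masked),
#'   `centers`, `fls` (`k x n_channels`), `member_counts`, `fractions`
#'   (photon-weighted), `tau_ns` (moment estimates), `palette`, `inertia`,
#'   `converged`, `channel_width_ps`.
#' @examples
#' panel <- validation_panel(4)
#' sim <- simulate_image(panel, scene_layout(block_layout(24, 24, 4), 500),
#'                       n_channels = 256, seed = 1)
#' res <- cluster_flim(sim$cube, k = 4)
#' tidy(res)
#' @export
cluster_flim <- function(cube, k, b = 16, min_counts = 10, seed = 1,
                         restarts = 10, normalize = TRUE, palette = NULL) {
  fm <- build_features(cube, b = b, min_counts = min_counts, normalize = normalize)
  km <- kmeans_partition(fm, k, seed = seed, restarts = restarts)
  fls <- accumulate_fls(cube, km$labels, fm$keep, k = k)
  tau <- apply(fls, 1, tau_moment, channel_width_ps = cube$channel_width_ps)
  ord <- order(tau)
  relabel <- match(seq_len(k), ord) # old label -> new rank
  labels_vec <- relabel[km$labels]
  fls <- fls[ord, , drop = FALSE]
  centers <- km$centers[ord, , drop = FALSE]
  tau <- tau[ord]
  d <- fm$dim
  label_map <- matrix(NA_integer_, d[1], d[2])
  label_map[fm$keep] <- labels_vec
  member_counts <- tabulate(labels_vec, nbins = k)
  photons <- rowSums(fls)
  if (is.null(palette)) palette <- default_palette(k)
  structure(
    list(labels = label_map, centers = centers, fls = fls,
         member_counts = member_counts,
         fractions = photons / sum(photons),
         tau_ns = tau, palette = palette,
         inertia = km$inertia, converged = km$converged,
         channel_width_ps = cube$channel_width_ps,
         b = b, min_counts = min_counts, k = k, seed = seed),
    class = "cluster_flim"
  )
}

#' @export
print.cluster_flim <- function(x, ...) {
  cat(sprintf("<cluster_flim> k = %d on %d x %d pixels (%d masked)\n",
              x$k, nrow(x$labels), ncol(x$labels), sum(is.na(x$labels))))
  print(tidy(x))
  invisible(x)
}

#' @describeIn cluster_flim Per-cluster summary: pixels, photons,
#'   photon-weighted fraction, mean-lifetime estimate, color.
#' @param x A `cluster_flim` object.
#' @param ... Unused.
#' @method tidy cluster_flim
#' @export
tidy.cluster_flim <- function(x, ...) {
  tibble(
    cluster = seq_len(x$k),
    n_pixels = x$member_counts,
    photons = rowSums(x$fls),
    fraction = x$fractions,
    tau_mean_ns = x$tau_ns,
    color = x$palette[seq_len(x$k)]
  )
}

#' @describeIn cluster_flim One-row fit summary.
#' @method glance cluster_flim
#' @export
glance.cluster_flim <- function(x, ...) {
  tibble(
    k = x$k,
    n_unmasked = sum(!is.na(x$labels)),
    n_masked = sum(is.na(x$labels)),
    inertia = x$inertia,
    converged = x$converged
  )
}

#' Photon- or pixel-weighted cluster fractions
#'
#' Relative cluster concentrations, expressed as each cluster's share of the
#' total accumulated intensity (default) or of the unmasked pixel count.
#'
#' @param result A `cluster_flim` object.
#' @param weight `"photon"` (default) or `"pixel"`.
#' @return Numeric vector summing to 1.
#' @export
quantify_clusters <- function(result, weight = c("photon", "pixel")) {
  weight <- match.arg(weight)
  stopifnot(inherits(result, "cluster_flim"))
  w <- if (weight == "photon") rowSums(result$fls) else result$member_counts
  w / sum(w)
}

#' False-color rendering of a clustered FLIM image
#'
#' Every pixel is painted its cluster's palette color; masked pixels are
#' painted `mask_color` (white by default).
#'
#' @param result A `cluster_flim` object.
#' @param mask_color Color for masked pixels.
#' @return `n_rows x n_cols x 3` array of RGB values in \[0, 1\].
#' @export
render_false_color <- function(result, mask_color = "white") {
  stopifnot(inherits(result, "cluster_flim"))
  cols <- c(result$palette[seq_len(result$k)], mask_color)
  idx <- result$labels
  idx[is.na(idx)] <- result$k + 1L
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(idx), ncol(idx), 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, idx], nrow(idx), ncol(idx))
  out
}

#' Match clusters of one image to a reference image
#'
#' Clusters are identified across images of a series by minimal Euclidean
#' distance between their unit-area FLSs, as a one-to-one assignment
#' (exhaustive over permutations, optimal for k <= 8). Needed for consistent
#' coloring and fraction tracking along a time series.
#'
#' @param result,reference `cluster_flim` objects with equal `k`.
#' @return Integer vector `m`: cluster `j` of `result` corresponds to
#'   reference cluster `m[j]`.
#' @export
match_clusters <- function(result, reference) {
  stopifnot(inherits(result, "cluster_flim"), inherits(reference, "cluster_flim"))
  if (result$k != reference$k) {
    abort("Cluster counts differ between images.", class = "clusterflim_argument_error")
  }
  a <- result$fls / rowSums(result$fls)
  b <- reference$fls / rowSums(reference$fls)
  cost <- dist2_to_centers(a, b)
  best_assignment(cost)
}

# minimal-cost one-to-one assignment by exhaustive permutation search (k <= 8)
best_assignment <- function(cost) {
  k <- nrow(cost)
  if (k > 8) abort("Assignment search supports k <= 8.", class = "clusterflim_argument_error")
  perms <- permutations(seq_len(k))
  costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(k), p)]), numeric(1))
  perms[[which.min(costs)]]
}

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(permutations(v[-i]), function(p) c(v[i], p))
  }))
}

#' Scan the number of clusters
#'
#' The method does not prescribe a rule for k; this helper reports, per
#' candidate k, the k-means inertia, the mean silhouette width (on a pixel
#' subsample), and the seed-stability of the partition (adjusted Rand index
#' between two seeds).
#'
#' @param cube A [decay_cube()].
#' @param ks Candidate cluster counts.
#' @param b,min_counts,restarts See [cluster_flim()].
#' @param seed Base seed; stability compares `seed` and `seed + 1`.
#' @param max_silhouette_pixels Subsample cap for the silhouette computation.
#' @return A tibble with columns `k`, `inertia`, `silhouette`, `ari_stability`.
#' @export
scan_k <- function(cube, ks = 2:6, b = 16, min_counts = 10, restarts = 10,
                   seed = 1, max_silhouette_pixels = 2000) {
  fm <- build_features(cube, b = b, min_counts = min_counts)
  x <- fm$features
  set.seed(seed)
  sub <- if (nrow(x) > max_silhouette_pixels) sample.int(nrow(x), max_silhouette_pixels) else seq_len(nrow(x))
  dsub <- stats::dist(x[sub, , drop = FALSE])
  purrr::map_dfr(ks, function(k) {
    km1 <- kmeans_partition(fm, k, seed = seed, restarts = restarts)
    km2 <- kmeans_partition(fm, k, seed = seed + 1, restarts = restarts)
    sil <- if (k > 1) {
      mean(cluster::silhouette(km1$labels[sub], dsub)[, "sil_width"])
    } else NA_real_
    tibble(k = k, inertia = km1$inertia, silhouette = sil,
           ari_stability = adjusted_rand_index(km1$labels, km2$labels))
  })
}
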