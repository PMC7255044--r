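#' Optimal matching of predicted clusters to truth classes
#'
#' k-means labels are arbitrary; scoring against ground truth requires the
#' one-to-one cluster-to-class assignment that maximizes the total diagonal of
#' the confusion table. Exhaustive over all permutations (optimal, k <= 8).
#'
#' @param pred Integer predicted labels in `1..k`.
#' @param truth Integer truth labels in `1..k`, same length.
#' @param k Number of classes (defaults to the larger max of both).
#' @return Integer mapping `m`: predicted label `j` maps to class `m[j]`.
#' @export
match_labels <- function(pred, truth, k = max(c(pred, truth))) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have equal length.", class = "clusterflim_argument_error")
  }
  tab <- table(factor(pred, levels = seq_len(k)), factor(truth, levels = seq_len(k)))
  # maximize diagonal == minimize negated counts
  best_assignment(-unclass(tab))
}

#' Per-class confusion rates against ground truth
#'
#' One-vs-rest confusion per class after applying a cluster-to-class mapping:
#' sensitivity (hit rate) `TP / (TP + FN)` and specificity (correct rejection
#' rate) `TN / (TN + FP)`, plus macro averages.
#'
#' @param pred Integer predicted labels.
#' @param truth Integer truth labels.
#' @param mapping Mapping from [match_labels()]; identity if `NULL`.
#' @return A `confusion_summary`: tibble with one row per class (`class`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`) and attributes
#'   `macro_sensitivity`, `macro_specificity`.
#' @export
confusion_rates <- function(pred, truth, mapping = NULL) {
  k <- max(c(pred, truth))
  if (is.null(mapping)) mapping <- seq_len(k)
  mapped <- mapping[pred]
  n <- length(pred)
  rows <- purrr::map_dfr(seq_len(k), function(cl) {
    tp <- sum(mapped == cl & truth == cl)
    fn <- sum(mapped != cl & truth == cl)
    fp <- sum(mapped == cl & truth != cl)
    tn <- n - tp - fn - fp
    tibble(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  structure(rows,
            macro_sensitivity = mean(rows$sensitivity, na.rm = TRUE),
            macro_specificity = mean(rows$specificity, na.rm = TRUE),
            class = c("confusion_summary", class(rows)))
}

#' Macro-averaged sensitivity and specificity
#'
#' @param x A `confusion_summary`.
#' @return Named numeric vector with `sensitivity` and `specificity`.
#' @export
macro_rates <- function(x) {
  stopifnot(inherits(x, "confusion_summary"))
  c(sensitivity = attr(x, "macro_sensitivity"),
    specificity = attr(x, "macro_specificity"))
}

#' Score one simulated image
#'
#' Simulates a balanced block-layout image from the species list, runs the
#' clustering with `k = length(species)`, optimally matches labels to truth,
#' and returns macro rates.
#'
#' @param species List of [species_def()].
#' @param mean_counts Mean decay photons per pixel.
#' @param seed Integer seed (simulation and clustering).
#' @param image_dim Image size `c(rows, cols)`.
#' @param n_channels,channel_width_ps Instrument grid.
#' @param b,min_counts Clustering parameters; see [cluster_flim()].
#' @return Tibble with one row: `mean_counts`, `seed`, `sensitivity`,
#'   `specificity`, `n_masked`.
#' @export
score_simulation <- function(species, mean_counts, seed = 1,
                             image_dim = c(128, 128), n_channels = 1024,
                             channel_width_ps = 19.97, b = 16, min_counts = 10) {
  k <- length(species)
  layout <- scene_layout(block_layout(image_dim[1], image_dim[2], k), mean_counts)
  sim <- simulate_image(species, layout, n_channels = n_channels,
                        channel_width_ps = channel_width_ps, seed = seed)
  res <- cluster_flim(sim$cube, k = k, b = b, min_counts = min_counts, seed = seed)
  keep <- !is.na(res$labels)
  pred <- res$labels[keep]
  truth <- sim$truth[keep]
  cm <- confusion_rates(pred, truth, match_labels(pred, truth, k))
  mr <- macro_rates(cm)
  tibble(mean_counts = mean_counts, seed = seed,
         sensitivity = mr[["sensitivity"]], specificity = mr[["specificity"]],
         n_masked = sum(!keep))
}

#' Sensitivity/specificity titration versus photon budget
#'
#' Reproduces the in-silico validation design: for each mean counts-per-pixel
#' level, simulate `replicates` balanced block-layout images, cluster with
#' `k = length(species)`, and score macro sensitivity and specificity against
#' the ground-truth labels. Deterministic per seed.
#'
#' @param species List of [species_def()], e.g. [validation_panel()].
#' @param counts_levels Mean counts-per-pixel levels (e.g. `c(40, 90, 120,
#'   170)`).
#' @param replicates Replicate images per level.
#' @param seed Base seed; replicate `r` at level `i` uses
#'   `seed + 1000 * i + r`.
#' @param ... Passed to [score_simulation()].
#' @return A `titration_curve` tibble: one row per (level, replicate) with
#'   `sensitivity` and `specificity`; summarize with [summary()] or plot with
#'   [autoplot()].
#' @export
titration_curve <- function(species, counts_levels, replicates = 5, seed = 1, ...) {
  if (any(counts_levels <= 0)) abort("Counts levels must be positive.", class = "clusterflim_argument_error")
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "clusterflim_argument_error")
  res <- purrr::map_dfr(seq_along(counts_levels), function(i) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      score_simulation(species, counts_levels[i], seed = seed + 1000L * i + r, ...) %>%
        mutate(replicate = r, .after = "mean_counts")
    })
  })
  structure(res, class = c("titration_curve", class(res)))
}

#' @export
summary.titration_curve <- function(object, ...) {
  object %>%
    group_by(.data$mean_counts) %>%
    summarise(
      sensitivity_mean = mean(.data$sensitivity),
      sensitivity_sd = sd(.data$sensitivity),
      specificity_mean = mean(.data$specificity),
      specificity_sd = sd(.data$specificity),
      .groups = "drop"
    )
}

#' @export
autoplot.titration_curve <- function(object, ...) {
  s <- summary(object) %>%
    tidyr::pivot_longer(-"mean_counts",
                        names_to = c("rate", ".value"), names_sep = "_")
  ggplot(s, aes(x = .data$mean_counts, y = .data$mean, color = .data$rate)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  width = 2) +
    labs(x = "mean counts per pixel", y = "rate", color = NULL) +
    theme_minimal()
}
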