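#' Assessment rule for the automated workflow
#'
#' A verdict rule on one cluster's intensity fraction, e.g. "at least 90% of
#' the signal in the red (slowest) cluster" as a read-out for lysosomal
#' trapping.
#'
#' @param cluster Cluster addressed by lifetime rank (integer; 1 = fastest)
#'   or by palette role name (`"cyan"`, `"yellow"`, `"red"` for ranks 1-3).
#' @param threshold Fraction threshold in \[0, 1\].
#' @param direction `"at_least"` or `"at_most"`.
#' @param verdict_labels Labels for (rule met, rule not met).
#' @return An `assessment_rule`.
#' @export
assessment_rule <- function(cluster = "red", threshold = 0.9,
                            direction = c("at_least", "at_most"),
                            verdict_labels = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (threshold < 0 || threshold > 1) {
    abort("`threshold` must be in [0, 1].", class = "clusterflim_config_error")
  }
  if (is.character(cluster)) {
    rank <- match(cluster, c("cyan", "yellow", "red"))
    if (is.na(rank)) abort("Named clusters must be cyan, yellow or red.", class = "clusterflim_config_error")
    cluster <- rank
  }
  structure(list(cluster = as.integer(cluster), threshold = threshold,
                 direction = direction, verdict_labels = verdict_labels),
            class = "assessment_rule")
}

apply_rule <- function(rule, fractions) {
  if (rule$cluster > length(fractions)) {
    abort(sprintf("Rule references cluster %d but only %d clusters exist.",
                  rule$cluster, length(fractions)),
          class = "clusterflim_config_error")
  }
  f <- fractions[rule$cluster]
  met <- if (rule$direction == "at_least") f >= rule$threshold else f <= rule$threshold
  list(fraction = f, met = met,
       verdict = rule$verdict_labels[if (met) 1 else 2])
}

#' Run the automated assessment workflow
#'
#' The full pipeline: every input cube is clustered, clusters are matched
#' across the series to a reference image (by FLS similarity) so that cluster
#' identities and colors stay consistent, intensity fractions are quantified
#' per image, and the assessment rule is applied. The overall verdict is the
#' final (last image's) assessment, matching the use of the rule as an
#' end-point read-out. Fully deterministic given the seed.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `inputs` (list of [decay_cube()] objects or TIFF paths, >= 1), `k`,
#'   optional `b`, `min_counts`, `seed`, `palette`, `reference` (index of the
#'   reference image, default 1), `rule` (an [assessment_rule()] or a list of
#'   its arguments), and optional `labels` (per-image names).
#' @return A `workflow_report`: `fractions` (tibble image x cluster),
#'   `verdicts` (tibble), `verdict` (overall), `results` (the per-image
#'   `cluster_flim` objects), `provenance`.
#' @seealso [write_report()]
#' @export
run_workflow <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$inputs) || length(config$inputs) == 0) {
    abort("Config must list at least one input cube.", class = "clusterflim_config_error")
  }
  if (is.null(config$k)) abort("Config must give `k`.", class = "clusterflim_config_error")
  paths <- vapply(config$inputs, function(x) if (is.character(x)) x else NA_character_, character(1))
  missing <- paths[!is.na(paths) & !file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("Input file(s) not found: %s", paste(missing, collapse = ", ")),
          class = "clusterflim_io_error")
  }
  cubes <- lapply(config$inputs, function(x) if (is.character(x)) read_cube(x) else x)
  b <- config$b %||% 16
  min_counts <- config$min_counts %||% 10
  seed <- config$seed %||% 1
  k <- config$k
  rule <- config$rule %||% assessment_rule()
  if (!inherits(rule, "assessment_rule")) rule <- do.call(assessment_rule, rule)
  labels <- config$labels %||% sprintf("image%02d", seq_along(cubes))
  ref_idx <- config$reference %||% 1L

  results <- lapply(cubes, cluster_flim, k = k, b = b, min_counts = min_counts,
                    seed = seed, palette = config$palette %||% NULL)
  # re-index every image's clusters to the reference image's identities
  ref <- results[[ref_idx]]
  results <- lapply(results, function(res) {
    map <- match_clusters(res, ref)
    reorder_clusters(res, order(map))
  })

  fractions <- purrr::map_dfr(seq_along(results), function(i) {
    fr <- quantify_clusters(results[[i]])
    tibble(image = labels[i], cluster = seq_len(k), fraction = fr)
  })
  verdicts <- purrr::map_dfr(seq_along(results), function(i) {
    v <- apply_rule(rule, quantify_clusters(results[[i]]))
    tibble(image = labels[i], fraction = v$fraction, met = v$met, verdict = v$verdict)
  })
  provenance <- list(
    package_version = as.character(utils::packageVersion("clusterflim")),
    seed = seed, k = k, b = b, min_counts = min_counts,
    config_digest = rlang::hash(list(k = k, b = b, min_counts = min_counts,
                                     seed = seed, rule = unclass(rule),
                                     labels = labels, n_inputs = length(cubes)))
  )
  structure(
    list(fractions = fractions, verdicts = verdicts,
         verdict = verdicts$verdict[nrow(verdicts)],
         rule = rule, results = results, labels = labels,
         provenance = provenance),
    class = "workflow_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# permute cluster indices of a cluster_flim result: new index j holds the
# cluster previously at ord[j]
reorder_clusters <- function(res, ord) {
  relabel <- match(seq_len(res$k), ord)
  res$labels[] <- relabel[res$labels]
  res$centers <- res$centers[ord, , drop = FALSE]
  res$fls <- res$fls[ord, , drop = FALSE]
  res$member_counts <- res$member_counts[ord]
  res$fractions <- res$fractions[ord]
  res$tau_ns <- res$tau_ns[ord]
  res
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("<workflow_report> %d image(s), overall verdict: %s\n",
              length(x$results), x$verdict))
  print(x$verdicts)
  invisible(x)
}

#' Write workflow outputs to a directory
#'
#' Emits `report.json` (verdicts + provenance), `fractions.csv`, one
#' `fls_<image>.csv` per image (cluster, channel, counts), and one false-color
#' `falsecolor_<image>.png` per image. Identical config and seed produce
#' byte-identical CSV/JSON output.
#'
#' @param report A `workflow_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "workflow_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(verdict = report$verdict,
         rule = unclass(report$rule),
         verdicts = report$verdicts,
         provenance = report$provenance),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  utils::write.csv(report$fractions, file.path(dir, "fractions.csv"), row.names = FALSE)
  for (i in seq_along(report$results)) {
    res <- report$results[[i]]
    fls_long <- tibble(
      cluster = rep(seq_len(res$k), each = ncol(res$fls)),
      channel = rep(seq_len(ncol(res$fls)), times = res$k),
      counts = as.vector(t(res$fls))
    )
    utils::write.csv(fls_long, file.path(dir, sprintf("fls_%s.csv", report$labels[i])),
                     row.names = FALSE)
    png::writePNG(render_false_color(res),
                  file.path(dir, sprintf("falsecolor_%s.png", report$labels[i])))
  }
  invisible(dir)
}
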