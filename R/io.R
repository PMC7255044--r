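#' Read a decay cube from disk
#'
#' The on-disk interchange format is a multi-page TIFF (one 16-bit grayscale
#' page per time channel) with a JSON sidecar (`<path>.json`) carrying the
#' channel width and free-form metadata. When the sidecar is missing, the
#' instrument default of 19.97 ps per channel is assumed.
#'
#' @param path Path to the TIFF file.
#' @param format_hint One of `"tiff"` or `"auto"` (resolved from the file
#'   extension). `"hdf5"` and `"sdt"` are recognised but not supported by this
#'   build and raise an informative error.
#' @return A [decay_cube()].
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format_hint = c("auto", "tiff", "hdf5", "sdt")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read decay cube: file '%s' does not exist.", path),
          class = "clusterflim_io_error")
  }
  fmt <- if (format_hint == "auto") guess_format(path) else format_hint
  if (fmt %in% c("hdf5", "sdt")) {
    abort(sprintf("Container format '%s' is not supported by this build; use multi-page TIFF with a JSON sidecar.", fmt),
          class = "clusterflim_format_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) {
    abort(sprintf("'%s' has %d page(s); a decay cube needs one page per time channel (>= 2).", path, length(pages)),
          class = "clusterflim_format_error")
  }
  counts <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  sidecar <- paste0(path, ".json")
  cw <- 19.97
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$channel_width_ps)) cw <- as.numeric(side$channel_width_ps)
    if (!is.null(side$meta)) meta <- as.list(side$meta)
  }
  decay_cube(counts, channel_width_ps = cw, meta = meta)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    h5 = , hdf5 = "hdf5",
    sdt = "sdt",
    abort(sprintf("Cannot infer the container format from extension '.%s'.", ext),
          class = "clusterflim_format_error")
  )
}

#' Write a decay cube to disk
#'
#' Writes one 16-bit grayscale TIFF page per time channel, plus a JSON sidecar
#' (`<path>.json`) with `channel_width_ps` and the metadata list. Counts above
#' 65535 do not fit a 16-bit TIFF sample and raise an overflow error; rebin
#' the time axis or split the acquisition instead.
#'
#' @param cube A [decay_cube()].
#' @param path Output path (`.tiff`).
#' @param format Only `"tiff"` is supported by this build.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("tiff", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "decay_cube"))
  if (format == "hdf5") {
    abort("HDF5 output is not supported by this build; use format = 'tiff'.",
          class = "clusterflim_format_error")
  }
  if (max(cube$counts) > 65535L) {
    abort("Counts exceed the 16-bit TIFF sample range (65535); rebin or split the data.",
          class = "clusterflim_overflow_error")
  }
  d <- dim(cube$counts)
  pages <- lapply(seq_len(d[3]), function(k) cube$counts[, , k] / 65535)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none"),
    error = function(e) abort(sprintf("Cannot write '%s': %s", path, conditionMessage(e)),
                              class = "clusterflim_io_error")
  )
  jsonlite::write_json(
    list(channel_width_ps = cube$channel_width_ps, meta = cube$meta),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
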