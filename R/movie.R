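#' Construct a movie bundle
#'
#' @param frames 3D numeric array [y, x, t] of fluorescence counts.
#' @param timestamps Frame times in seconds.
#' @param planeIndex Integer imaging-plane index per frame (default all 1).
#' @param stimIntervals Two-column matrix of (start, end) stimulation
#'   times in seconds; zero rows for an unstimulated recording.
#' @param pixelRate Imaging pixel clock in Hz (default 8.2e6).
#' @param scanModel "resonant" (default) or "linear".
#' @return A [MovieBundle-class].
#' @export
movieBundle <- function(frames, timestamps,
                        planeIndex = rep(1L, length(timestamps)),
                        stimIntervals = matrix(numeric(0), 0, 2),
                        pixelRate = 8.2e6,
                        scanModel = c("resonant", "linear")) {
  scanModel <- match.arg(scanModel)
  stimIntervals <- matrix(as.numeric(stimIntervals), ncol = 2)
  new("MovieBundle", frames = frames, timestamps = as.numeric(timestamps),
      planeIndex = as.integer(planeIndex), stimIntervals = stimIntervals,
      pixelRate = pixelRate, scanModel = scanModel)
}

#' Frames overlapping any stimulation interval
#'
#' @param movie A [MovieBundle-class].
#' @return Integer indices of stimulation frames.
#' @export
stimFrames <- function(movie) {
  if (!nrow(movie@stimIntervals)) return(integer(0))
  hits <- lapply(seq_len(nrow(movie@stimIntervals)), function(i)
    which(movie@timestamps >= movie@stimIntervals[i, 1] &
          movie@timestamps <= movie@stimIntervals[i, 2]))
  sort(unique(unlist(hits)))
}

setMethod("show", "MovieBundle", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "MovieBundle: %d x %d px, %d frames, %d plane(s), %d stim interval(s), %s scan\n",
    d[1], d[2], d[3], length(unique(object@planeIndex)),
    nrow(object@stimIntervals), object@scanModel))
})

#' Read / write movies as multi-page TIFF with a JSON sidecar
#'
#' The frames go to a multi-page 32-bit float TIFF (normalized to the
#' global maximum); timestamps, plane indices, stimulation intervals,
#' pixel rate and scan model go to \code{<path>.json}. This pair is the
#' package's file of record for movies.
#'
#' @param movie A [MovieBundle-class].
#' @param path TIFF path.
#' @return \code{writeMovie}: \code{path} invisibly; \code{readMovie}:
#'   a [MovieBundle-class].
#' @export
writeMovie <- function(movie, path) {
  mx <- max(movie@frames)
  if (mx == 0) mx <- 1
  pages <- lapply(seq_len(dim(movie@frames)[3]), function(i)
    movie@frames[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(
    timestamps = movie@timestamps, plane_index = movie@planeIndex,
    stim_intervals = movie@stimIntervals, pixel_rate = movie@pixelRate,
    scan_model = movie@scanModel, scale = mx
  ), paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  si <- meta$stim_intervals
  if (is.null(si) || !length(si)) si <- matrix(numeric(0), 0, 2)
  movieBundle(arr, meta$timestamps, as.integer(meta$plane_index),
              matrix(as.numeric(si), ncol = 2), meta$pixel_rate,
              meta$scan_model)
}

#' Export an artifact mask as a 1-bit-style TIFF
#'
#' @param mask Logical array [y, x, t].
#' @param path TIFF path.
#' @return \code{path} invisibly.
#' @export
writeArtifactMask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask)[3]), function(i)
    matrix(as.numeric(mask[, , i]), dim(mask)[1], dim(mask)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}
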