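#' Expected spacing of mesh-artifact pixels along a scan line
#'
#' During photostimulation, laser pulses arrive more slowly than the
#' imaging pixel clock, so only every few pixels along a line are
#' contaminated: the base spacing is pixelRate / fRep pixels. Under the
#' resonant scan model the spacing is modulated by the local scanner
#' velocity (cosine profile): minimum (= the base spacing) at the line
#' centre and diverging toward the turnaround edges, which is why the
#' mesh looks non-uniform across the image.
#'
#' @param pixelRate Imaging pixel clock, Hz (default 8.2e6).
#' @param fRep Photostimulation laser repetition rate, Hz.
#' @param scanModel "linear" or "resonant".
#' @param column Column index (1-based) at which to evaluate the
#'   spacing; only used for the resonant model.
#' @param nColumns Number of columns in the image (resonant model).
#' @return Spacing in pixels (possibly fractional).
#' @examples
#' expectedArtifactSpacing(8.2e6, 1e6, "linear")   # 8.2 px
#' expectedArtifactSpacing(8.2e6, 2e5, "linear")   # 41 px
#' @export
expectedArtifactSpacing <- function(pixelRate = 8.2e6, fRep,
                                    scanModel = c("linear", "resonant"),
                                    column = NULL, nColumns = 512L) {
  scanModel <- match.arg(scanModel)
  if (pixelRate <= fRep)
    stop("pixel rate <= laser repetition rate: every pixel is compromised; ",
         "use frame deletion instead")
  base <- pixelRate / fRep
  if (scanModel == "linear") return(base)
  if (is.null(column)) column <- (nColumns + 1) / 2
  xi <- (column - 0.5) / nColumns          # 0..1 across the line
  vf <- cos(pi * (xi - 0.5))               # 1 at centre, -> 0 at edges
  base / pmax(vf, 1e-9)
}

#' Detect mesh-grid photostimulation artifact pixels
#'
#' Two-stage detector. Stage 1 (intensity): within each stimulation
#' interval, a pixel is a candidate when its value exceeds its own mean
#' plus \code{kSigma} standard deviations, both computed from
#' \code{prePostFrames} clean frames of the same imaging plane just
#' before and just after the interval. Stage 2 (geometry): candidate
#' runs along each horizontal and vertical line are kept only when the
#' run width does not exceed \code{maxWidth} pixels, and - where a row
#' carries more than one run - when the spacing between neighbouring
#' runs agrees with [expectedArtifactSpacing()] for the stimulation
#' condition within \code{spacingTol} (relative). Pixels are masked
#' only where both stages pass; the mask is therefore empty for movies
#' without stimulation intervals, and a uniformly elevated frame (run
#' width = full line) yields an empty mask, flagging the movie for
#' frame deletion instead.
#'
#' @param movie A [MovieBundle-class].
#' @param fRep Photostimulation laser repetition rate, Hz (default 5e5).
#' @param kSigma SD multiplier for stage 1 (default 3).
#' @param prePostFrames Clean frames used on each side (default 5).
#' @param maxWidth Maximum contaminated run width, pixels (default 2).
#' @param spacingTol Relative spacing tolerance (default 0.5).
#' @return Logical array [y, x, t], TRUE = contaminated; attribute
#'   \code{"report"} holds per-interval candidate/masked counts.
#' @export
detectArtifactPixels <- function(movie, fRep = 5e5, kSigma = 3,
                                 prePostFrames = 5L, maxWidth = 2L,
                                 spacingTol = 0.5) {
  d <- dim(movie@frames)
  mask <- array(FALSE, dim = d)
  if (!nrow(movie@stimIntervals)) {
    attr(mask, "report") <- data.frame()
    return(mask)
  }
  nc <- d[2]
  expSpacing <- expectedArtifactSpacing(movie@pixelRate, fRep,
                                        movie@scanModel,
                                        column = seq_len(nc),
                                        nColumns = nc)
  if (length(expSpacing) == 1) expSpacing <- rep(expSpacing, nc)
  report <- list()
  allStim <- stimFrames(movie)
  for (iv in seq_len(nrow(movie@stimIntervals))) {
    t0 <- movie@stimIntervals[iv, 1]; t1 <- movie@stimIntervals[iv, 2]
    inStim <- which(movie@timestamps >= t0 & movie@timestamps <= t1)
    for (f in inStim) {
      p <- movie@planeIndex[f]
      samePlane <- which(movie@planeIndex == p)
      inAnyStim <- samePlane %in% allStim
      pre <- rev(samePlane[samePlane < f & !inAnyStim])
      post <- samePlane[samePlane > f & !inAnyStim]
      pre <- pre[seq_len(min(length(pre), prePostFrames))]
      post <- post[seq_len(min(length(post), prePostFrames))]
      clean <- c(pre, post)
      if (length(clean) < 2)
        stop("no clean frames available around a stimulation interval")
      sub <- matrix(movie@frames[, , clean, drop = FALSE],
                    ncol = length(clean))
      nCl <- length(clean)
      mu <- matrix(rowMeans(sub), d[1], d[2])
      sdv <- matrix(sqrt(pmax(rowSums(sub^2) - nCl * rowMeans(sub)^2, 0) /
                           (nCl - 1)), d[1], d[2])
      # few clean frames make per-pixel SDs noisy; flooring at the
      # frame-wide median guards against underestimated tails
      sdv <- pmax(sdv, stats::median(sdv))
      cand <- movie@frames[, , f] > mu + kSigma * sdv
      keep <- cand & runGeometryTest(cand, maxWidth, expSpacing, spacingTol)
      mask[, , f] <- mask[, , f] | keep
      report[[length(report) + 1]] <- data.frame(
        interval = iv, frame = f, candidates = sum(cand), masked = sum(keep))
    }
  }
  attr(mask, "report") <- do.call(rbind, report)
  mask
}

# geometry gate, per row of a stimulation frame:
# 1. anchor runs: candidate runs no wider than maxWidth whose gap to a
#    neighbouring run matches the local expected spacing within
#    spacingTol (the expected gap from a run at column c to the next is
#    the spacing at c, so backward gaps reference the previous run);
#    a lone run in its row is accepted as an anchor.
# 2. the anchors seed the predicted pulse comb (stepping the local
#    spacing in both directions), and the final mask keeps candidate
#    pixels within one pixel of the comb, provided their run is not
#    wider than mergeWidth. this splits artifact pixels merged with
#    bright structure (e.g. an active cell body) out of their run,
#    while a uniformly elevated line (run width = full line) yields no
#    anchors and therefore no mask.
# a vertical run-width gate rejects tall blobs except where the comb
# vouches for the pixel.
runGeometryTest <- function(cand, maxWidth, expSpacing, spacingTol,
                            mergeWidth = 3L * maxWidth) {
  d <- dim(cand)
  ok <- array(FALSE, dim = d)
  colWidthOk <- matrix(TRUE, d[1], d[2])
  for (x in seq_len(d[2])) {
    r <- rle(cand[, x])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths > maxWidth))
      colWidthOk[starts[k]:ends[k], x] <- FALSE
  }
  spacingAt <- function(c0) expSpacing[max(1L, min(d[2], round(c0)))]
  for (y in seq_len(d[1])) {
    r <- rle(cand[y, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs)) next
    centres <- (starts[runs] + ends[runs]) / 2
    widths <- r$lengths[runs]
    anchor <- logical(length(runs))
    for (j in seq_along(runs)) {
      if (widths[j] > maxWidth) next
      spacingOk <- TRUE
      if (length(runs) > 1) {
        okGaps <- logical(0)
        if (j > 1) {
          expPrev <- spacingAt(centres[j - 1])
          okGaps <- c(okGaps, abs((centres[j] - centres[j - 1]) - expPrev)
                      <= spacingTol * expPrev)
        }
        if (j < length(runs)) {
          expHere <- spacingAt(centres[j])
          okGaps <- c(okGaps, abs((centres[j + 1] - centres[j]) - expHere)
                      <= spacingTol * expHere)
        }
        spacingOk <- any(okGaps)
      }
      anchor[j] <- spacingOk
    }
    if (!any(anchor)) next
    comb <- numeric(0)
    for (c0 in centres[anchor]) {
      p <- c0
      while (TRUE) {
        p <- p + spacingAt(p)
        if (p > d[2] + 1) break
        comb <- c(comb, p)
      }
      p <- c0
      while (TRUE) {
        p <- p - spacingAt(p)
        if (p < 0) break
        comb <- c(comb, p)
      }
      comb <- c(comb, c0)
    }
    comb <- sort(unique(round(comb * 2) / 2))
    for (j in seq_along(runs)) {
      if (widths[j] > mergeWidth) next
      cols <- starts[runs[j]]:ends[runs[j]]
      near <- vapply(cols, function(cc) any(abs(comb - cc) <= 1),
                     logical(1))
      if (widths[j] > maxWidth) {
        # comb-rescued pixels inside merged runs bypass the vertical
        # width gate (the blob they merged with is tall by nature)
        colWidthOk[y, cols[near]] <- TRUE
      }
      ok[y, cols[near]] <- TRUE
    }
  }
  ok & colWidthOk
}

#' Replace contaminated pixels from adjacent clean pixels
#'
#' Each masked pixel takes the value of the nearest clean pixel along
#' its scan line (row); when the two nearest clean neighbours are
#' equidistant, their mean is used. A fully contaminated row falls back
#' to the nearest clean pixel in the column (logged via \code{message}).
#' Pixels outside the mask are bit-identical to the input, and the
#' operation is idempotent.
#'
#' @param movie A [MovieBundle-class].
#' @param mask Logical array from [detectArtifactPixels()]; must be
#'   FALSE outside stimulation frames.
#' @return A cleaned [MovieBundle-class].
#' @export
inpaintArtifact <- function(movie, mask) {
  d <- dim(movie@frames)
  stopifnot(all(dim(mask) == d))
  sf <- stimFrames(movie)
  outside <- setdiff(which(apply(mask, 3, any)), sf)
  if (length(outside))
    stop("mask marks pixels outside stimulation frames")
  frames <- movie@frames
  for (f in which(apply(mask, 3, any))) {
    fr <- frames[, , f]
    mk <- mask[, , f]
    for (y in which(rowSums(mk) > 0)) {
      bad <- which(mk[y, ])
      clean <- which(!mk[y, ])
      if (!length(clean)) {
        message("fully contaminated row ", y, " in frame ", f,
                "; falling back to column neighbours")
        for (x in bad) {
          cleanCol <- which(!mk[, x])
          if (!length(cleanCol)) next
          dd <- abs(cleanCol - y)
          nn <- cleanCol[dd == min(dd)]
          fr[y, x] <- mean(frames[nn, x, f])
        }
        next
      }
      for (x in bad) {
        dd <- abs(clean - x)
        nn <- clean[dd == min(dd)]
        fr[y, x] <- mean(frames[y, nn, f])
      }
    }
    frames[, , f] <- fr
  }
  movieBundle(frames, movie@timestamps, movie@planeIndex,
              movie@stimIntervals, movie@pixelRate, movie@scanModel)
}

#' Delete frames overlapping stimulation intervals
#'
#' For short stimulations that contaminate only one frame per plane,
#' the impacted frames can simply be dropped with negligible data loss.
#' Timestamps of the surviving frames are preserved, so downstream
#' analysis sees irregular sampling across the gap.
#'
#' @param movie A [MovieBundle-class].
#' @return List with \code{movie} (frames removed), \code{removed}
#'   (dropped frame indices) and \code{gaps} (data.frame of dropped
#'   frame index, timestamp and plane). Warns when an interval covers
#'   more than one frame in a plane.
#' @export
deleteStimFrames <- function(movie) {
  rem <- stimFrames(movie)
  if (length(rem)) {
    perPlane <- table(movie@planeIndex[rem])
    if (any(perPlane > 1))
      warning("stimulation covers more than one frame per plane; ",
              "consider inpainting instead of deletion")
  }
  keep <- setdiff(seq_along(movie@timestamps), rem)
  gaps <- data.frame(frame = rem, timestamp = movie@timestamps[rem],
                     plane = movie@planeIndex[rem])
  cleaned <- movieBundle(movie@frames[, , keep, drop = FALSE],
                         movie@timestamps[keep], movie@planeIndex[keep],
                         movie@stimIntervals, movie@pixelRate,
                         movie@scanModel)
  list(movie = cleaned, removed = rem, gaps = gaps)
}
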