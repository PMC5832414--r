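#' Construct a synthetic-scene specification
#'
#' Defaults emulate the large-scale in vivo configuration: an imaged
#' volume of 480 x 480 x 150 microns in cortical layer 2/3, cell bodies
#' of ~12 micron diameter with a minimum spacing of 10 microns (the
#' lower end of the observed target separations), a slow-indicator
#' kernel (0.2 s rise, 1.5 s decay), a per-trial targeted response
#' probability of 0.82, a silent-cell fraction of 0.08, and nonspecific
#' activation decaying exponentially with distance to the nearest
#' target with a 12-micron length constant (placing the half-response
#' distance near ln(2) * 12 = 8.3 microns, comfortably inside the
#' sub-25-micron confinement regime).
#'
#' @param bounds Volume extents (x, y, z), microns.
#' @param nCells Number of cells in the volume.
#' @param minSpacing Minimum inter-cell spacing, microns.
#' @param cellRadius Cell-body radius, microns.
#' @param riseTau,decayTau Calcium kernel time constants, seconds.
#' @param baseline Baseline fluorescence, counts.
#' @param amplitude Transient peak amplitude at the cell centre, counts.
#' @param noiseSd Gaussian noise SD, counts.
#' @param pTargeted P(respond | targeted) per trial.
#' @param p0 Nonspecific activation probability at distance 0.
#' @param lambdaD Nonspecific length constant, microns.
#' @param silentFraction Fraction of cells that never respond.
#' @param seed Integer seed.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(bounds = c(480, 480, 150), nCells = 100L,
                      minSpacing = 10, cellRadius = 6,
                      riseTau = 0.2, decayTau = 1.5,
                      baseline = 100, amplitude = 150, noiseSd = 10,
                      pTargeted = 0.82, p0 = 0.9, lambdaD = 12,
                      silentFraction = 0.08, seed = 1L) {
  new("SceneSpec", bounds = as.numeric(bounds), nCells = as.integer(nCells),
      minSpacing = minSpacing, cellRadius = cellRadius, riseTau = riseTau,
      decayTau = decayTau, baseline = baseline, amplitude = amplitude,
      noiseSd = noiseSd, pTargeted = pTargeted, p0 = p0, lambdaD = lambdaD,
      silentFraction = silentFraction, seed = as.integer(seed))
}

# Poisson-disk-style dart throwing inside the scene volume
samplePoints <- function(n, bounds, minSpacing, maxTries = 10000L) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  for (tr in seq_len(maxTries)) {
    cand <- (stats::runif(3) - 0.5) * bounds
    if (got > 0) {
      dd <- sqrt(rowSums((pts[seq_len(got), , drop = FALSE] -
                          matrix(cand, got, 3, byrow = TRUE))^2))
      if (min(dd) < minSpacing) next
    }
    got <- got + 1L
    pts[got, ] <- cand
    if (got == n) break
  }
  if (got < n)
    stop("could not place ", n, " points at spacing ", minSpacing,
         " after ", maxTries, " tries")
  pts
}

#' Lay out the cells of a synthetic scene
#'
#' Cells are placed by Poisson-disk-style dart throwing at the scene's
#' minimum spacing, snapped axially to \code{nPlanes} imaging planes,
#' and a \code{silentFraction} of them marked silent (never responding,
#' emulating cells without functional opsin).
#'
#' @param spec A [SceneSpec-class].
#' @param nPlanes Number of imaging planes spanning the axial extent.
#' @return data.frame with x, y, z, plane, silent; deterministic given
#'   the scene seed.
#' @export
makeCells <- function(spec, nPlanes = 3L) {
  set.seed(spec@seed)
  pts <- samplePoints(spec@nCells, spec@bounds, spec@minSpacing)
  zs <- planeDepths(spec, nPlanes)
  plane <- vapply(pts[, 3], function(z) which.min(abs(zs - z)), integer(1))
  pts[, 3] <- zs[plane]
  silent <- stats::runif(spec@nCells) < spec@silentFraction
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             plane = plane, silent = silent)
}

planeDepths <- function(spec, nPlanes)
  if (nPlanes == 1) 0 else
    seq(-spec@bounds[3] / 2, spec@bounds[3] / 2, length.out = nPlanes)

#' Sample a photostimulation target set
#'
#' Either picks M cells from an existing scene layout (so targets
#' coincide with imaged cells) or throws M fresh Poisson-disk points in
#' the scene volume. Deterministic given the scene seed.
#'
#' @param spec A [SceneSpec-class].
#' @param m Number of targets.
#' @param cells Optional data.frame from [makeCells()]; targets are
#'   drawn from its rows (silent and responsive cells alike).
#' @return A [TargetSet-class]. When \code{cells} is supplied the
#'   attribute \code{"cellIndex"} gives the selected rows.
#' @export
makeTargets <- function(spec, m, cells = NULL) {
  set.seed(spec@seed + 1L)
  if (is.null(cells)) {
    if (m > spec@nCells) stop("m exceeds the scene cell count")
    return(targetSet(samplePoints(m, spec@bounds, spec@minSpacing)))
  }
  if (m > nrow(cells)) stop("m exceeds the number of cells")
  idx <- sort(sample(nrow(cells), m))
  ts <- targetSet(as.matrix(cells[idx, c("x", "y", "z")]))
  attr(ts, "cellIndex") <- idx
  ts
}

# normalized double-exponential calcium kernel, peak 1
calciumKernel <- function(t, riseTau, decayTau) {
  k <- (1 - exp(-pmax(t, 0) / riseTau)) * exp(-pmax(t, 0) / decayTau)
  k[t < 0] <- 0
  tp <- riseTau * log(1 + decayTau / riseTau)
  k / ((1 - exp(-tp / riseTau)) * exp(-tp / decayTau))
}

#' Render a synthetic multi-plane calcium movie with ground truth
#'
#' Builds the full study fixture: cells respond to photostimulation
#' trials according to the scene's response model (targeted cells with
#' probability pTargeted, non-targeted cells with probability
#' p0 * exp(-d / lambdaD) of their nearest-target distance d, silent
#' cells never), responses are convolved with the calcium kernel,
#' rendered as Gaussian cell bodies onto per-plane frames at the
#' volumetric sampling rate, Gaussian noise is added, and stimulation
#' frames receive a mesh-grid artifact whose pixel geometry follows
#' [expectedArtifactSpacing()] for the movie's pixel clock and the
#' laser repetition rate.
#'
#' @param spec A [SceneSpec-class].
#' @param targets A [TargetSet-class] built from the same cells (use
#'   [makeTargets()] with \code{cells}).
#' @param cells data.frame from [makeCells()].
#' @param nTrials Number of stimulation trials (default 8).
#' @param stimDuration Stimulation duration, seconds (default 0.5).
#' @param interTrial Trial spacing, seconds (default 6).
#' @param npx Frame size in pixels (square).
#' @param nPlanes Imaging planes (default 3).
#' @param fRep Photostimulation repetition rate, Hz (default 5e5).
#' @param artifactAmplitude Artifact brightness, counts (default 300).
#' @param scanModel Scan model for the artifact geometry.
#' @return List: \code{movie} (a [MovieBundle-class], with artifact),
#'   \code{cleanMovie} (without artifact), \code{artifactMask} (logical
#'   ground truth), \code{events} (logical [volume, cell] response
#'   onsets), \code{responders} (logical [trial, cell]), \code{cells},
#'   \code{targetIndex}, \code{trials} (trial table), \code{volumeTimes}.
#' @export
makeMovie <- function(spec, targets, cells, nTrials = 8L,
                      stimDuration = 0.5, interTrial = 6, npx = 64L,
                      nPlanes = 3L, fRep = 5e5,
                      artifactAmplitude = 300,
                      scanModel = c("resonant", "linear")) {
  scanModel <- match.arg(scanModel)
  targetIndex <- attr(targets, "cellIndex")
  if (is.null(targetIndex))
    stop("targets must carry the cellIndex attribute from makeTargets()")
  set.seed(spec@seed + 2L)
  nCell <- nrow(cells)
  volRate <- volumetricRate(nPlanes)
  dtVol <- 1 / volRate

  lead <- 4
  total <- lead + nTrials * interTrial
  volTimes <- seq(0, total, by = dtVol)
  nVol <- length(volTimes)
  stimStarts <- lead + (seq_len(nTrials) - 1) * interTrial
  trials <- data.frame(trial = seq_len(nTrials), pattern = 1L,
                       stimStart = stimStarts,
                       stimEnd = stimStarts + stimDuration)

  # response model: who responds on each trial
  pos <- as.matrix(cells[, c("x", "y", "z")])
  tpos <- pos[targetIndex, , drop = FALSE]
  dNearest <- vapply(seq_len(nCell), function(i)
    sqrt(min(rowSums((tpos - matrix(pos[i, ], nrow(tpos), 3,
                                    byrow = TRUE))^2))), numeric(1))
  pResp <- ifelse(seq_len(nCell) %in% targetIndex, spec@pTargeted,
                  spec@p0 * exp(-dNearest / spec@lambdaD))
  pResp[cells$silent] <- 0
  responders <- matrix(stats::runif(nTrials * nCell) <
                         rep(pResp, each = nTrials), nTrials, nCell)

  # event onsets on the volume clock
  events <- matrix(FALSE, nVol, nCell)
  for (tr in seq_len(nTrials)) {
    iv <- which.min(abs(volTimes - stimStarts[tr]))
    events[iv, responders[tr, ]] <- TRUE
  }

  # per-cell fluorescence on the volume clock
  kernelT <- seq(0, 8 * spec@decayTau, by = dtVol)
  kern <- calciumKernel(kernelT, spec@riseTau, spec@decayTau)
  fluor <- matrix(spec@baseline, nVol, nCell)
  for (j in seq_len(nCell)) {
    on <- which(events[, j])
    for (i in on) {
      idx <- i:min(nVol, i + length(kern) - 1)
      fluor[idx, j] <- fluor[idx, j] + spec@amplitude * kern[seq_along(idx)]
    }
  }

  # render frames: plane-by-plane Gaussian cell bodies
  zs <- planeDepths(spec, nPlanes)
  pxSize <- spec@bounds[1] / npx
  ax <- (seq_len(npx) - (npx + 1) / 2) * pxSize
  sigma <- spec@cellRadius / 2
  footprints <- lapply(seq_len(nCell), function(j) {
    wx <- exp(-(ax - cells$x[j])^2 / (2 * sigma^2))
    wy <- exp(-(ax - cells$y[j])^2 / (2 * sigma^2))
    fp <- outer(wy, wx)
    fp[fp < 0.05] <- 0
    fp
  })

  nFrames <- nVol * nPlanes
  frames <- array(0, dim = c(npx, npx, nFrames))
  timestamps <- numeric(nFrames)
  planeIndex <- integer(nFrames)
  frameDt <- dtVol / nPlanes
  f <- 0L
  for (iv in seq_len(nVol)) {
    for (p in seq_len(nPlanes)) {
      f <- f + 1L
      timestamps[f] <- volTimes[iv] + (p - 1) * frameDt
      planeIndex[f] <- p
      img <- matrix(0, npx, npx)
      for (j in which(cells$plane == p))
        img <- img + fluor[iv, j] * footprints[[j]]
      frames[, , f] <- img + spec@baseline / 4      # neuropil floor
    }
  }
  noise <- array(stats::rnorm(length(frames), 0, spec@noiseSd), dim(frames))
  clean <- pmax(frames + noise, 0)

  stimIntervals <- cbind(trials$stimStart, trials$stimEnd)
  bundleClean <- movieBundle(clean, timestamps, planeIndex, stimIntervals,
                             scanModel = scanModel)

  # inject the mesh artifact into stimulation frames
  mask <- array(FALSE, dim = dim(clean))
  dirty <- clean
  sf <- stimFrames(bundleClean)
  spacingAt <- function(col) expectedArtifactSpacing(
    bundleClean@pixelRate, fRep, scanModel, column = col, nColumns = npx)
  baseSpacing <- bundleClean@pixelRate / fRep
  for (fr in sf) {
    p <- stats::runif(1, 0, baseSpacing)
    for (y in seq_len(npx)) {
      while (p <= npx) {
        c0 <- max(1, min(npx, round(p)))
        mask[y, c0, fr] <- TRUE
        dirty[y, c0, fr] <- dirty[y, c0, fr] + artifactAmplitude
        p <- p + spacingAt(c0)
      }
      p <- p - npx
    }
  }
  bundleDirty <- movieBundle(dirty, timestamps, planeIndex, stimIntervals,
                             scanModel = scanModel)
  list(movie = bundleDirty, cleanMovie = bundleClean, artifactMask = mask,
       events = events, responders = responders, cells = cells,
       targetIndex = targetIndex, trials = trials, volumeTimes = volTimes)
}

#' Extract ROI traces from a movie
#'
#' Averages each cell's footprint pixels in its own imaging plane, one
#' sample per volume, and converts to dF/F against the per-ROI median.
#' This is deliberately simple source extraction (the upstream
#' segmentation problem is out of scope); positions are taken from the
#' generator's cell table.
#'
#' @param movie A [MovieBundle-class] from [makeMovie()].
#' @param cells data.frame from [makeCells()].
#' @param spec The [SceneSpec-class] used to build the movie.
#' @param trials Trial table from [makeMovie()].
#' @param targetIndex Indices of targeted cells.
#' @param npx Frame size used in [makeMovie()].
#' @return A [TraceSet-class] on the volume clock.
#' @export
extractTraces <- function(movie, cells, spec, trials, targetIndex,
                          npx = dim(movie@frames)[1]) {
  pxSize <- spec@bounds[1] / npx
  ax <- (seq_len(npx) - (npx + 1) / 2) * pxSize
  nCell <- nrow(cells)
  planes <- sort(unique(movie@planeIndex))
  volFrames <- lapply(planes, function(p) which(movie@planeIndex == p))
  nVol <- min(lengths(volFrames))
  tt <- movie@timestamps[volFrames[[1]][seq_len(nVol)]]
  raw <- matrix(0, nVol, nCell)
  for (j in seq_len(nCell)) {
    iy <- which(abs(ax - cells$y[j]) <= spec@cellRadius / 2)
    ix <- which(abs(ax - cells$x[j]) <= spec@cellRadius / 2)
    if (!length(iy)) iy <- which.min(abs(ax - cells$y[j]))
    if (!length(ix)) ix <- which.min(abs(ax - cells$x[j]))
    fidx <- volFrames[[cells$plane[j]]][seq_len(nVol)]
    raw[, j] <- vapply(fidx, function(f)
      mean(movie@frames[iy, ix, f]), numeric(1))
  }
  f0 <- apply(raw, 2, stats::median)
  f0[f0 <= 0] <- 1
  dff <- sweep(sweep(raw, 2, f0), 2, f0, "/")
  roi <- data.frame(x = cells$x, y = cells$y, z = cells$z,
                    targeted = seq_len(nCell) %in% targetIndex)
  traceSet(dff, tt, roi, trials, decayTau = spec@decayTau)
}

#' Generate a calibration point fixture
#'
#' A 7 x 7 grid over 240 x 240 microns per depth, forward-mapped
#' through the supplied true affine transforms with optional Gaussian
#' measurement noise. Seed-deterministic.
#'
#' @param trueAffines List of affines (A, b), one per depth.
#' @param depths Depths in microns (default 25-micron spacing).
#' @param noiseSd Measurement noise SD, microns (default 0).
#' @param seed Integer seed.
#' @return List with \code{slm} (49 x 2 grid), \code{image} (list of
#'   49 x 2 matrices per depth) and \code{depths}.
#' @export
makeCalibrationFixture <- function(trueAffines,
                                   depths = seq(0, by = 25,
                                     length.out = length(trueAffines)),
                                   noiseSd = 0, seed = 1L) {
  stopifnot(length(trueAffines) == length(depths), noiseSd >= 0)
  set.seed(seed)
  g <- unname(as.matrix(expand.grid(x = seq(-120, 120, length.out = 7),
                                    y = seq(-120, 120, length.out = 7))))
  image <- lapply(trueAffines, function(tr)
    applyAffine(tr, g) + matrix(stats::rnorm(length(g), 0, noiseSd),
                                nrow(g), 2))
  list(slm = g, image = image, depths = depths)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %g x %g x %g um, %d cells, p(target)=%.2f, silent=%.2f, seed %d\n",
    object@bounds[1], object@bounds[2], object@bounds[3], object@nCells,
    object@pTargeted, object@silentFraction, object@seed))
})
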