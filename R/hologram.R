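#' Multi-target hologram by complex superposition
#'
#' Builds the SLM phase mask addressing every target in one shot as the
#' phase of the coherent sum
#' \deqn{\phi(u,v) = \arg \sum_{i=1}^{M} A_i \exp\{2\pi j [x_i u + y_i v
#'   + Z_2^0 C_2^0(z_i) + Z_4^0 C_4^0(z_i) + Z_6^0 C_6^0(z_i)]\}}
#' where (u, v) are physical spatial frequencies on the pupil
#' (cycles/micron), so the tilt term is an exact Fourier shift, and the
#' Zernike block (evaluated on unit-disk radii) provides
#' aberration-compensated defocus to each target depth.
#'
#' @param targets A [TargetSet-class]; lateral positions must lie within
#'   [addressableRange()] of the SLM grid.
#' @param optics An [OpticalConfig-class].
#' @return A [PhaseMask-class] with pixels outside the pupil set to 0.
#' @examples
#' opt <- opticalConfig(slmPixels = 64)
#' mask <- superpositionHologram(targetSet(cbind(10, 0, 0)), opt)
#' @export
superpositionHologram <- function(targets, optics) {
  field <- superpositionField(targets, optics)
  g <- pupilGrid(optics)
  ph <- wrapPhase(Arg(field))
  ph[!g$pupil] <- 0
  new("PhaseMask", phase = ph, optics = optics)
}

#' Complex pupil field of the target superposition
#'
#' The unnormalized complex sum whose argument
#' [superpositionHologram()] keeps. Exposed so that the linearity of the
#' superposition (hologram of a union = phase of the sum of fields, not
#' the sum of phases) can be exercised directly.
#'
#' @inheritParams superpositionHologram
#' @return Complex matrix (slmPixels x slmPixels); zero outside the pupil.
#' @export
superpositionField <- function(targets, optics) {
  validObject(targets)
  g <- pupilGrid(optics)
  rng <- addressableRange(optics)
  xy <- targets@coords[, 1:2, drop = FALSE]
  bad <- which(abs(xy[, 1]) >= rng | abs(xy[, 2]) >= rng)
  if (length(bad))
    stop(sprintf(
      "target %d at (%.1f, %.1f) um exceeds the addressable range +/- %.1f um",
      bad[1], xy[bad[1], 1], xy[bad[1], 2], rng))
  field <- matrix(0 + 0i, optics@slmPixels, optics@slmPixels)
  for (i in seq_len(nrow(targets@coords))) {
    p <- targets@coords[i, ]
    waves <- p[1] * g$u + p[2] * g$v +
      zernikeRadial(2, g$rho2) * zernikeCoef(2, p[3], optics) +
      zernikeRadial(4, g$rho2) * zernikeCoef(4, p[3], optics) +
      zernikeRadial(6, g$rho2) * zernikeCoef(6, p[3], optics)
    field <- field + targets@weights[i] * exp(2i * pi * waves)
  }
  field[!g$pupil] <- 0 + 0i
  field
}

#' Multi-plane Gerchberg-Saxton hologram
#'
#' Iterative phase retrieval for extended 3D intensity targets (e.g. a
#' 12-micron disk covering a cell body). Each iteration propagates the
#' pupil field to every target plane with the aberration-compensated
#' defocus kernel of [zernikeDefocusPhase()], replaces the amplitude
#' with the target amplitude (keeping phase), back-propagates, sums the
#' pupil fields over planes, and re-imposes the pupil illumination
#' amplitude. Iteration stops at \code{iterations} or when the
#' target-intensity correlation improves by less than \code{tol}.
#'
#' @param targetAmps List of nonnegative amplitude matrices, one per
#'   plane, each sized slmPixels x slmPixels on the focal-plane grid of
#'   [gsFocalGrid()] (indexed [y, x]).
#' @param zPlanes Plane depths in microns, one per amplitude image.
#' @param optics An [OpticalConfig-class].
#' @param iterations Maximum iterations (default 50).
#' @param seed Integer seed for the uniform-random initial phase.
#' @param illumination "uniform" (flat-top disk, default) or "gaussian"
#'   (1/e^2 waist at the pupil edge).
#' @param tol Early-stop threshold on the correlation change (default 1e-4).
#' @return A [PhaseMask-class] with attribute \code{"trace"}: the
#'   per-iteration correlation between achieved intensity and squared
#'   target amplitude.
#' @export
gs3dHologram <- function(targetAmps, zPlanes, optics, iterations = 50L,
                         seed = 1L, illumination = c("uniform", "gaussian"),
                         tol = 1e-4) {
  illumination <- match.arg(illumination)
  if (!is.list(targetAmps)) targetAmps <- list(targetAmps)
  if (length(targetAmps) < 1 || length(targetAmps) != length(zPlanes))
    stop("need one target amplitude image per z plane")
  if (iterations < 1) stop("iterations must be >= 1")
  n <- optics@slmPixels
  for (a in targetAmps) {
    if (!all(dim(a) == c(n, n))) stop("target amplitudes must be slmPixels^2")
    if (any(a < 0)) stop("target amplitudes must be nonnegative")
  }
  if (all(vapply(targetAmps, function(a) all(a == 0), logical(1))))
    stop("all-zero target amplitude")

  g <- pupilGrid(optics)
  amp <- if (illumination == "uniform") ifelse(g$pupil, 1, 0)
         else ifelse(g$pupil, exp(-g$rho2), 0)
  # propagation kernel to depth z is the conjugate of the defocus mask
  # that displaces a focus by +z
  kernels <- lapply(zPlanes, function(z)
    exp(-1i * defocusPhaseRaw(z, optics, g)))
  targetI <- unlist(lapply(targetAmps, function(a) as.numeric(a^2)))

  set.seed(seed)
  phase <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  P <- amp * exp(1i * phase)
  trace <- numeric(0)
  lastCor <- -Inf
  for (it in seq_len(iterations)) {
    back <- matrix(0 + 0i, n, n)
    achieved <- numeric(0)
    for (p in seq_along(zPlanes)) {
      E <- fftshift2(stats::fft(fftshift2(P * kernels[[p]]))) / n
      achieved <- c(achieved, as.numeric(Mod(E)^2))
      Ep <- targetAmps[[p]] * exp(1i * Arg(E))
      Pp <- fftshift2(stats::fft(fftshift2(Ep), inverse = TRUE)) / n
      back <- back + Pp * Conj(kernels[[p]])
    }
    phase <- Arg(back)
    P <- amp * exp(1i * phase)
    co <- suppressWarnings(stats::cor(achieved, targetI))
    if (!is.finite(co)) co <- 0
    trace <- c(trace, co)
    if (it > 1 && abs(co - lastCor) < tol) break
    lastCor <- co
  }
  ph <- wrapPhase(phase)
  ph[!g$pupil] <- 0
  mask <- new("PhaseMask", phase = ph, optics = optics)
  attr(mask, "trace") <- trace
  mask
}

#' Focal-plane grid matching the Gerchberg-Saxton target images
#'
#' The single-FFT propagation used inside [gs3dHologram()] maps the
#' slmPixels^2 pupil onto a focal grid with pitch 1/(2 uMax) microns.
#' Use these coordinates to paint target amplitude images.
#'
#' @param optics An [OpticalConfig-class].
#' @return List with vectors \code{xs}, \code{ys} (microns) and scalar
#'   \code{dx}.
#' @export
gsFocalGrid <- function(optics) {
  g <- pupilGrid(optics)
  n <- optics@slmPixels
  dx <- 1 / (n * g$du)
  ax <- ((0:(n - 1)) - n / 2) * dx
  list(xs = ax, ys = ax, dx = dx)
}

#' Paint a disk target amplitude image
#'
#' Convenience builder for scanless-style disk targets (a flat disk of
#' the cell-body size) on the [gsFocalGrid()].
#'
#' @param optics An [OpticalConfig-class].
#' @param centre Length-2 (x, y) centre in microns.
#' @param diameter Disk diameter in microns (default 12, cell-body size).
#' @return Amplitude matrix [y, x] with 1 inside the disk, 0 outside.
#' @export
diskTarget <- function(optics, centre = c(0, 0), diameter = 12) {
  grid <- gsFocalGrid(optics)
  X <- matrix(grid$xs, length(grid$ys), length(grid$xs), byrow = TRUE)
  Y <- matrix(grid$ys, length(grid$ys), length(grid$xs))
  ifelse((X - centre[1])^2 + (Y - centre[2])^2 <= (diameter / 2)^2, 1, 0)
}

#' Equalize delivered power across targets
#'
#' The SLM's diffraction efficiency eta(x, y, z) drops with deflection
#' angle, so distant targets receive less light. Rescaling each field
#' weight to A_i / sqrt(eta_i) makes the delivered power (proportional
#' to A_i^2 eta_i) uniform in the requested weights while preserving
#' their relative ordering.
#'
#' @param targets A [TargetSet-class].
#' @param model An [EfficiencyModel-class] from [fitEfficiency()].
#' @return A new [TargetSet-class] with compensated weights.
#' @export
compensateEfficiency <- function(targets, model) {
  eta <- predictEfficiency(model, targets@coords)
  if (any(eta <= 0))
    stop("efficiency model is nonpositive at a target position")
  targetSet(targets@coords, targets@weights / sqrt(eta))
}

setMethod("show", "PhaseMask", function(object) {
  cat(sprintf("PhaseMask: %d x %d px, phase in [%.3f, %.3f) rad\n",
              nrow(object@phase), ncol(object@phase),
              min(object@phase), max(object@phase)))
})

#' Read / write phase masks
#'
#' Two on-disk dialects are supported: 32-bit float TIFF holding radians
#' directly, and 8-bit PNG mapping 0-255 onto [0, 2*pi) (the common SLM
#' driver format). Round-tripping a mask through TIFF is exact to float
#' precision; through PNG it quantizes to 256 levels.
#'
#' @param mask A [PhaseMask-class].
#' @param path Output path ending in .tif/.tiff or .png.
#' @param optics The [OpticalConfig-class] to attach on read.
#' @return \code{writePhaseMask} returns \code{path} invisibly;
#'   \code{readPhaseMask} returns a [PhaseMask-class].
#' @export
writePhaseMask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(mask@phase / (2 * pi), path)
  } else {
    tiff::writeTIFF(mask@phase / (2 * pi), path, bits.per.sample = 32L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' @rdname writePhaseMask
#' @export
readPhaseMask <- function(path, optics) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (is.list(img)) img <- img[[1]]
  new("PhaseMask", phase = wrapPhase(img * 2 * pi), optics = optics)
}
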