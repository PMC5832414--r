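#' @import methods
NULL

#' Optical configuration of the photostimulation path
#'
#' Holds the optical parameters needed to synthesize SLM phase holograms
#' and to simulate the focal field they produce: excitation wavelength,
#' immersion refractive index, numerical aperture, and SLM geometry.
#' The \code{effectiveNA} slot is the calibration knob used only inside
#' the Zernike defocus coefficients (the defocus model can be tuned
#' against a measured axial displacement without touching the pupil
#' size); it defaults to \code{na}.
#'
#' @slot wavelength Excitation wavelength in microns.
#' @slot refractiveIndex Immersion refractive index (1.33 for water).
#' @slot na Numerical aperture n*sin(alpha) of the photostimulation beam.
#' @slot effectiveNA Effective NA used in the defocus coefficients.
#' @slot slmPixels Pixels per side of the (square) SLM.
#' @slot slmPitch SLM pixel pitch in millimetres.
#'
#' @seealso [opticalConfig()] for the user constructor, [pupilGrid()]
#'   for the derived spatial-frequency grid.
#' @export
setClass("OpticalConfig",
  representation(
    wavelength = "numeric",
    refractiveIndex = "numeric",
    na = "numeric",
    effectiveNA = "numeric",
    slmPixels = "integer",
    slmPitch = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a positive scalar (microns)")
  if (length(object@na) != 1 || object@na <= 0 ||
      object@na >= object@refractiveIndex)
    msg <- c(msg, "na must satisfy 0 < na < refractiveIndex")
  if (length(object@effectiveNA) != 1 || object@effectiveNA <= 0 ||
      object@effectiveNA >= object@refractiveIndex)
    msg <- c(msg, "effectiveNA must satisfy 0 < effectiveNA < refractiveIndex")
  if (length(object@slmPixels) != 1 || object@slmPixels < 32L)
    msg <- c(msg, "slmPixels must be >= 32")
  if (object@slmPitch <= 0) msg <- c(msg, "slmPitch must be positive")
  if (length(msg)) msg else TRUE
})

#' A set of 3D photostimulation targets
#'
#' Cell-body centroids to be addressed simultaneously by the hologram,
#' in sample coordinates (microns; origin at the centre of the field of
#' view on the nominal focal plane, z positive deeper into the sample),
#' together with per-target field-amplitude weights that control the
#' laser power each target receives.
#'
#' @slot coords Numeric matrix with M rows and columns x, y, z (microns).
#' @slot weights Nonnegative field amplitudes, one per target.
#'
#' @seealso [targetSet()], [superpositionHologram()],
#'   [compensateEfficiency()]
#' @export
setClass("TargetSet",
  representation(coords = "matrix", weights = "numeric")
)

setValidity("TargetSet", function(object) {
  msg <- character()
  if (nrow(object@coords) < 1) msg <- c(msg, "need at least one target")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (length(object@weights) != nrow(object@coords))
    msg <- c(msg, "one weight per target required")
  if (any(object@weights < 0) || !any(object@weights > 0))
    msg <- c(msg, "weights must be nonnegative with at least one positive")
  if (length(msg)) msg else TRUE
})

#' SLM phase mask
#'
#' A square array of phase values in radians, wrapped to [0, 2*pi), on
#' the SLM plane. The attached [OpticalConfig-class] links pixel (p, q)
#' to pupil spatial-frequency coordinates (u, v).
#'
#' @slot phase Numeric matrix (slmPixels x slmPixels), radians in [0, 2*pi).
#' @slot optics The [OpticalConfig-class] the mask was built for.
#' @export
setClass("PhaseMask",
  representation(phase = "matrix", optics = "OpticalConfig")
)

setValidity("PhaseMask", function(object) {
  msg <- character()
  n <- object@optics@slmPixels
  if (!all(dim(object@phase) == c(n, n)))
    msg <- c(msg, "phase dimensions must match slmPixels")
  if (any(object@phase < 0) || any(object@phase >= 2 * pi))
    msg <- c(msg, "phase values must lie in [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' Simulated 3D focal intensity stack
#'
#' Intensity |E|^2 of the focal field on a regular (y, x, z) voxel grid,
#' in arbitrary units. Two-photon signal is the square of this intensity
#' when \code{photonOrder == 2}; use [twoPhotonSignal()].
#'
#' @slot intensity 3D numeric array indexed [y, x, z].
#' @slot xs,ys,zs Voxel-centre coordinates along each axis (microns).
#' @slot photonOrder 1L (fluence) or 2L (two-photon excitation).
#' @export
setClass("FocalStack",
  representation(intensity = "array", xs = "numeric", ys = "numeric",
                 zs = "numeric", photonOrder = "integer")
)

setValidity("FocalStack", function(object) {
  msg <- character()
  d <- dim(object@intensity)
  if (length(d) != 3) msg <- c(msg, "intensity must be a 3D array")
  else {
    if (d[1] != length(object@ys) || d[2] != length(object@xs) ||
        d[3] != length(object@zs))
      msg <- c(msg, "grid vectors must match intensity dimensions")
  }
  if (any(object@intensity < 0)) msg <- c(msg, "intensity must be nonnegative")
  if (length(object@zs) > 1 && any(diff(object@zs) <= 0))
    msg <- c(msg, "z planes must be strictly increasing")
  if (!object@photonOrder %in% c(1L, 2L))
    msg <- c(msg, "photonOrder must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Per-depth affine calibration between SLM and imaging coordinates
#'
#' One 2D affine transform (2x2 matrix plus offset) per calibration
#' depth, fitted from burn-spot correspondences; depths in between are
#' linearly interpolated with [interpAffine()].
#'
#' @slot depths Strictly increasing calibration depths (microns).
#' @slot transforms List, one per depth, each with elements \code{A}
#'   (2x2), \code{b} (length-2 offset, microns) and \code{residual}
#'   (RMS fit residual, microns).
#' @export
setClass("AffineCalibration",
  representation(depths = "numeric", transforms = "list")
)

setValidity("AffineCalibration", function(object) {
  msg <- character()
  if (length(object@depths) < 1) msg <- c(msg, "need at least one depth")
  if (length(object@depths) != length(object@transforms))
    msg <- c(msg, "one transform per depth required")
  if (length(object@depths) > 1 && any(diff(object@depths) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  for (tr in object@transforms) {
    if (!is.matrix(tr$A) || any(dim(tr$A) != 2) ||
        abs(det(tr$A)) < .Machine$double.eps)
      msg <- c(msg, "every transform matrix must be 2x2 and invertible")
  }
  if (length(msg)) msg else TRUE
})

#' SLM diffraction-efficiency model
#'
#' Beam-steering efficiency drops with deflection angle, i.e. with
#' distance from the centre of the field of view (laterally) and from
#' the nominal focus (axially). Modelled as a separable linear decay,
#' eta(x, y, z) = c0 + c1|x| + c2|y| + c3|z|, clamped to (0, 1] and
#' normalized so eta(0, 0, 0) = 1.
#'
#' @slot coef Numeric length-4 vector (c0, c1, c2, c3).
#' @slot residual RMS residual of the fit.
#' @export
setClass("EfficiencyModel",
  representation(coef = "numeric", residual = "numeric")
)

setValidity("EfficiencyModel", function(object) {
  msg <- character()
  if (length(object@coef) != 4) msg <- c(msg, "coef must have 4 elements")
  if (object@coef[1] <= 0) msg <- c(msg, "c0 must be positive")
  if (length(msg)) msg else TRUE
})

#' Spiral scan trajectory over a cell body
#'
#' An inward Archimedean spiral, sampled uniformly in time: the radius
#' decays linearly from outerDiameter/2 to zero while the angle advances
#' by 2*pi per rotation.
#'
#' @slot outerDiameter Outer spiral diameter in microns (default 12).
#' @slot rotations Number of rotations (8-50 typical).
#' @slot duration Scan duration in milliseconds.
#' @slot sampleRate Galvo command rate in Hz.
#' @slot waypoints Two-column matrix of (x, y) offsets in microns.
#' @export
setClass("SpiralScan",
  representation(outerDiameter = "numeric", rotations = "numeric",
                 duration = "numeric", sampleRate = "numeric",
                 waypoints = "matrix")
)

setValidity("SpiralScan", function(object) {
  msg <- character()
  if (object@rotations < 1) msg <- c(msg, "rotations must be >= 1")
  r <- sqrt(rowSums(object@waypoints^2))
  if (any(diff(r) > 1e-9)) msg <- c(msg, "radius must be non-increasing")
  if (abs(max(r) - object@outerDiameter / 2) > 1e-9)
    msg <- c(msg, "max radius must equal outerDiameter/2")
  if (length(msg)) msg else TRUE
})

#' Photostimulation laser configuration
#'
#' @slot repRate Pulse repetition rate in Hz (200 kHz - 1 MHz typical;
#'   lowering it raises peak power at fixed average power).
#' @slot averagePower Total average power delivered to the sample, mW.
#' @slot nTargets Number of simultaneously addressed targets M.
#' @export
setClass("LaserConfig",
  representation(repRate = "numeric", averagePower = "numeric",
                 nTargets = "integer")
)

setValidity("LaserConfig", function(object) {
  msg <- character()
  if (object@repRate <= 0) msg <- c(msg, "repRate must be positive")
  if (object@averagePower < 0) msg <- c(msg, "averagePower must be >= 0")
  if (object@nTargets < 1L) msg <- c(msg, "nTargets must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Photostimulation plan
#'
#' A spiral scan repeated back-to-back, with the per-cell power implied
#' by the laser budget.
#'
#' @slot spiral The [SpiralScan-class] repeated.
#' @slot repeats Number of back-to-back repeats.
#' @slot totalDuration Total duration in milliseconds.
#' @slot perCellPower Average power per targeted cell, mW.
#' @slot laser The [LaserConfig-class].
#' @export
setClass("StimPlan",
  representation(spiral = "SpiralScan", repeats = "integer",
                 totalDuration = "numeric", perCellPower = "numeric",
                 laser = "LaserConfig")
)

setValidity("StimPlan", function(object) {
  msg <- character()
  if (abs(object@totalDuration -
          object@repeats * object@spiral@duration) > 1e-9)
    msg <- c(msg, "totalDuration must equal repeats * spiral duration")
  if (object@perCellPower * object@laser@nTargets >
      object@laser@averagePower + 1e-9)
    msg <- c(msg, "per-cell power exceeds the laser power budget")
  if (length(msg)) msg else TRUE
})

#' Multi-plane calcium-imaging movie with stimulation metadata
#'
#' Frames are stored [y, x, t]; each frame carries a timestamp and the
#' index of the imaging plane it belongs to. Stimulation intervals are
#' (start, end) times in seconds. The pixel clock and scan model govern
#' the expected geometry of the mesh-grid photostimulation artifact.
#'
#' @slot frames 3D numeric array [y, x, t] of fluorescence counts.
#' @slot timestamps Frame times in seconds.
#' @slot planeIndex Integer plane index per frame.
#' @slot stimIntervals Two-column matrix of (start, end) seconds.
#' @slot pixelRate Imaging pixel clock in Hz (default 8.2e6).
#' @slot scanModel "resonant" or "linear".
#' @export
setClass("MovieBundle",
  representation(frames = "array", timestamps = "numeric",
                 planeIndex = "integer", stimIntervals = "matrix",
                 pixelRate = "numeric", scanModel = "character")
)

setValidity("MovieBundle", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a 3D [y, x, t] array")
  else if (d[3] != length(object@timestamps) ||
           d[3] != length(object@planeIndex))
    msg <- c(msg, "timestamps and planeIndex must match frame count")
  if (any(object@frames < 0)) msg <- c(msg, "frames must be nonnegative")
  for (p in unique(object@planeIndex)) {
    tt <- object@timestamps[object@planeIndex == p]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      msg <- c(msg, "timestamps must strictly increase within each plane")
      break
    }
  }
  if (nrow(object@stimIntervals) > 0) {
    if (ncol(object@stimIntervals) != 2)
      msg <- c(msg, "stimIntervals must have 2 columns")
    else if (any(object@stimIntervals[, 1] > object@stimIntervals[, 2]))
      msg <- c(msg, "stim interval start must not exceed end")
  }
  if (!object@scanModel %in% c("resonant", "linear"))
    msg <- c(msg, "scanModel must be 'resonant' or 'linear'")
  if (object@pixelRate <= 0) msg <- c(msg, "pixelRate must be positive")
  if (length(msg)) msg else TRUE
})

#' ROI traces aligned to a trial structure
#'
#' Per-ROI dF/F time series plus a deconvolved (event-probability)
#' series, shared timestamps, ROI positions, and the stimulation trial
#' table.
#'
#' @slot dff Numeric matrix [time, roi] of dF/F.
#' @slot deconvolved Nonnegative matrix [time, roi].
#' @slot timestamps Sample times in seconds.
#' @slot roi data.frame with columns x, y, z (microns) and logical
#'   \code{targeted}.
#' @slot trials data.frame with columns trial, pattern, stimStart,
#'   stimEnd (seconds).
#' @export
setClass("TraceSet",
  representation(dff = "matrix", deconvolved = "matrix",
                 timestamps = "numeric", roi = "data.frame",
                 trials = "data.frame")
)

setValidity("TraceSet", function(object) {
  msg <- character()
  if (nrow(object@dff) != length(object@timestamps))
    msg <- c(msg, "dff rows must match timestamps")
  if (!all(dim(object@deconvolved) == dim(object@dff)))
    msg <- c(msg, "deconvolved must match dff dimensions")
  if (any(object@deconvolved < 0)) msg <- c(msg, "deconvolved must be >= 0")
  if (ncol(object@dff) != nrow(object@roi))
    msg <- c(msg, "one roi row per trace required")
  if (length(msg)) msg else TRUE
})

#' Synthetic-scene specification
#'
#' Generator knobs for the synthetic fixtures: imaged volume, cell
#' layout, GCaMP kernel, noise, and the stimulation response model
#' P(respond | targeted) and P(respond | d) = p0 * exp(-d / lambdaD)
#' for non-targeted cells at distance d from their nearest target.
#'
#' @slot bounds Numeric length-3 (x, y, z) extents of the volume, microns.
#' @slot nCells Number of cells.
#' @slot minSpacing Minimum inter-cell spacing, microns.
#' @slot cellRadius Cell-body radius, microns.
#' @slot riseTau,decayTau GCaMP kernel time constants, seconds.
#' @slot baseline Baseline fluorescence (counts).
#' @slot amplitude Transient amplitude (counts at the cell centre).
#' @slot noiseSd Gaussian noise SD (counts).
#' @slot pTargeted P(respond | targeted) per trial.
#' @slot p0 Nonspecific activation probability at d = 0.
#' @slot lambdaD Nonspecific activation length constant, microns.
#' @slot silentFraction Fraction of cells that never respond.
#' @slot seed Integer seed making the generator reproducible.
#' @export
setClass("SceneSpec",
  representation(bounds = "numeric", nCells = "integer",
                 minSpacing = "numeric", cellRadius = "numeric",
                 riseTau = "numeric", decayTau = "numeric",
                 baseline = "numeric", amplitude = "numeric",
                 noiseSd = "numeric", pTargeted = "numeric",
                 p0 = "numeric", lambdaD = "numeric",
                 silentFraction = "numeric", seed = "integer")
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@bounds) != 3 || any(object@bounds <= 0))
    msg <- c(msg, "bounds must be 3 positive extents")
  if (object@minSpacing >= sqrt(sum(object@bounds^2)))
    msg <- c(msg, "minSpacing must be smaller than the volume diagonal")
  p <- c(object@pTargeted, object@p0, object@silentFraction)
  if (any(p < 0) || any(p > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@riseTau <= 0 || object@decayTau <= 0)
    msg <- c(msg, "kernel time constants must be positive")
  if (length(msg)) msg else TRUE
})
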