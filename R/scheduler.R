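#' Inward spiral scan trajectory
#'
#' Archimedean spiral sampled uniformly in time: radius
#' r(t) = (diameter/2)(1 - t/T) decays linearly from the outer radius to
#' zero while theta(t) = 2*pi*rotations*t/T advances at constant angular
#' speed. This is the galvo trajectory spiralled over each cell body
#' (default 12-micron outer diameter; 8-50 rotations typical). A
#' uniform-in-arc-length variant is available for rigs that command
#' constant scan speed.
#'
#' @param diameter Outer spiral diameter, microns (default 12).
#' @param rotations Number of rotations (>= 1).
#' @param duration Scan duration, milliseconds.
#' @param sampleRate Galvo command rate, Hz (default 10 kHz). Must give
#'   at least 10 samples per rotation.
#' @param parameterization "time" (default) or "arclength".
#' @return A [SpiralScan-class]; waypoints include t = 0 and t = T.
#' @examples
#' sp <- spiralTrajectory(12, 50, 20)
#' max(sqrt(rowSums(sp@waypoints^2)))  # = 6 um
#' @export
spiralTrajectory <- function(diameter = 12, rotations = 50, duration = 20,
                             sampleRate = 1e4,
                             parameterization = c("time", "arclength")) {
  parameterization <- match.arg(parameterization)
  if (duration <= 0) stop("duration must be positive")
  nSamp <- sampleRate * duration / 1000
  if (nSamp < 10 * rotations)
    stop(sprintf(
      "undersampled spiral: %g rotations in %g ms needs a command rate >= %g Hz",
      rotations, duration, 1e4 * rotations / duration))
  tt <- seq(0, 1, length.out = floor(nSamp) + 1)
  s <- if (parameterization == "time") tt else {
    # constant speed along the arc: invert the (approximate) arc length,
    # which for r = R(1 - s) with many turns grows like 1 - (1 - s)^2
    1 - sqrt(1 - tt)
  }
  r <- (diameter / 2) * (1 - s)
  th <- 2 * pi * rotations * s
  new("SpiralScan", outerDiameter = diameter, rotations = rotations,
      duration = duration, sampleRate = sampleRate,
      waypoints = cbind(x = r * cos(th), y = r * sin(th)))
}

#' Total duration of a repeated spiral schedule
#'
#' @param perScanDuration Duration of one spiral, milliseconds.
#' @param repeats Number of back-to-back repeats.
#' @return List with \code{ms} and \code{seconds}. 175 repeats of a
#'   16 ms spiral give 2.8 s.
#' @export
repeatSchedule <- function(perScanDuration, repeats) {
  if (perScanDuration <= 0 || repeats <= 0)
    stop("duration and repeats must be positive")
  ms <- perScanDuration * repeats
  list(ms = ms, seconds = ms / 1000)
}

#' Laser power budget for M-target photostimulation
#'
#' Splitting the beam into M beamlets divides the peak power per target
#' by M, so the two-photon excitation per cell scales as (P_peak / M)^2.
#' At fixed average power, peak power is inversely proportional to the
#' repetition rate: halving f_rep quadruples the per-cell two-photon
#' dose. The relative dose reported here is (P_ave / (f_rep M))^2 up to
#' a pulse-shape constant.
#'
#' @param laser A [LaserConfig-class].
#' @return List with \code{perCellAveragePower} (mW),
#'   \code{peakPowerTotal} (P_ave / f_rep, energy-per-pulse units) and
#'   \code{relativeDose} (arbitrary units).
#' @examples
#' b <- powerBudget(laserConfig(5e5, 300, 83))
#' round(b$perCellAveragePower, 1)  # 3.6 mW/cell
#' @export
powerBudget <- function(laser) {
  validObject(laser)
  m <- as.numeric(laser@nTargets)
  list(perCellAveragePower = laser@averagePower / m,
       peakPowerTotal = laser@averagePower / laser@repRate,
       relativeDose = (laser@averagePower / (laser@repRate * m))^2)
}

#' Construct a laser configuration
#'
#' @param repRate Pulse repetition rate, Hz.
#' @param averagePower Total average power, mW.
#' @param nTargets Number of simultaneous targets M.
#' @return A [LaserConfig-class].
#' @export
laserConfig <- function(repRate, averagePower, nTargets = 1L)
  new("LaserConfig", repRate = repRate, averagePower = averagePower,
      nTargets = as.integer(nTargets))

#' Rescale stimulation power for a new duration at equal dose
#'
#' Two dose conventions: \code{constant_energy} keeps P * T constant
#' (equal delivered pulse energy), giving P' = P T / T';
#' \code{constant_power_sq_time} keeps P^2 * T constant (equal
#' integrated two-photon excitation, the convention used when comparing
#' spiral durations), giving P' = P sqrt(T / T').
#'
#' @param refDuration Reference duration, ms.
#' @param refPower Reference power, mW.
#' @param newDuration New duration, ms.
#' @param mode "constant_energy" or "constant_power_sq_time".
#' @return Power in mW for the new duration.
#' @examples
#' equalDosePower(20, 2.25, 10, "constant_energy")  # 4.5 mW
#' @export
equalDosePower <- function(refDuration, refPower, newDuration,
                           mode = c("constant_energy",
                                    "constant_power_sq_time")) {
  mode <- match.arg(mode)
  if (refDuration <= 0 || newDuration <= 0 || refPower <= 0)
    stop("durations and power must be positive")
  switch(mode,
    constant_energy = refPower * refDuration / newDuration,
    constant_power_sq_time = refPower * sqrt(refDuration / newDuration))
}

#' Volumetric imaging rate
#'
#' With an intrinsic frame rate of ~30 fps (33.33 ms frame period) and a
#' settle wait of 10-17 ms between frames for the tunable lens to reach
#' its new focal length, the volume rate over nPlanes planes is
#' 1000 / (nPlanes * (framePeriod + settleWait)) volumes per second.
#'
#' @param nPlanes Imaging planes per volume.
#' @param framePeriod Frame period, ms (default 33.33).
#' @param settleWait Inter-frame settle wait, ms (default 16.67).
#' @return Volumes per second.
#' @examples
#' volumetricRate(3)  # 6.67 vol/s
#' @export
volumetricRate <- function(nPlanes, framePeriod = 33.33, settleWait = 16.67) {
  if (nPlanes <= 0 || framePeriod <= 0 || settleWait < 0)
    stop("invalid timing parameters")
  1000 / (nPlanes * (framePeriod + settleWait))
}

#' Laser pulses delivered in a stimulation window
#'
#' @param duration Window duration, ms.
#' @param repRate Repetition rate, Hz.
#' @return floor(duration * repRate / 1000), the whole pulses delivered.
#' @export
pulsesDelivered <- function(duration, repRate) {
  if (duration <= 0 || repRate <= 0) stop("inputs must be positive")
  floor(duration * repRate / 1000)
}

#' Assemble a stimulation plan
#'
#' @param spiral A [SpiralScan-class].
#' @param repeats Back-to-back repeats of the spiral.
#' @param laser A [LaserConfig-class].
#' @return A [StimPlan-class] with the per-cell power from
#'   [powerBudget()].
#' @export
stimPlan <- function(spiral, repeats, laser) {
  new("StimPlan", spiral = spiral, repeats = as.integer(repeats),
      totalDuration = spiral@duration * repeats,
      perCellPower = powerBudget(laser)$perCellAveragePower, laser = laser)
}

#' Read / write a stimulation plan as JSON; export a trajectory as CSV
#'
#' @param plan A [StimPlan-class].
#' @param path Output path.
#' @return \code{writeStimPlan} / \code{writeTrajectory}: \code{path}
#'   invisibly; \code{readStimPlan}: a [StimPlan-class].
#' @export
writeStimPlan <- function(plan, path) {
  jsonlite::write_json(list(
    spiral = list(outer_diameter = plan@spiral@outerDiameter,
                  rotations = plan@spiral@rotations,
                  duration_ms = plan@spiral@duration,
                  sample_rate = plan@spiral@sampleRate),
    repeats = plan@repeats,
    total_duration_ms = plan@totalDuration,
    per_cell_power_mw = plan@perCellPower,
    laser = list(rep_rate = plan@laser@repRate,
                 average_power_mw = plan@laser@averagePower,
                 n_targets = plan@laser@nTargets)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStimPlan
#' @export
readStimPlan <- function(path) {
  j <- jsonlite::fromJSON(path)
  sp <- spiralTrajectory(j$spiral$outer_diameter, j$spiral$rotations,
                         j$spiral$duration_ms, j$spiral$sample_rate)
  stimPlan(sp, j$repeats,
           laserConfig(j$laser$rep_rate, j$laser$average_power_mw,
                       j$laser$n_targets))
}

#' @rdname writeStimPlan
#' @param spiral A [SpiralScan-class] whose waypoints to export.
#' @export
writeTrajectory <- function(spiral, path) {
  utils::write.csv(data.frame(x_um = spiral@waypoints[, 1],
                              y_um = spiral@waypoints[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "SpiralScan", function(object) {
  cat(sprintf(
    "SpiralScan: %g um outer diameter, %g rotations, %g ms, %d waypoints\n",
    object@outerDiameter, object@rotations, object@duration,
    nrow(object@waypoints)))
})

setMethod("show", "StimPlan", function(object) {
  cat(sprintf(
    "StimPlan: %d x %g ms spirals = %g ms total, %.2f mW/cell over %d cells\n",
    object@repeats, object@spiral@duration, object@totalDuration,
    object@perCellPower, object@laser@nTargets))
})
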