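#' Radial Zernike polynomials used for defocus and spherical aberration
#'
#' The rotationally symmetric Zernike terms Z20 (defocus), Z40
#' (first-order spherical) and Z60 (second-order spherical) on the unit
#' pupil disk, in the sqrt(2n+1)-normalized convention:
#' \deqn{Z_2^0 = \sqrt3 (2\rho^2 - 1)}
#' \deqn{Z_4^0 = \sqrt5 (6\rho^4 - 6\rho^2 + 1)}
#' \deqn{Z_6^0 = \sqrt7 (20\rho^6 - 30\rho^4 + 12\rho^2 - 1)}
#'
#' @param m Radial order: 2, 4 or 6.
#' @param rho2 Squared unit-disk radius (numeric, any shape).
#' @return Polynomial values, same shape as \code{rho2}.
#' @export
zernikeRadial <- function(m, rho2) {
  switch(as.character(m),
    "2" = sqrt(3) * (2 * rho2 - 1),
    "4" = sqrt(5) * (6 * rho2^2 - 6 * rho2 + 1),
    "6" = sqrt(7) * (20 * rho2^3 - 30 * rho2^2 + 12 * rho2 - 1),
    stop("m must be 2, 4 or 6"))
}

#' Zernike defocus coefficients for an axial focal shift
#'
#' Coefficients C20, C40, C60 (in waves) that, combined with the
#' corresponding Zernike polynomials, refocus the beam by z microns into
#' a medium of index n while compensating the first- and second-order
#' spherical aberration that defocusing introduces. With k = 2*pi/lambda
#' and sin(alpha) = effectiveNA / n:
#' \deqn{C_2^0 = \frac{n k z \sin^2\alpha}{8\pi\sqrt3}
#'   (1 + \tfrac14 \sin^2\alpha + \tfrac{9}{80}\sin^4\alpha +
#'    \tfrac{1}{16}\sin^6\alpha)}
#' \deqn{C_4^0 = \frac{n k z \sin^4\alpha}{96\pi\sqrt5}
#'   (1 + \tfrac34 \sin^2\alpha + \tfrac{15}{18}\sin^4\alpha)}
#' \deqn{C_6^0 = \frac{n k z \sin^6\alpha}{640\pi\sqrt7}
#'   (1 + \tfrac54 \sin^2\alpha)}
#' All three are linear in z. These are the Zernike expansion of the
#' exact (nonparaxial) defocus phase n k z sqrt(1 - sin^2(alpha) rho^2),
#' truncated at sixth radial order.
#'
#' @param m Radial order: 2, 4 or 6.
#' @param z Axial shift in microns (positive = deeper into the sample).
#' @param optics An [OpticalConfig-class]; uses \code{effectiveNA}.
#' @return Coefficient in waves (cycles), same length as \code{z}.
#' @export
zernikeCoef <- function(m, z, optics) {
  n <- optics@refractiveIndex
  k <- 2 * pi / optics@wavelength
  s2 <- (optics@effectiveNA / n)^2
  base <- n * k * z
  switch(as.character(m),
    "2" = base * s2 / (8 * pi * sqrt(3)) *
      (1 + s2 / 4 + 9 / 80 * s2^2 + s2^3 / 16),
    "4" = base * s2^2 / (96 * pi * sqrt(5)) *
      (1 + 3 / 4 * s2 + 15 / 18 * s2^2),
    "6" = base * s2^3 / (640 * pi * sqrt(7)) * (1 + 5 / 4 * s2),
    stop("m must be 2, 4 or 6"))
}

#' Bundle of Zernike defocus evaluators
#'
#' Convenience container pairing the three polynomial evaluators with
#' their coefficient functions of z for a given optical configuration.
#'
#' @param optics An [OpticalConfig-class].
#' @return List with functions \code{z20, z40, z60} (of rho2) and
#'   \code{c20, c40, c60} (of z, microns; waves).
#' @export
zernikeDefocusModel <- function(optics) {
  list(
    z20 = function(rho2) zernikeRadial(2, rho2),
    z40 = function(rho2) zernikeRadial(4, rho2),
    z60 = function(rho2) zernikeRadial(6, rho2),
    c20 = function(z) zernikeCoef(2, z, optics),
    c40 = function(z) zernikeCoef(4, z, optics),
    c60 = function(z) zernikeCoef(6, z, optics)
  )
}

# unwrapped defocus phase (radians) on the pupil grid; 0 outside pupil
defocusPhaseRaw <- function(z, optics, grid = pupilGrid(optics)) {
  waves <- zernikeRadial(2, grid$rho2) * zernikeCoef(2, z, optics) +
    zernikeRadial(4, grid$rho2) * zernikeCoef(4, z, optics) +
    zernikeRadial(6, grid$rho2) * zernikeCoef(6, z, optics)
  ph <- 2 * pi * waves
  ph[!grid$pupil] <- 0
  ph
}

#' Aberration-compensated defocus phase mask
#'
#' The pure defocus hologram 2*pi*[Z20 C20(z) + Z40 C40(z) + Z60 C60(z)]
#' wrapped to [0, 2*pi): displayed alone it shifts the focus axially by
#' z microns while correcting the defocus-induced first- and
#' second-order spherical aberration. Before wrapping the phase is
#' linear in z.
#'
#' @param z Axial shift in microns. Values beyond the characterized
#'   +/- 300 micron range trigger a warning.
#' @param optics An [OpticalConfig-class].
#' @return A [PhaseMask-class].
#' @examples
#' m <- zernikeDefocusPhase(50, opticalConfig(slmPixels = 64))
#' @export
zernikeDefocusPhase <- function(z, optics) {
  if (abs(z) > 300)
    warning("|z| = ", abs(z), " um is beyond the characterized 300 um range")
  new("PhaseMask", phase = wrapPhase(defocusPhaseRaw(z, optics)),
      optics = optics)
}

wrapPhase <- function(phase) {
  w <- phase %% (2 * pi)
  # guard against 2*pi appearing from floating-point roundoff
  w[w >= 2 * pi] <- 0
  w
}
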