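#' Construct an optical configuration
#'
#' Defaults describe the photostimulation path of a dual-beam two-photon
#' microscope: 1040 nm excitation through a water-immersion objective at
#' an excitation NA of about 0.35, shaped by a 512 x 512 SLM with a
#' 7.68 mm active area.
#'
#' @param wavelength Wavelength in microns (default 1.04).
#' @param refractiveIndex Immersion index (default 1.33, water).
#' @param na Numerical aperture of the photostimulation beam (default 0.35).
#' @param effectiveNA Effective NA used inside the Zernike defocus
#'   coefficients only; defaults to \code{na}. Adjusting it calibrates
#'   the commanded-vs-realized defocus without changing the pupil.
#' @param slmPixels Pixels per SLM side (default 512).
#' @param slmPitch Pixel pitch in millimetres (default 7.68/512).
#' @return An [OpticalConfig-class] object.
#' @examples
#' opt <- opticalConfig(slmPixels = 128)
#' pupilRadiusFrequency(opt)  # NA / wavelength, cycles per micron
#' @export
opticalConfig <- function(wavelength = 1.04, refractiveIndex = 1.33,
                          na = 0.35, effectiveNA = na,
                          slmPixels = 512L, slmPitch = 7.68 / 512) {
  new("OpticalConfig", wavelength = wavelength,
      refractiveIndex = refractiveIndex, na = na,
      effectiveNA = effectiveNA, slmPixels = as.integer(slmPixels),
      slmPitch = slmPitch)
}

#' Pupil radius as a spatial frequency
#'
#' @param optics An [OpticalConfig-class].
#' @return NA / wavelength in cycles per micron; spatial frequencies
#'   beyond this radius are not transmitted by the objective.
#' @export
pupilRadiusFrequency <- function(optics) optics@na / optics@wavelength

#' Spatial-frequency grid of the SLM pupil
#'
#' Maps SLM pixel (p, q) to physical spatial-frequency coordinates
#' (u, v) in cycles per micron, with the pupil circle inscribed in the
#' SLM square: u and v each span [-uMax, uMax).
#'
#' @param optics An [OpticalConfig-class].
#' @return List with matrices \code{u}, \code{v} (cycles/micron),
#'   \code{rho2} (squared unit-disk radius), logical \code{pupil}
#'   (inside the pupil), scalars \code{du} (grid step) and \code{uMax}.
#' @export
pupilGrid <- function(optics) {
  n <- optics@slmPixels
  uMax <- pupilRadiusFrequency(optics)
  du <- 2 * uMax / n
  ax <- ((0:(n - 1)) - n / 2) * du
  u <- matrix(ax, n, n, byrow = TRUE)
  v <- matrix(ax, n, n)
  rho2 <- (u^2 + v^2) / uMax^2
  list(u = u, v = v, rho2 = rho2, pupil = rho2 <= 1, du = du, uMax = uMax)
}

#' Maximum addressable lateral offset of the SLM grid
#'
#' The fastest representable tilt is set by the Nyquist limit of the
#' pupil sampling: |x| < 1/(2 du) = slmPixels / (4 uMax). Targets beyond
#' this alias back into the field and are rejected.
#'
#' @param optics An [OpticalConfig-class].
#' @return Maximum |x| (= |y|) in microns.
#' @export
addressableRange <- function(optics) {
  g <- pupilGrid(optics)
  1 / (2 * g$du)
}

#' Read / write an optical configuration as YAML
#'
#' @param path File path.
#' @return \code{readOpticalConfig} returns an [OpticalConfig-class];
#'   \code{writeOpticalConfig} returns \code{path} invisibly.
#' @export
readOpticalConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("wavelength", "refractive_index", "na", "effective_na",
             "slm_pixels", "slm_pitch")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown optical config keys: ", paste(bad, collapse = ", "))
  opticalConfig(
    wavelength = y$wavelength %||% 1.04,
    refractiveIndex = y$refractive_index %||% 1.33,
    na = y$na %||% 0.35,
    effectiveNA = y$effective_na %||% y$na %||% 0.35,
    slmPixels = y$slm_pixels %||% 512L,
    slmPitch = y$slm_pitch %||% (7.68 / 512)
  )
}

#' @rdname readOpticalConfig
#' @param optics An [OpticalConfig-class] to serialize.
#' @export
writeOpticalConfig <- function(optics, path) {
  yaml::write_yaml(list(
    wavelength = optics@wavelength,
    refractive_index = optics@refractiveIndex,
    na = optics@na,
    effective_na = optics@effectiveNA,
    slm_pixels = optics@slmPixels,
    slm_pitch = optics@slmPitch
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf(
    "OpticalConfig: lambda %g um, n %g, NA %g (effective %g), SLM %d px @ %.4g mm\n",
    object@wavelength, object@refractiveIndex, object@na,
    object@effectiveNA, object@slmPixels, object@slmPitch))
})
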