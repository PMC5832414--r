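# swap quadrants so DC moves between corner and centre (even sizes only,
# where shift and inverse shift coincide)
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2))]
}

# nonparaxial axial wavenumber k_z(u, v) = 2*pi*sqrt((n/lambda)^2 - u^2 - v^2)
axialWavenumber <- function(optics, grid = pupilGrid(optics)) {
  arg <- (optics@refractiveIndex / optics@wavelength)^2 -
    grid$u^2 - grid$v^2
  kz <- matrix(0, nrow(grid$u), ncol(grid$u))
  ok <- grid$pupil & arg > 0
  kz[ok] <- 2 * pi * sqrt(arg[ok])
  kz
}

#' Simulate the 3D focal intensity of a phase mask
#'
#' Debye-type angular-spectrum propagation, one FFT per z plane: the
#' pupil field P(u,v) = A(u,v) exp(i phi(u,v)) is multiplied by the
#' exact nonparaxial defocus kernel exp(i k_z(u,v) z) with
#' k_z = 2*pi*sqrt((n/lambda)^2 - u^2 - v^2) and Fourier-transformed to
#' the sample plane. The pupil is zero-padded by \code{pad} (default 2)
#' to refine the lateral sampling to 1/(2 pad uMax) microns and
#' suppress wrap-around. Energy per plane obeys Parseval's identity
#' exactly (no absorbing boundaries).
#'
#' @param mask A [PhaseMask-class].
#' @param optics An [OpticalConfig-class] matching the mask (defaults to
#'   the one attached to the mask).
#' @param zPlanes Depths to evaluate, microns (strictly increasing).
#' @param fov Optional field of view (microns): the output is cropped to
#'   the central fov x fov window. Default: the full padded grid.
#' @param pixels Optional number of output pixels per side; raises the
#'   padding so the grid pitch is at most fov/pixels. It is an error to
#'   request a pitch coarser than the Nyquist limit 1/(2 uMax) of the
#'   band-limited field.
#' @param pad Zero-padding factor (default 2).
#' @param zeroOrderFraction Fraction of unmodulated (flat-phase) pupil
#'   field added coherently before propagation, emulating residual SLM
#'   zeroth order (default 0).
#' @param blockRadius If nonempty, radius (microns) of a central disk
#'   zeroed in the z = 0 intermediate focal plane before the z stack is
#'   formed, emulating the physical zeroth-order beam block.
#' @return A [FocalStack-class] with photonOrder = 2.
#' @examples
#' opt <- opticalConfig(slmPixels = 64)
#' st <- propagateFocalStack(zernikeDefocusPhase(0, opt), opt, zPlanes = 0)
#' @export
propagateFocalStack <- function(mask, optics = mask@optics, zPlanes,
                                fov = NULL, pixels = NULL, pad = 2,
                                zeroOrderFraction = 0, blockRadius = NULL) {
  if (!length(zPlanes)) stop("zPlanes must be non-empty")
  if (is.unsorted(zPlanes, strictly = TRUE) && length(zPlanes) > 1)
    stop("zPlanes must be strictly increasing")
  g <- pupilGrid(optics)
  n <- optics@slmPixels
  nyq <- 1 / (2 * g$uMax)
  if (!is.null(pixels)) {
    if (is.null(fov)) stop("pixels requires fov")
    want <- fov / pixels
    if (want > nyq + 1e-12)
      stop(sprintf(
        "fov/pixels = %.3f um undersamples the field (Nyquist pitch %.3f um)",
        want, nyq))
    pad <- max(pad, ceiling(1 / (n * g$du * want)))
  }
  np <- as.integer(round(n * pad))
  if (np %% 2L) np <- np + 1L
  dx <- 1 / (np * g$du)

  P <- exp(1i * mask@phase)
  P[!g$pupil] <- 0 + 0i
  if (zeroOrderFraction > 0) {
    flat <- ifelse(g$pupil, 1 + 0i, 0 + 0i)
    P <- (1 - zeroOrderFraction) * P + zeroOrderFraction * flat
  }
  kz <- axialWavenumber(optics, g)
  i0 <- np / 2 - n / 2 + 1
  idx <- i0:(i0 + n - 1)

  embed <- function(field) {
    big <- matrix(0 + 0i, np, np)
    big[idx, idx] <- field
    big
  }
  toFocal <- function(big) fftshift2(stats::fft(fftshift2(big))) / np

  if (!is.null(blockRadius)) {
    # image the z = 0 plane, zero the central disk, return to the pupil
    E0 <- toFocal(embed(P))
    ax <- ((0:(np - 1)) - np / 2) * dx
    R2 <- outer(ax^2, ax^2, "+")
    E0[R2 <= blockRadius^2] <- 0 + 0i
    Pb <- fftshift2(stats::fft(fftshift2(E0), inverse = TRUE)) / np
    P <- Pb[idx, idx]
  }

  ax <- ((0:(np - 1)) - np / 2) * dx
  if (!is.null(fov)) {
    keep <- which(abs(ax) <= fov / 2)
  } else keep <- seq_len(np)
  xs <- ax[keep]

  out <- array(0, dim = c(length(keep), length(keep), length(zPlanes)))
  for (iz in seq_along(zPlanes)) {
    E <- toFocal(embed(P * exp(1i * kz * zPlanes[iz])))
    out[, , iz] <- Mod(E[keep, keep])^2
  }
  new("FocalStack", intensity = out, xs = xs, ys = xs,
      zs = as.numeric(zPlanes), photonOrder = 2L)
}

#' Two-photon signal of a focal stack
#'
#' @param stack A [FocalStack-class].
#' @return Array of intensity^2 when photonOrder is 2, else the
#'   intensity itself.
#' @export
twoPhotonSignal <- function(stack) {
  if (stack@photonOrder == 2L) stack@intensity^2 else stack@intensity
}

#' Evaluate the focal field at arbitrary 3D points
#'
#' Direct (non-FFT) evaluation of the Debye integral at continuous
#' sample coordinates; slow per point but free of grid quantization.
#' Used for subgrid peak refinement and on-axis profiles.
#'
#' @param mask A [PhaseMask-class].
#' @param pts Matrix with columns x, y, z (microns).
#' @param optics An [OpticalConfig-class] (defaults to the mask's).
#' @return Numeric vector of intensities |E|^2 (same normalization as
#'   [propagateFocalStack()]'s full grid up to a constant).
#' @export
fieldIntensityAt <- function(mask, pts, optics = mask@optics) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  g <- pupilGrid(optics)
  kz <- axialWavenumber(optics, g)
  sel <- g$pupil
  P <- exp(1i * mask@phase[sel])
  u <- g$u[sel]; v <- g$v[sel]; kzv <- kz[sel]
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ph <- -2 * pi * (u * pts[i, 1] + v * pts[i, 2]) + kzv * pts[i, 3]
    out[i] <- Mod(sum(P * exp(1i * ph)))^2
  }
  out / optics@slmPixels^2
}

#' Locate foci in a focal stack
#'
#' Finds local maxima of the two-photon signal above
#' \code{relThreshold} times the global maximum, applies non-maximum
#' suppression at \code{minSeparation} (greedy, strongest first; ties
#' broken by lowest z, then y, then x), and refines each peak to
#' subvoxel precision with a 3-point quadratic fit per axis.
#'
#' @param stack A [FocalStack-class].
#' @param minSeparation Minimum separation between reported foci, microns.
#' @param relThreshold Fraction of the global maximum (default 0.1).
#' @return data.frame with columns x, y, z (microns) and peak
#'   (two-photon signal); zero rows if nothing exceeds the threshold.
#' @export
findFoci <- function(stack, minSeparation = 5, relThreshold = 0.1) {
  sig <- twoPhotonSignal(stack)
  d <- dim(sig)
  thr <- relThreshold * max(sig)
  cand <- which(sig >= thr & sig > 0)
  if (!length(cand)) return(emptyFoci())
  ai <- arrayInd(cand, d)
  # local maximum within the 3x3x3 neighbourhood
  isMax <- vapply(seq_along(cand), function(k) {
    iy <- ai[k, 1]; ix <- ai[k, 2]; iz <- ai[k, 3]
    nb <- sig[max(1, iy - 1):min(d[1], iy + 1),
              max(1, ix - 1):min(d[2], ix + 1),
              max(1, iz - 1):min(d[3], iz + 1)]
    sig[iy, ix, iz] >= max(nb)
  }, logical(1))
  ai <- ai[isMax, , drop = FALSE]
  vals <- sig[cbind(ai[, 1], ai[, 2], ai[, 3])]
  pos <- cbind(x = stack@xs[ai[, 2]], y = stack@ys[ai[, 1]],
               z = stack@zs[ai[, 3]])
  ord <- order(-vals, pos[, "z"], pos[, "y"], pos[, "x"])
  ai <- ai[ord, , drop = FALSE]; vals <- vals[ord]
  pos <- pos[ord, , drop = FALSE]
  keep <- logical(length(vals))
  for (k in seq_along(vals)) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    dd <- sqrt(rowSums((pos[keep, , drop = FALSE] -
                        matrix(pos[k, ], sum(keep), 3, byrow = TRUE))^2))
    if (all(dd >= minSeparation)) keep[k] <- TRUE
  }
  ai <- ai[keep, , drop = FALSE]; vals <- vals[keep]

  refine1 <- function(coords, along) {
    # 3-point quadratic vertex along one axis; clamp to half a voxel
    v0 <- sig[coords[1], coords[2], coords[3]]
    cm <- coords; cp <- coords
    cm[along] <- coords[along] - 1L; cp[along] <- coords[along] + 1L
    lim <- d[along]
    if (cm[along] < 1 || cp[along] > lim) return(0)
    vm <- sig[cm[1], cm[2], cm[3]]; vp <- sig[cp[1], cp[2], cp[3]]
    den <- vm - 2 * v0 + vp
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  res <- lapply(seq_len(nrow(ai)), function(k) {
    co <- ai[k, ]
    oy <- refine1(co, 1); ox <- refine1(co, 2); oz <- refine1(co, 3)
    stepx <- if (length(stack@xs) > 1) stack@xs[2] - stack@xs[1] else 0
    stepy <- if (length(stack@ys) > 1) stack@ys[2] - stack@ys[1] else 0
    stepz <- if (length(stack@zs) > 1) stack@zs[2] - stack@zs[1] else 0
    data.frame(x = stack@xs[co[2]] + ox * stepx,
               y = stack@ys[co[1]] + oy * stepy,
               z = stack@zs[co[3]] + oz * stepz,
               peak = vals[k])
  })
  do.call(rbind, res)
}

emptyFoci <- function()
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             peak = numeric(0))

#' Axial FWHM of the two-photon profile through a focus
#'
#' Extracts the on-axis two-photon (squared-intensity) profile through
#' the focus along z and measures its full width at half maximum by
#' linear interpolation between samples.
#'
#' @param stack A [FocalStack-class] with z sampling <= 1 micron.
#' @param focus One row of [findFoci()] output (or a list with x, y, z).
#' @return FWHM in microns.
#' @export
axialFwhm <- function(stack, focus) {
  sig <- twoPhotonSignal(stack)
  ix <- which.min(abs(stack@xs - focus$x))
  iy <- which.min(abs(stack@ys - focus$y))
  prof <- sig[iy, ix, ]
  fwhmLinear(stack@zs, prof)
}

# linear-interpolated FWHM of a sampled profile; errors if the profile
# never drops below half max on either side of the peak
fwhmLinear <- function(xs, prof) {
  ip <- which.max(prof)
  half <- prof[ip] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(ip, 2)) {
    if (prof[i - 1] < half) {
      left <- xs[i - 1] + (half - prof[i - 1]) * (xs[i] - xs[i - 1]) /
        (prof[i] - prof[i - 1])
      break
    }
  }
  for (i in seq(ip, length(prof) - 1)) {
    if (prof[i + 1] < half) {
      right <- xs[i] + (half - prof[i]) * (xs[i + 1] - xs[i]) /
        (prof[i + 1] - prof[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("profile does not drop below half maximum inside the stack")
  right - left
}

#' Targeting-error summary
#'
#' Greedy nearest-neighbour assignment between requested targets and
#' found foci (closest pair first, each focus used once), followed by
#' per-target lateral and axial displacement statistics.
#'
#' @param requested A [TargetSet-class].
#' @param found data.frame from [findFoci()].
#' @param maxDistance Pairs farther apart than this are left unmatched
#'   (microns, default 15).
#' @return List with \code{lateral} and \code{axial} (each mean, sd in
#'   microns), \code{perTarget} data.frame, and \code{unmatched}
#'   (indices of requested targets without a focus).
#' @export
targetingError <- function(requested, found, maxDistance = 15) {
  co <- requested@coords
  m <- nrow(co)
  if (!nrow(found)) {
    return(list(lateral = c(mean = NA, sd = NA),
                axial = c(mean = NA, sd = NA),
                perTarget = data.frame(), unmatched = seq_len(m)))
  }
  fp <- as.matrix(found[, c("x", "y", "z")])
  D <- outer(seq_len(m), seq_len(nrow(fp)),
             Vectorize(function(i, j) sqrt(sum((co[i, ] - fp[j, ])^2))))
  assign <- rep(NA_integer_, m)
  Dw <- D
  repeat {
    if (all(!is.finite(Dw)) || min(Dw, na.rm = TRUE) > maxDistance) break
    k <- which(Dw == min(Dw), arr.ind = TRUE)[1, ]
    assign[k[1]] <- k[2]
    Dw[k[1], ] <- Inf
    Dw[, k[2]] <- Inf
    if (all(!is.na(assign))) break
  }
  matched <- which(!is.na(assign))
  per <- do.call(rbind, lapply(matched, function(i) {
    j <- assign[i]
    data.frame(target = i,
               lateral = sqrt(sum((co[i, 1:2] - fp[j, 1:2])^2)),
               axial = abs(co[i, 3] - fp[j, 3]))
  }))
  if (is.null(per)) per <- data.frame()
  stat <- function(x) if (length(x)) c(mean = mean(x), sd = stats::sd(x))
                      else c(mean = NA, sd = NA)
  list(lateral = stat(per$lateral), axial = stat(per$axial),
       perTarget = per, unmatched = which(is.na(assign)))
}

setMethod("show", "FocalStack", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "FocalStack: %d x %d px x %d plane(s), z in [%g, %g] um, photon order %d\n",
    d[1], d[2], d[3], min(object@zs), max(object@zs), object@photonOrder))
})

#' Export / import a focal stack as multi-page TIFF + JSON sidecar
#'
#' Intensity planes go to a 32-bit float multi-page TIFF (normalized to
#' the global maximum); the grid vectors, photon order and the
#' normalization constant go to \code{<path>.json}.
#'
#' @param stack A [FocalStack-class].
#' @param path TIFF path.
#' @return \code{writeFocalStack}: \code{path} invisibly;
#'   \code{readFocalStack}: the reconstructed [FocalStack-class].
#' @export
writeFocalStack <- function(stack, path) {
  mx <- max(stack@intensity)
  if (mx == 0) mx <- 1
  pages <- lapply(seq_along(stack@zs), function(i)
    stack@intensity[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(xs = stack@xs, ys = stack@ys, zs = stack@zs,
         photon_order = stack@photonOrder, scale = mx),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFocalStack
#' @export
readFocalStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  new("FocalStack", intensity = arr, xs = meta$xs, ys = meta$ys,
      zs = meta$zs, photonOrder = as.integer(meta$photon_order))
}
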