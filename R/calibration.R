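#' Fit a 2D affine transform between SLM and imaging coordinates
#'
#' Least-squares fit of image = A %*% slm + b from burn-spot
#' correspondences (e.g. a 7 x 7 grid over 240 x 240 microns projected
#' onto an autofluorescent slide and re-imaged).
#'
#' @param slmPoints Matrix (n x 2) of commanded SLM coordinates, microns.
#' @param imagePoints Matrix (n x 2) of measured imaging coordinates.
#' @return List with \code{A} (2 x 2), \code{b} (length 2) and
#'   \code{residual} (RMS residual, microns).
#' @examples
#' g <- as.matrix(expand.grid(x = seq(-120, 120, 40), y = seq(-120, 120, 40)))
#' fitAffine(g, g)$residual
#' @export
fitAffine <- function(slmPoints, imagePoints) {
  slmPoints <- as.matrix(slmPoints); imagePoints <- as.matrix(imagePoints)
  n <- nrow(slmPoints)
  if (n < 3 || nrow(imagePoints) != n)
    stop("need at least 3 point pairs")
  X <- cbind(slmPoints, 1)
  if (qr(X)$rank < 3)
    stop("points are collinear; the affine transform is not identifiable")
  beta <- qr.solve(X, imagePoints)        # 3 x 2: rows = (a1, a2, b)
  A <- t(beta[1:2, , drop = FALSE])
  dimnames(A) <- NULL
  b <- as.numeric(beta[3, ])
  fitted <- X %*% beta
  res <- sqrt(mean(rowSums((imagePoints - fitted)^2) / 2))
  list(A = A, b = b, residual = res)
}

#' Apply an affine transform
#'
#' @param affine List with \code{A} and \code{b} as from [fitAffine()].
#' @param pts Matrix (n x 2).
#' @return Transformed matrix (n x 2).
#' @export
applyAffine <- function(affine, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  t(affine$A %*% t(pts) + affine$b)
}

#' Assemble a per-depth affine calibration
#'
#' @param depths Calibration depths, microns (default spacing 25).
#' @param transforms List of affines (from [fitAffine()]), one per depth.
#' @return An [AffineCalibration-class].
#' @export
affineCalibration <- function(depths, transforms) {
  ord <- order(depths)
  new("AffineCalibration", depths = as.numeric(depths[ord]),
      transforms = transforms[ord])
}

#' Interpolate the calibration to an arbitrary depth
#'
#' Elementwise linear interpolation of the matrix and offset between the
#' bracketing calibration depths; at a calibration depth the stored
#' transform is returned bit-exactly. Depths beyond the calibrated range
#' (plus a 25-micron margin) are an error; inside the margin the nearest
#' knot is used with a warning.
#'
#' @param cal An [AffineCalibration-class].
#' @param z Depth in microns.
#' @return An affine list (\code{A}, \code{b}, \code{residual}).
#' @export
interpAffine <- function(cal, z) {
  d <- cal@depths
  if (!length(d)) stop("empty calibration")
  if (z < min(d) - 25 || z > max(d) + 25)
    stop(sprintf("z = %g um is outside the calibrated range [%g, %g] um",
                 z, min(d), max(d)))
  hit <- which(d == z)
  if (length(hit)) return(cal@transforms[[hit[1]]])
  if (z < min(d) || z > max(d)) {
    warning(sprintf(
      "z = %g um is outside the calibrated depths; clamping to nearest knot", z))
    return(cal@transforms[[which.min(abs(d - z))]])
  }
  i <- findInterval(z, d)
  w <- (z - d[i]) / (d[i + 1] - d[i])
  t1 <- cal@transforms[[i]]; t2 <- cal@transforms[[i + 1]]
  list(A = (1 - w) * t1$A + w * t2$A,
       b = (1 - w) * t1$b + w * t2$b,
       residual = (1 - w) * (t1$residual %||% 0) + w * (t2$residual %||% 0))
}

#' Fit the SLM diffraction-efficiency model
#'
#' Least-squares fit of the separable linear decay
#' eta(x, y, z) = c0 + c1|x| + c2|y| + c3|z| to measured per-target
#' powers, then normalized so eta at the origin is 1.
#'
#' @param positions Matrix (n x 3) of target positions, microns.
#' @param measuredPowers Measured focal powers (arbitrary units).
#' @return An [EfficiencyModel-class].
#' @export
fitEfficiency <- function(positions, measuredPowers) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 5) stop("need at least 5 measurement points")
  X <- cbind(1, abs(positions[, 1]), abs(positions[, 2]), abs(positions[, 3]))
  if (qr(X)$rank < 4) stop("degenerate design: positions do not span x, y, z")
  beta <- qr.solve(X, as.numeric(measuredPowers))
  if (beta[1] <= 0) stop("fitted efficiency at the origin is nonpositive")
  res <- sqrt(mean((X %*% beta - measuredPowers)^2)) / beta[1]
  new("EfficiencyModel", coef = as.numeric(beta / beta[1]), residual = res)
}

#' Evaluate an efficiency model
#'
#' @param model An [EfficiencyModel-class].
#' @param positions Matrix (n x 3), microns.
#' @return Efficiencies clamped to (0, 1].
#' @export
predictEfficiency <- function(model, positions) {
  positions <- matrix(as.numeric(as.matrix(positions)), ncol = 3)
  eta <- model@coef[1] + model@coef[2] * abs(positions[, 1]) +
    model@coef[3] * abs(positions[, 2]) + model@coef[4] * abs(positions[, 3])
  pmin(pmax(eta, 0), 1)
}

#' Read / write a calibration as JSON
#'
#' @param cal An [AffineCalibration-class].
#' @param path JSON path.
#' @return \code{writeCalibration}: \code{path} invisibly;
#'   \code{readCalibration}: an [AffineCalibration-class].
#' @export
writeCalibration <- function(cal, path) {
  jsonlite::write_json(list(
    depths = cal@depths,
    transforms = lapply(cal@transforms, function(tr)
      list(A = tr$A, b = tr$b, residual = tr$residual %||% 0)),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  transforms <- lapply(j$transforms, function(tr) {
    A <- if (is.matrix(tr$A)) tr$A else do.call(rbind, tr$A)
    list(A = A, b = as.numeric(unlist(tr$b)),
         residual = as.numeric(tr$residual))
  })
  affineCalibration(as.numeric(j$depths), transforms)
}

setMethod("show", "AffineCalibration", function(object) {
  cat(sprintf("AffineCalibration: %d depth(s) in [%g, %g] um\n",
              length(object@depths), min(object@depths), max(object@depths)))
})

setMethod("show", "EfficiencyModel", function(object) {
  cat(sprintf(
    "EfficiencyModel: eta = %.4g + %.3g|x| + %.3g|y| + %.3g|z| (RMS %.3g)\n",
    object@coef[1], object@coef[2], object@coef[3], object@coef[4],
    object@residual))
})
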