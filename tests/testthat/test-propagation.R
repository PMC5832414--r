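test_that("propagation conserves energy per plane (Parseval)", {
  opt <- smallOptics(64L)
  mask <- superpositionHologram(targetSet(cbind(c(5, -12), c(3, 8),
                                               c(0, 25))), opt)
  g <- pupilGrid(opt)
  pupilEnergy <- sum(g$pupil)      # unit-amplitude pupil
  st <- propagateFocalStack(mask, zPlanes = c(-10, 0, 25))
  for (i in seq_along(st@zs)) {
    planeEnergy <- sum(st@intensity[, , i])
    expect_lt(abs(planeEnergy - pupilEnergy) / pupilEnergy, 1e-6)
  }
})

test_that("a zero-phase mask focuses at the origin with an Airy-like core", {
  opt <- smallOptics(64L)
  st <- propagateFocalStack(zernikeDefocusPhase(0, opt), zPlanes = 0,
                            fov = 40)
  foci <- findFoci(st, minSeparation = 3, relThreshold = 0.5)
  expect_equal(nrow(foci), 1)
  expect_lt(abs(foci$x), 0.5)
  expect_lt(abs(foci$y), 0.5)
  # radial monotone decay over the core
  mid <- which.min(abs(st@xs))
  iy <- which.min(abs(st@ys))
  core <- st@intensity[iy, mid:(mid + 2), 1]
  expect_true(all(diff(core) < 0))
})

test_that("the shift theorem holds exactly on the unpadded grid", {
  opt <- smallOptics(64L)
  g <- pupilGrid(opt)
  dx <- 1 / (64 * g$du)
  shiftPix <- 5L
  base <- zernikeDefocusPhase(13, opt)
  tilt <- superpositionHologram(targetSet(cbind(shiftPix * dx, 0, 0)), opt)
  combo <- new("PhaseMask",
               phase = holostim:::wrapPhase(base@phase + tilt@phase),
               optics = opt)
  # tilt phase exists only inside the pupil, so compare within the
  # image of the pupil field: intensities must be circularly shifted
  i0 <- propagateFocalStack(base, zPlanes = 0, pad = 1)@intensity[, , 1]
  i1 <- propagateFocalStack(combo, zPlanes = 0, pad = 1)@intensity[, , 1]
  shifted <- i0[, c(64 - shiftPix + seq_len(shiftPix), 1:(64 - shiftPix))]
  expect_equal(i1, shifted, tolerance = 1e-10)
})

test_that("two-photon signal is the square of intensity", {
  opt <- smallOptics(64L)
  st <- propagateFocalStack(zernikeDefocusPhase(0, opt), zPlanes = 0)
  expect_equal(twoPhotonSignal(st), st@intensity^2)
  st1 <- new("FocalStack", intensity = st@intensity, xs = st@xs,
             ys = st@ys, zs = st@zs, photonOrder = 1L)
  expect_equal(twoPhotonSignal(st1), st@intensity)
})

test_that("axial FWHM scales as 1/NA^2 and matches a Gaussian closed form", {
  # synthetic Gaussian profile: FWHM = 2.355 sigma exactly
  sigma <- 4
  zs <- seq(-20, 20, by = 0.5)
  prof <- exp(-zs^2 / (2 * sigma^2))
  st <- new("FocalStack",
            intensity = array(prof, dim = c(1, 1, length(zs))),
            xs = 0, ys = 0, zs = zs, photonOrder = 1L)
  got <- axialFwhm(st, data.frame(x = 0, y = 0, z = 0))
  expect_equal(got, 2 * sqrt(2 * log(2)) * sigma, tolerance = 1e-3)

  fwhmAtNA <- function(na, n = 128L) {
    opt <- smallOptics(n, na = na)
    zr <- if (na > 0.5) 6 else 25
    zs <- seq(-zr, zr, by = if (na > 0.5) 0.25 else 1)
    prof <- fieldIntensityAt(zernikeDefocusPhase(0, opt), cbind(0, 0, zs))^2
    holostim:::fwhmLinear(zs, prof)
  }
  f35 <- fwhmAtNA(0.35)
  f70 <- fwhmAtNA(0.70)
  expect_lt(abs(f70 / f35 - 0.25), 0.2 * 0.25)
})

test_that("axialFwhm errors when the stack is too shallow", {
  zs <- seq(-2, 2, by = 0.5)
  st <- new("FocalStack",
            intensity = array(exp(-zs^2 / 200), dim = c(1, 1, length(zs))),
            xs = 0, ys = 0, zs = zs, photonOrder = 1L)
  expect_error(axialFwhm(st, data.frame(x = 0, y = 0, z = 0)),
               "half maximum")
})

test_that("findFoci respects threshold and suppression contracts", {
  opt <- smallOptics(128L)
  co <- cbind(x = c(-30, 0, 30), y = c(15, -25, 5), z = c(-30, 0, 30))
  mask <- superpositionHologram(targetSet(co), opt)
  st <- propagateFocalStack(mask, zPlanes = c(-30, 0, 30), fov = 100)
  foci <- findFoci(st, minSeparation = 10, relThreshold = 0.2)
  expect_equal(nrow(foci), 3)
  err <- targetingError(targetSet(co), foci)
  expect_length(err$unmatched, 0)
  expect_lt(err$lateral["mean"], 1)
  # threshold 1 keeps only the global maximum
  expect_lte(nrow(findFoci(st, minSeparation = 1, relThreshold = 1)), 1)
})

test_that("targeting error is zero for a perfect match and reports spurious foci", {
  ts <- targetSet(cbind(c(0, 10), c(0, -5), c(0, 20)))
  found <- data.frame(x = c(0, 10), y = c(0, -5), z = c(0, 20),
                      peak = c(1, 1))
  err <- targetingError(ts, found)
  expect_equal(unname(err$lateral["mean"]), 0)
  expect_equal(unname(err$axial["mean"]), 0)
  # an extra focus leaves one requested target matched, none unmatched,
  # while a missing focus leaves a target unmatched
  errMissing <- targetingError(ts, found[1, ])
  expect_equal(errMissing$unmatched, 2L)
  errEmpty <- targetingError(ts, found[0, ])
  expect_equal(errEmpty$unmatched, c(1L, 2L))
})

test_that("undersampled output grids are rejected", {
  opt <- smallOptics(64L)
  mask <- zernikeDefocusPhase(0, opt)
  expect_error(propagateFocalStack(mask, zPlanes = 0, fov = 100,
                                   pixels = 10), "undersamples")
})

test_that("zeroth-order handling: block removes the central spot", {
  opt <- smallOptics(64L)
  # an off-axis target plus a strong unmodulated component
  mask <- superpositionHologram(targetSet(cbind(20, 0, 0)), opt)
  stRaw <- propagateFocalStack(mask, zPlanes = 0, fov = 60,
                               zeroOrderFraction = 0.3)
  stBlk <- propagateFocalStack(mask, zPlanes = 0, fov = 60,
                               zeroOrderFraction = 0.3, blockRadius = 5)
  mid <- which.min(abs(stRaw@xs))
  expect_gt(stRaw@intensity[mid, mid, 1], 10 * stBlk@intensity[mid, mid, 1])
})
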