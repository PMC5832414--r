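test_that("single on-axis target gives a constant zero-phase mask", {
  opt <- smallOptics(64L)
  mask <- superpositionHologram(targetSet(cbind(0, 0, 0)), opt)
  expect_true(all(mask@phase == 0))
})

test_that("every mask honours the phase-only contract", {
  opt <- smallOptics(64L)
  masks <- list(
    superpositionHologram(targetSet(cbind(c(10, -20), c(5, 0), c(0, 40))),
                          opt),
    zernikeDefocusPhase(77, opt),
    gs3dHologram(diskTarget(opt), 0, opt, iterations = 3L, seed = 7L))
  for (m in masks) {
    expect_true(all(m@phase >= 0 & m@phase < 2 * pi))
    expect_equal(Mod(exp(1i * m@phase)), matrix(1, 64, 64))
  }
})

test_that("a lateral target produces a focus at the requested position", {
  opt <- smallOptics(128L)
  mask <- superpositionHologram(targetSet(cbind(10, 0, 0)), opt)
  foci <- fociFor(mask, zPlanes = 0, fov = 60)
  expect_equal(nrow(foci), 1)
  expect_lt(abs(foci$x - 10), 1)
  expect_lt(abs(foci$y - 0), 1)
})

test_that("a 3D multi-target mask places every focus within tolerance", {
  opt <- smallOptics(128L)
  co <- cbind(x = c(-40, 0, 35, 20), y = c(10, -30, 25, 0),
              z = c(-40, 0, 0, 40))
  mask <- superpositionHologram(targetSet(co), opt)
  for (i in seq_len(nrow(co))) {
    # local subgrid search around the request, free of stack gridding
    xs <- co[i, 1] + seq(-2, 2, by = 0.25)
    prof <- fieldIntensityAt(mask, cbind(xs, co[i, 2], co[i, 3]))
    expect_lt(abs(xs[which.max(prof)] - co[i, 1]), 1)
    zs <- co[i, 3] + seq(-4, 4, by = 0.5)
    profz <- fieldIntensityAt(mask, cbind(co[i, 1], co[i, 2], zs))
    expect_lt(abs(zs[which.max(profz)] - co[i, 3]), 3)
  }
})

test_that("per-focus two-photon intensity scales with the squared weight", {
  opt <- smallOptics(128L)
  co <- cbind(x = c(-40, 0, 40), y = c(-20, 30, -10), z = c(0, 0, 0))
  w <- c(1, 0.8, 0.6)
  mask <- superpositionHologram(targetSet(co, w), opt)
  inten <- fieldIntensityAt(mask, co)      # |E|^2 ~ A^2
  scale <- mean(inten / w^2)               # proportionality constant
  expect_true(all(abs(inten / (scale * w^2) - 1) < 0.15))
})

test_that("union hologram is the phase of summed fields, not summed phases", {
  opt <- smallOptics(64L)
  a <- targetSet(cbind(15, 0, 0))
  b <- targetSet(cbind(-10, 20, 30))
  un <- targetSet(rbind(targetCoords(a), targetCoords(b)))
  fSum <- superpositionField(a, opt) + superpositionField(b, opt)
  mUnion <- superpositionHologram(un, opt)
  g <- pupilGrid(opt)
  expSum <- holostim:::wrapPhase(Arg(fSum))
  expSum[!g$pupil] <- 0
  expect_equal(mUnion@phase, expSum)
  mPhaseSum <- holostim:::wrapPhase(
    superpositionHologram(a, opt)@phase + superpositionHologram(b, opt)@phase)
  expect_false(isTRUE(all.equal(mUnion@phase, mPhaseSum)))
})

test_that("targets beyond the addressable range raise a named error", {
  opt <- smallOptics(64L)
  rng <- addressableRange(opt)
  expect_error(
    superpositionHologram(targetSet(cbind(c(0, rng + 5), 0, 0)), opt),
    "target 2")
  expect_error(targetSet(matrix(numeric(0), 0, 3)))
})

test_that("GS hologram converges toward a disk target", {
  opt <- smallOptics(64L)
  disk <- diskTarget(opt, diameter = 12)
  m1 <- gs3dHologram(disk, 0, opt, iterations = 1L, seed = 3L)
  m50 <- gs3dHologram(disk, 0, opt, iterations = 50L, seed = 3L)
  corrFor <- function(m) {
    st <- propagateFocalStack(m, zPlanes = 0, pad = 1)
    stats::cor(as.numeric(st@intensity[, , 1]), as.numeric(disk^2))
  }
  expect_gt(corrFor(m50), corrFor(m1))
  expect_gt(corrFor(m50), 0.5)
  tr <- attr(m50, "trace")
  expect_true(length(tr) > 1)
})

test_that("GS with a single bright pixel recovers a tilt hologram", {
  opt <- smallOptics(64L)
  grid <- gsFocalGrid(opt)
  ix <- which.min(abs(grid$xs - 12))
  amp <- matrix(0, 64, 64)
  iy <- which.min(abs(grid$ys - 0))
  amp[iy, ix] <- 1
  mask <- gs3dHologram(amp, 0, opt, iterations = 20L, seed = 5L)
  xs <- grid$xs[ix] + seq(-2, 2, by = 0.2)
  prof <- fieldIntensityAt(mask, cbind(xs, 0, 0))
  expect_lt(abs(xs[which.max(prof)] - grid$xs[ix]), 1)
})

test_that("GS is deterministic for a fixed seed and errors on empty target", {
  opt <- smallOptics(64L)
  disk <- diskTarget(opt)
  m1 <- gs3dHologram(disk, 0, opt, iterations = 5L, seed = 11L)
  m2 <- gs3dHologram(disk, 0, opt, iterations = 5L, seed = 11L)
  expect_identical(m1@phase, m2@phase)
  expect_error(gs3dHologram(matrix(0, 64, 64), 0, opt), "all-zero")
})

test_that("efficiency compensation rescales weights as 1/sqrt(eta)", {
  uniformEta <- new("EfficiencyModel", coef = c(1, 0, 0, 0), residual = 0)
  ts <- targetSet(cbind(c(0, 100), 0, 0), c(1, 1))
  expect_equal(targetWeights(compensateEfficiency(ts, uniformEta)),
               c(1, 1))
  decay <- new("EfficiencyModel", coef = c(1, -0.0075, 0, 0), residual = 0)
  # eta(100,0,0) = 0.25 -> weight doubles
  comp <- compensateEfficiency(ts, decay)
  expect_equal(targetWeights(comp)[2] / targetWeights(comp)[1], 2)
  dead <- new("EfficiencyModel", coef = c(1, -0.02, 0, 0), residual = 0)
  expect_error(compensateEfficiency(ts, dead), "nonpositive")
})
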