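grid49 <- function() as.matrix(expand.grid(x = seq(-120, 120, length.out = 7),
                                           y = seq(-120, 120, length.out = 7)))

rotScale <- function(deg = 5, s = 1.02, shift = c(3, -2)) {
  th <- deg * pi / 180
  list(A = s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
       b = shift)
}

test_that("identity correspondences give the identity transform", {
  g <- grid49()
  fit <- fitAffine(g, g)
  expect_equal(fit$A, diag(2), tolerance = 1e-12)
  expect_equal(fit$b, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
})

test_that("a known affine is recovered exactly from noiseless points", {
  g <- grid49()
  tr <- rotScale()
  fit <- fitAffine(g, applyAffine(tr, g))
  expect_lt(max(abs(fit$A - tr$A)), 1e-9)
  expect_lt(max(abs(fit$b - tr$b)), 1e-9)
  expect_lt(fit$residual, 1e-9)
  # exact left inverse on its own forward-mapped points
  expect_equal(applyAffine(fit, g), applyAffine(tr, g), tolerance = 1e-9)
})

test_that("with Gaussian noise the residual matches sigma and parameters stay close", {
  sigma <- 0.3
  fx <- makeCalibrationFixture(list(rotScale()), depths = 0,
                               noiseSd = sigma, seed = 20)
  fit <- fitAffine(fx$slm, fx$image[[1]])
  expect_lt(abs(fit$residual - sigma), sigma * 0.5)
  tr <- rotScale()
  # SE of affine coefficients on a 240-um 7x7 grid is ~ sigma/sqrt(n)/sd(x)
  se <- sigma / sqrt(49) / stats::sd(fx$slm[, 1])
  expect_true(all(abs(fit$A - tr$A) < 3 * se + 1e-9))
  expect_true(all(abs(fit$b - tr$b) < 3 * sigma / sqrt(49)))
})

test_that("degenerate point sets are rejected", {
  line <- cbind(seq(0, 10, 1), seq(0, 20, 2))
  expect_error(fitAffine(line, line), "collinear")
  expect_error(fitAffine(grid49()[1:2, ], grid49()[1:2, ]), "3 point")
})

test_that("interpolation is exact at knots and linear in between", {
  t0 <- list(A = diag(2), b = c(0, 0), residual = 0)
  t1 <- list(A = diag(2) * 1.1, b = c(10, 0), residual = 0)
  cal <- affineCalibration(c(0, 50), list(t0, t1))
  expect_identical(interpAffine(cal, 0), t0)
  expect_identical(interpAffine(cal, 50), t1)
  mid <- interpAffine(cal, 25)
  expect_equal(mid$b, c(5, 0))
  expect_equal(mid$A, diag(2) * 1.05)
  # piecewise linearity: second differences vanish within a segment
  zs <- seq(0, 50, by = 5)
  b1 <- vapply(zs, function(z) interpAffine(cal, z)$b[1], numeric(1))
  expect_lt(max(abs(diff(diff(b1)))), 1e-12)
})

test_that("extrapolation clamps with a warning and errors far outside", {
  cal <- affineCalibration(c(0, 50),
    list(list(A = diag(2), b = c(0, 0), residual = 0),
         list(A = diag(2), b = c(10, 0), residual = 0)))
  expect_warning(tr <- interpAffine(cal, 60), "clamping")
  expect_equal(tr$b, c(10, 0))
  expect_error(interpAffine(cal, 200), "outside")
})

test_that("the efficiency model recovers a linear decay exactly", {
  set.seed(5)
  pos <- cbind(runif(30, -120, 120), runif(30, -120, 120),
               runif(30, -150, 150))
  eta <- 1 - 0.001 * abs(pos[, 3])
  fit <- fitEfficiency(pos, eta)
  expect_equal(fit@coef, c(1, 0, 0, -0.001), tolerance = 1e-9)
  expect_lt(fit@residual, 1e-9)
  # constant powers -> eta identically 1
  flat <- fitEfficiency(pos, rep(2.5, 30))
  expect_equal(predictEfficiency(flat, pos), rep(1, 30))
  expect_error(fitEfficiency(pos[, c(1, 1, 1)] * 0, eta), "degenerate")
})

test_that("compensated weights yield uniform delivered intensity under the eta screen", {
  opt <- smallOptics(128L)
  model <- new("EfficiencyModel", coef = c(1, -0.004, 0, 0), residual = 0)
  co <- cbind(x = c(-80, -20, 30, 85), y = c(10, -30, 25, 0), z = 0)
  comp <- compensateEfficiency(targetSet(co), model)
  mask <- superpositionHologram(comp, opt)
  inten <- fieldIntensityAt(mask, co)
  delivered <- inten * predictEfficiency(model, co)
  expect_lt(max(delivered) / min(delivered) - 1, 0.05 * 2)
  # and uncompensated weights are measurably nonuniform
  maskRaw <- superpositionHologram(targetSet(co), opt)
  rawDelivered <- fieldIntensityAt(maskRaw, co) *
    predictEfficiency(model, co)
  expect_gt(max(rawDelivered) / min(rawDelivered) - 1, 0.2)
})

test_that("calibration JSON round-trips", {
  cal <- affineCalibration(c(0, 25, 50), list(
    list(A = diag(2), b = c(0, 0), residual = 0.1),
    list(A = rotScale()$A, b = c(1, 2), residual = 0.2),
    list(A = diag(2) * 0.98, b = c(-3, 4), residual = 0.3)))
  path <- tempfile(fileext = ".json")
  writeCalibration(cal, path)
  back <- readCalibration(path)
  expect_equal(back@depths, cal@depths)
  for (i in 1:3) {
    expect_equal(back@transforms[[i]]$A, cal@transforms[[i]]$A)
    expect_equal(back@transforms[[i]]$b, cal@transforms[[i]]$b)
  }
})
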