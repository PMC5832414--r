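test_that("stim response is the fractional change over baseline", {
  tt <- seq(0, 10, by = 0.1)
  tr <- ifelse(tt >= 5 & tt <= 6, 1.5, 1.0)
  expect_equal(stimResponse(tr, tt, c(5, 6)), 0.5)
  expect_equal(stimResponse(rep(2, length(tt)), tt, c(5, 6)), 0)
  expect_error(stimResponse(tr, tt, c(0.5, 1)), "baseline")
  expect_error(stimResponse(tr - 1, tt, c(5, 6)), "nonpositive")
})

test_that("a kernel-convolved transient of known amplitude is recovered within 10%", {
  tt <- seq(0, 20, by = 0.15)
  kern <- holostim:::calciumKernel(tt - 8, 0.2, 1.5)
  base <- 1
  amp <- 0.8
  tr <- base + amp * kern
  # stimulation window covering the transient peak region
  got <- stimResponse(tr, tt, c(8, 9.5), baselineWindow = 2)
  # closed form: window average of the normalized kernel times amplitude
  peak <- with(list(r = 0.2, d = 1.5), {
    tp <- r * log(1 + d / r); (1 - exp(-tp / r)) * exp(-tp / d)
  })
  kfun <- function(t) (1 - exp(-t / 0.2)) * exp(-t / 1.5) / peak
  want <- amp * stats::integrate(kfun, 0, 1.5)$value / 1.5
  expect_lt(abs(got - want) / want, 0.1)
})

test_that("the post-stimulation response window option works", {
  tt <- seq(0, 10, by = 0.1)
  tr <- ifelse(tt > 6 & tt <= 7, 2, 1)
  expect_equal(stimResponse(tr, tt, c(5, 6), responseWindow = "after"), 1)
})

test_that("event detection is invariant under positive rescaling", {
  set.seed(7)
  tt <- seq(0, 60, by = 0.15)
  dff <- stats::rnorm(length(tt), 0, 0.05)
  on <- seq(40, length(tt) - 60, by = 45)
  for (i in on) dff[i:(i + 30)] <- dff[i:(i + 30)] +
    holostim:::calciumKernel(seq(0, 30) * 0.15, 0.2, 1.5)
  roi <- data.frame(x = 0, y = 0, z = 0, targeted = TRUE)
  ts1 <- traceSet(matrix(dff), tt, roi)
  ts2 <- traceSet(matrix(dff * 7.3), tt, roi)
  expect_identical(detectEvents(ts1), detectEvents(ts2))
})

test_that("white-noise event rate stays below the independence bound", {
  set.seed(11)
  n <- 1e4
  tt <- seq_len(n) * 0.1
  dff <- stats::rnorm(n)
  dec <- pmax(stats::rnorm(n), 0)
  ts <- traceSet(matrix(dff), tt, data.frame(x = 0, y = 0, z = 0,
                                             targeted = FALSE),
                 deconvolved = matrix(dec))
  rate <- mean(detectEvents(ts, kSd = 2))
  pTail <- 1 - stats::pnorm(2)
  bound <- pTail^2 + 3 * sqrt(pTail^2 * (1 - pTail^2) / n)
  # the two thresholded series are independent here, so the joint rate
  # is at most the product plus sampling error
  expect_lt(rate, bound + 0.002)
})

test_that("twenty known transients are detected with F1 >= 0.9", {
  set.seed(13)
  dt <- 0.15
  tt <- seq(0, 150, by = dt)
  dff <- stats::rnorm(length(tt), 0, 0.03)
  onsets <- round(seq(30, length(tt) - 80, length.out = 20))
  kern <- holostim:::calciumKernel(seq(0, 40) * dt, 0.2, 1.5)
  for (i in onsets) {
    idx <- i:(i + 40)
    dff[idx] <- dff[idx] + kern
  }
  ts <- traceSet(matrix(dff), tt,
                 data.frame(x = 0, y = 0, z = 0, targeted = TRUE))
  ev <- which(detectEvents(ts, kSd = 2)[, 1])
  # cluster detections: count an onset hit if any event lies within 3
  # frames of it; count false events as those > 3 frames from any onset
  hits <- sum(vapply(onsets, function(o) any(abs(ev - o) <= 3), logical(1)))
  false <- sum(vapply(ev, function(e) all(abs(onsets - e) > 3), logical(1)))
  precision <- hits / max(1, hits + false)
  recall <- hits / length(onsets)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.9)
})

test_that("nonresponder classification requires silence in every trial", {
  tt <- seq(0, 100, by = 0.5)
  ev <- rep(FALSE, length(tt))
  trials <- data.frame(trial = 1:8, pattern = 1,
                       stimStart = seq(10, 80, by = 10),
                       stimEnd = seq(10.5, 80.5, by = 10))
  expect_true(classifyNonresponder(ev, tt, trials))
  ev[which(tt >= 30 & tt <= 30.5)[1]] <- TRUE   # event in trial 3 only
  expect_false(classifyNonresponder(ev, tt, trials))
  expect_error(classifyNonresponder(ev, tt, trials[1, ]), "2 trials")
})

test_that("a synthetic silent-cell cohort is recovered within the binomial CI", {
  set.seed(17)
  nCells <- 200
  pSilent <- 0.08
  silent <- stats::runif(nCells) < pSilent
  tt <- seq(0, 100, by = 0.5)
  trials <- data.frame(trial = 1:8, pattern = 1,
                       stimStart = seq(10, 80, by = 10),
                       stimEnd = seq(11, 81, by = 10))
  flags <- vapply(seq_len(nCells), function(j) {
    ev <- rep(FALSE, length(tt))
    if (!silent[j]) {
      # responds on ~82% of trials
      for (i in seq_len(nrow(trials)))
        if (stats::runif(1) < 0.82)
          ev[which(tt >= trials$stimStart[i])[1]] <- TRUE
    }
    classifyNonresponder(ev, tt, trials)
  }, logical(1))
  se <- sqrt(pSilent * (1 - pSilent) / nCells)
  expect_lt(abs(mean(flags) - pSilent), 3 * se + 0.082^8)
})

test_that("ensemble response rate averages per-trial percentages", {
  resp <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(ensembleResponseRate(resp, c(TRUE, TRUE, TRUE)),
               mean(c(2 / 3, 1 / 3)) * 100)
  expect_equal(ensembleResponseRate(matrix(TRUE, 5, 4), 1:4), 100)
  half <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(ensembleResponseRate(half, 1:2), 50)
  expect_error(ensembleResponseRate(resp, logical(3)), "empty")
})

test_that("rate is monotone in the per-trial responder sets and bounded", {
  set.seed(3)
  a <- matrix(stats::runif(40) < 0.4, 8, 5)
  b <- a | (matrix(stats::runif(40) < 0.3, 8, 5))
  ra <- ensembleResponseRate(a, 1:5)
  rb <- ensembleResponseRate(b, 1:5)
  expect_gte(rb, ra)
  expect_gte(ra, 0); expect_lte(rb, 100)
})

test_that("nonspecific activation curve recovers an exponential falloff", {
  set.seed(19)
  lambda <- 12
  nOther <- 400
  d <- stats::runif(nOther, 0, 80)
  roi <- data.frame(
    x = c(0, d), y = 0, z = 0,
    targeted = c(TRUE, rep(FALSE, nOther)))
  responses <- c(1, exp(-d / lambda))
  res <- nonspecificVsDistance(responses, roi, binWidth = 5)
  expect_equal(res$curve$response[1], exp(-mean(d[d < 5]) / lambda),
               tolerance = 0.1)
  # half-response distance ~ ln(2) * lambda given the first-bin reference
  expect_lt(abs(res$halfResponseDistance - log(2) * lambda), 5)
  expect_lt(res$halfResponseDistance, 25)
})

test_that("a flat response profile yields a flat normalized curve", {
  roi <- data.frame(x = c(0, 15, 40, 75), y = 0, z = 0,
                    targeted = c(TRUE, FALSE, FALSE, FALSE))
  res <- nonspecificVsDistance(rep(2.2, 4), roi, binWidth = 10)
  known <- res$curve$response[!is.na(res$curve$response)]
  expect_true(all(abs(known - 1) < 1e-12))
  expect_true(is.na(res$halfResponseDistance))
})

test_that("orientation selectivity follows the two-grating contrast", {
  r <- orientationSelectivity(0.3, 0.1)
  expect_equal(r$index, 0.5)
  expect_equal(r$preference, 90)
  expect_equal(orientationSelectivity(0.4, 0.4)$index, 0)
  r2 <- orientationSelectivity(0.2, 0)
  expect_equal(r2$index, 1)
  expect_equal(r2$preference, 90)
  r3 <- orientationSelectivity(0.1, 0.3)
  expect_equal(r3$preference, 0)
  expect_false(orientationSelectivity(0.2, -0.2)$defined)
  # index bounded and preference antisymmetric
  set.seed(23)
  for (i in 1:20) {
    a <- stats::runif(1); b <- stats::runif(1)
    f <- orientationSelectivity(a, b); g <- orientationSelectivity(b, a)
    expect_gte(f$index, 0); expect_lte(f$index, 1)
    expect_equal(f$index, g$index)
    if (abs(a - b) > 1e-12) expect_false(identical(f$preference,
                                                   g$preference))
  }
})

test_that("condition comparison flags a 5-SD shift and not identical data", {
  set.seed(29)
  a <- matrix(stats::rnorm(30 * 3), 30, 3)
  res <- compareConditions(a, a + 0)
  expect_true(all(res$p > 0.9999 | !res$defined))
  b <- a; b[, 2] <- b[, 2] + 5
  res2 <- compareConditions(a, b)
  expect_true(res2$significant[2])
  degenerate <- compareConditions(matrix(1, 5, 1), matrix(1, 5, 1))
  expect_false(degenerate$defined[1])
})

test_that("null false-positive rate of the t-test is near alpha", {
  set.seed(31)
  nRoi <- 1000
  a <- matrix(stats::rnorm(30 * nRoi), 30, nRoi)
  b <- matrix(stats::rnorm(30 * nRoi), 30, nRoi)
  res <- compareConditions(a, b, alpha = 0.05)
  fpr <- mean(res$significant)
  se <- sqrt(0.05 * 0.95 / nRoi)
  expect_lt(abs(fpr - 0.05), 3 * se)
})

test_that("the deconvolution stub inverts its own kernel", {
  tt <- seq(0, 30, by = 0.2)
  tau <- 1.5
  dff <- exp(-pmax(tt - 10, 0) / tau) * (tt >= 10)
  dec <- deconvolveStub(dff, tt, decayTau = tau)
  on <- which(tt == 10)
  expect_gt(dec[on], 0.99)
  expect_true(all(dec[-on] < 1e-9))
  # a flat (zero dF/F) trace deconvolves to silence
  expect_equal(deconvolveStub(rep(0, 50), seq_len(50) * 0.2, 1.5),
               rep(0, 50))
})

test_that("spike-train onsets are recovered within one frame", {
  set.seed(37)
  dt <- 0.2
  tt <- seq(0, 120, by = dt)
  onsets <- sort(sample(50:(length(tt) - 50), 12))
  tau <- 1.5
  dff <- numeric(length(tt))
  for (o in onsets) {
    idx <- o:length(tt)
    dff[idx] <- dff[idx] + exp(-(seq_along(idx) - 1) * dt / tau)
  }
  dec <- deconvolveStub(dff, tt, decayTau = tau)
  found <- which(dec > 0.5)
  expect_true(all(vapply(onsets, function(o)
    any(abs(found - o) <= 1), logical(1))))
})
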