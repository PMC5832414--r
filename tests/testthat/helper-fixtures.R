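# shared fixtures: small optical configs keep FFT sizes test-friendly
smallOptics <- function(n = 128L, ...) opticalConfig(slmPixels = n, ...)

# simulate a mask around given z planes and locate foci
fociFor <- function(mask, zPlanes, fov = NULL, minSeparation = 5,
                    relThreshold = 0.2) {
  stack <- propagateFocalStack(mask, zPlanes = zPlanes, fov = fov)
  findFoci(stack, minSeparation = minSeparation,
           relThreshold = relThreshold)
}

# tiny flat-field movie with a known injected mesh artifact
meshMovie <- function(npx = 64L, nFrames = 24L, stimFrom = 1.0, stimTo = 1.2,
                      baseline = 100, noiseSd = 5, artifact = 250,
                      spacing = 8, phase = 3, fps = 10, seed = 42) {
  set.seed(seed)
  frames <- array(stats::rnorm(npx * npx * nFrames, baseline, noiseSd),
                  dim = c(npx, npx, nFrames))
  frames <- pmax(frames, 0)
  tt <- (seq_len(nFrames) - 1) / fps
  stim <- which(tt >= stimFrom & tt <= stimTo)
  truth <- array(FALSE, dim = dim(frames))
  for (f in stim) {
    for (y in seq_len(npx)) {
      cols <- seq(phase + ((y - 1) %% 2), npx, by = spacing)
      truth[y, cols, f] <- TRUE
      frames[y, cols, f] <- frames[y, cols, f] + artifact
    }
  }
  movie <- movieBundle(frames, tt,
                       stimIntervals = cbind(stimFrom, stimTo),
                       pixelRate = spacing * 1e6, scanModel = "linear")
  list(movie = movie, truth = truth, stimFrames = stim, fRep = 1e6)
}
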