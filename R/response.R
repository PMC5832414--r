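#' Construct a trace set
#'
#' @param dff Matrix [time, roi] of dF/F.
#' @param timestamps Sample times, seconds.
#' @param roi data.frame with columns x, y, z (microns) and logical
#'   \code{targeted}.
#' @param trials data.frame with columns trial, pattern, stimStart,
#'   stimEnd (seconds); may be empty.
#' @param deconvolved Optional matrix [time, roi]; when missing it is
#'   produced by [deconvolveStub()].
#' @param decayTau Decay constant passed to [deconvolveStub()] (s).
#' @return A [TraceSet-class].
#' @export
traceSet <- function(dff, timestamps, roi,
                     trials = data.frame(trial = integer(0),
                                         pattern = integer(0),
                                         stimStart = numeric(0),
                                         stimEnd = numeric(0)),
                     deconvolved = NULL, decayTau = 1.5) {
  dff <- as.matrix(dff)
  if (is.null(deconvolved))
    deconvolved <- apply(dff, 2, deconvolveStub,
                         timestamps = timestamps, decayTau = decayTau)
  new("TraceSet", dff = dff, deconvolved = as.matrix(deconvolved),
      timestamps = as.numeric(timestamps), roi = roi, trials = trials)
}

#' Minimal AR(1) deconvolution stand-in
#'
#' Inverse filter for an exponential-decay calcium kernel:
#' max(0, f(t) - exp(-dt/tau) f(t-1)). This is a stand-in for the
#' deconvolved output of an upstream source-extraction algorithm (e.g.
#' constrained NMF) and can be replaced by any such series; it exactly
#' inverts a single-exponential transient of matching tau into one
#' positive sample at onset.
#'
#' @param dff Numeric dF/F vector.
#' @param timestamps Sample times, seconds (uniform or not; the local
#'   dt is used).
#' @param decayTau Decay time constant, seconds (> 0).
#' @return Nonnegative vector, same length as \code{dff}.
#' @export
deconvolveStub <- function(dff, timestamps, decayTau = 1.5) {
  if (decayTau <= 0) stop("decayTau must be positive")
  n <- length(dff)
  if (n < 2) return(pmax(dff, 0))
  dt <- diff(timestamps)
  g <- exp(-dt / decayTau)
  out <- c(max(0, dff[1]), pmax(0, dff[-1] - g * dff[-n]))
  out
}

#' Stimulation-evoked dF/F change
#'
#' (mean fluorescence during the stimulation window - baseline mean) /
#' baseline mean, with the baseline taken from a window of
#' \code{baselineWindow} seconds ending at stimulation onset (the
#' conventional 0.5-2 s pre-stimulus window). Optionally the response
#' window can be placed just after the stimulation instead (useful when
#' the stimulation period itself carries an artifact).
#'
#' @param trace Numeric fluorescence (or dF/F) vector.
#' @param timestamps Sample times, seconds.
#' @param stimInterval Length-2 (start, end), seconds.
#' @param baselineWindow Baseline length, seconds (default 1; the
#'   window ends at stimulation onset).
#' @param responseWindow "during" (default) or "after" (first
#'   \code{afterLength} seconds after stimulation end).
#' @param afterLength Length of the post-stimulation window, seconds.
#' @return The fractional change (scalar).
#' @export
stimResponse <- function(trace, timestamps, stimInterval,
                         baselineWindow = 1,
                         responseWindow = c("during", "after"),
                         afterLength = 1) {
  responseWindow <- match.arg(responseWindow)
  b0 <- stimInterval[1] - baselineWindow
  if (b0 < min(timestamps) - 1e-9)
    stop("baseline window extends before the recording start")
  base <- trace[timestamps >= b0 & timestamps < stimInterval[1]]
  if (!length(base)) stop("no samples in the baseline window")
  bm <- mean(base)
  if (bm <= 0) stop("nonpositive baseline mean; trace is not normalizable")
  win <- if (responseWindow == "during")
    timestamps >= stimInterval[1] & timestamps <= stimInterval[2]
  else
    timestamps > stimInterval[2] &
      timestamps <= stimInterval[2] + afterLength
  if (!any(win)) stop("no samples in the response window")
  (mean(trace[win]) - bm) / bm
}

#' Detect activity events from deconvolved + derivative thresholds
#'
#' An event is recorded at sample t when the deconvolved signal exceeds
#' its own mean + kSd standard deviations AND the temporal first
#' derivative of the dF/F trace exceeds the derivative's own mean + kSd
#' standard deviations, both statistics taken over the full trace. The
#' thresholds are SD-relative, so the event train is invariant under
#' positive rescaling of the raw trace.
#'
#' @param traces A [TraceSet-class].
#' @param kSd SD multiplier (default 2).
#' @return Logical matrix [time, roi] of events; constant traces yield
#'   no events with a warning.
#' @export
detectEvents <- function(traces, kSd = 2) {
  nt <- nrow(traces@dff)
  if (nt < 100)
    warning("fewer than 100 samples; mean/SD thresholds may be unstable")
  dt <- diff(traces@timestamps)
  ev <- matrix(FALSE, nt, ncol(traces@dff))
  for (j in seq_len(ncol(traces@dff))) {
    dec <- traces@deconvolved[, j]
    der <- c(0, diff(traces@dff[, j]) / dt)
    sdec <- stats::sd(dec); sder <- stats::sd(der)
    if (!is.finite(sdec) || sdec == 0 || !is.finite(sder) || sder == 0) {
      warning("constant trace for ROI ", j, "; no events detected")
      next
    }
    ev[, j] <- dec > mean(dec) + kSd * sdec & der > mean(der) + kSd * sder
  }
  ev
}

#' Classify a cell as a photostimulation nonresponder
#'
#' TRUE when no single activity event falls inside the stimulation
#' period of any trial; such cells (typically from poor opsin
#' expression) are excluded from response-rate statistics.
#'
#' @param events Logical event vector for one ROI (length = samples).
#' @param timestamps Sample times, seconds.
#' @param trials data.frame with stimStart, stimEnd per trial (>= 2
#'   trials required).
#' @return Logical flag.
#' @export
classifyNonresponder <- function(events, timestamps, trials) {
  if (nrow(trials) < 2) stop("need at least 2 trials")
  for (i in seq_len(nrow(trials))) {
    win <- timestamps >= trials$stimStart[i] & timestamps <= trials$stimEnd[i]
    if (any(events[win])) return(FALSE)
  }
  TRUE
}

#' Per-trial responder matrix
#'
#' @param events Logical matrix [time, roi].
#' @param timestamps Sample times, seconds.
#' @param trials Trial table with stimStart, stimEnd.
#' @return Logical matrix [trial, roi]: any event within the trial's
#'   stimulation period.
#' @export
trialResponders <- function(events, timestamps, trials) {
  out <- matrix(FALSE, nrow(trials), ncol(events))
  for (i in seq_len(nrow(trials))) {
    win <- timestamps >= trials$stimStart[i] & timestamps <= trials$stimEnd[i]
    out[i, ] <- colSums(events[win, , drop = FALSE]) > 0
  }
  out
}

#' Ensemble response rate
#'
#' Mean over trials of the percentage of targeted cells responding in
#' that trial.
#'
#' @param responders Logical matrix [trial, roi] from
#'   [trialResponders()].
#' @param targeted Logical (or index) vector selecting targeted ROIs.
#' @return Percentage in [0, 100].
#' @export
ensembleResponseRate <- function(responders, targeted) {
  sub <- responders[, targeted, drop = FALSE]
  if (!ncol(sub)) stop("targeted set is empty")
  mean(rowMeans(sub)) * 100
}

#' Nonspecific activation versus distance to the nearest target
#'
#' Bins the non-targeted ROIs by 3D Euclidean distance to their nearest
#' targeted cell and reports the mean response per bin, normalized to
#' the mean response of the targeted cells. The half-response distance
#' is found by linear interpolation of the binned curve at half of its
#' value in the nearest bin.
#'
#' @param responses Per-ROI response values (e.g. mean evoked dF/F).
#' @param roi data.frame with x, y, z and logical \code{targeted}.
#' @param binWidth Distance bin width, microns (default 10).
#' @return List with \code{curve} (data.frame: bin centre, mean
#'   normalized response, n; empty bins reported as NA, not zero) and
#'   \code{halfResponseDistance} (microns; NA when the curve never
#'   falls below half).
#' @export
nonspecificVsDistance <- function(responses, roi, binWidth = 10) {
  targeted <- which(roi$targeted)
  others <- which(!roi$targeted)
  if (!length(others)) stop("no non-targeted ROIs")
  tMean <- mean(responses[targeted])
  if (!is.finite(tMean) || tMean <= 0)
    stop("targeted mean response must be positive for normalization")
  pos <- as.matrix(roi[, c("x", "y", "z")])
  d <- vapply(others, function(i)
    sqrt(min(rowSums((pos[targeted, , drop = FALSE] -
                      matrix(pos[i, ], length(targeted), 3,
                             byrow = TRUE))^2))), numeric(1))
  norm <- responses[others] / tMean
  edges <- seq(0, max(d) + binWidth, by = binWidth)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  centres <- edges[-length(edges)] + binWidth / 2
  curve <- data.frame(
    distance = centres,
    response = vapply(seq_along(centres), function(b) {
      v <- norm[bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n = vapply(seq_along(centres), function(b) sum(bin == b), numeric(1)))
  known <- which(!is.na(curve$response))
  half <- NA_real_
  if (length(known) >= 2) {
    ref <- curve$response[known[1]] / 2
    for (k in seq_len(length(known) - 1)) {
      i1 <- known[k]; i2 <- known[k + 1]
      y1 <- curve$response[i1]; y2 <- curve$response[i2]
      if (y1 >= ref && y2 < ref) {
        half <- curve$distance[i1] + (y1 - ref) *
          (curve$distance[i2] - curve$distance[i1]) / (y1 - y2)
        break
      }
    }
  }
  list(curve = curve, halfResponseDistance = half)
}

#' Orientation selectivity index for two orthogonal gratings
#'
#' index = |(dff90 - dff0) / (dff90 + dff0)|; the preference is 90
#' degrees when the signed ratio is positive, 0 degrees when negative.
#'
#' @param dff90 Mean dF/F during the 90-degree drifting grating.
#' @param dff0 Mean dF/F during the 0-degree grating.
#' @return List with \code{index} in [0, 1], \code{preference} (0 or
#'   90, NA for a zero difference) and \code{defined} (FALSE when the
#'   denominator is zero).
#' @export
orientationSelectivity <- function(dff90, dff0) {
  den <- dff90 + dff0
  if (abs(den) < .Machine$double.eps)
    return(list(index = NA_real_, preference = NA_real_, defined = FALSE))
  s <- (dff90 - dff0) / den
  list(index = abs(s),
       preference = if (s > 0) 90 else if (s < 0) 0 else NA_real_,
       defined = TRUE)
}

#' Per-ROI two-sample comparison between conditions
#'
#' Two-sample t-test per ROI on per-trial response values (e.g. evoked
#' dF/F with and without interneuron photostimulation), at level
#' \code{alpha}.
#'
#' @param trialsA Matrix [trial, roi] of responses in condition A.
#' @param trialsB Matrix [trial, roi] in condition B.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with roi, p, significant, and \code{defined}
#'   (FALSE where both conditions have zero variance).
#' @export
compareConditions <- function(trialsA, trialsB, alpha = 0.05) {
  trialsA <- as.matrix(trialsA); trialsB <- as.matrix(trialsB)
  if (nrow(trialsA) < 2 || nrow(trialsB) < 2)
    stop("need at least 2 trials per condition")
  if (ncol(trialsA) != ncol(trialsB)) stop("ROI counts differ")
  res <- lapply(seq_len(ncol(trialsA)), function(j) {
    a <- trialsA[, j]; b <- trialsB[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(data.frame(roi = j, p = NA_real_, significant = NA,
                        defined = FALSE))
    p <- stats::t.test(a, b)$p.value
    data.frame(roi = j, p = p, significant = p < alpha, defined = TRUE)
  })
  do.call(rbind, res)
}

#' Read / write trace sets (long-format CSV + JSON metadata)
#'
#' The CSV holds columns roi, t, dff, deconvolved; ROI positions and
#' the trial table go to \code{<path>.json}.
#'
#' @param traces A [TraceSet-class].
#' @param path CSV path.
#' @return \code{writeTraceSet}: \code{path} invisibly;
#'   \code{readTraceSet}: a [TraceSet-class].
#' @export
writeTraceSet <- function(traces, path) {
  nt <- nrow(traces@dff); nr <- ncol(traces@dff)
  long <- data.frame(
    roi = rep(seq_len(nr), each = nt),
    t = rep(traces@timestamps, nr),
    dff = as.numeric(traces@dff),
    deconvolved = as.numeric(traces@deconvolved))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(roi = traces@roi, trials = traces@trials),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeTraceSet
#' @export
readTraceSet <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  rois <- sort(unique(long$roi))
  tt <- long$t[long$roi == rois[1]]
  dff <- vapply(rois, function(r) long$dff[long$roi == r],
                numeric(length(tt)))
  dec <- vapply(rois, function(r) long$deconvolved[long$roi == r],
                numeric(length(tt)))
  trials <- as.data.frame(meta$trials)
  if (!nrow(trials))
    trials <- data.frame(trial = integer(0), pattern = integer(0),
                         stimStart = numeric(0), stimEnd = numeric(0))
  traceSet(dff, tt, as.data.frame(meta$roi), trials, deconvolved = dec)
}

setMethod("show", "TraceSet", function(object) {
  cat(sprintf(
    "TraceSet: %d ROIs (%d targeted) x %d samples, %d trial(s)\n",
    ncol(object@dff), sum(object@roi$targeted), nrow(object@dff),
    nrow(object@trials)))
})
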