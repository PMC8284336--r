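#' Construct a VoltageTrace
#'
#' @param samples voltage samples (uV).
#' @param sampleRate samples per second (Hz).
#' @param pulseTimes stimulation-pulse onset times (s), sorted.
#' @return A \linkS4class{VoltageTrace}.
#' @export
voltageTrace <- function(samples, sampleRate = 20000, pulseTimes = numeric()) {
  new("VoltageTrace", samples = as.numeric(samples),
      sampleRate = sampleRate, pulseTimes = sort(as.numeric(pulseTimes)))
}

# sample indices covered by the blanking windows (merged if overlapping)
blankIndices <- function(trace, blankMs) {
  sr <- trace@sampleRate
  n <- length(trace@samples)
  idx <- integer()
  warned <- FALSE
  prevEnd <- 0L
  for (p in trace@pulseTimes) {
    a <- floor(p * sr) + 1L
    b <- min(n, floor((p + blankMs / 1000) * sr))
    if (a <= prevEnd && !warned) {
      warning("overlapping blanking windows merged")
      warned <- TRUE
    }
    idx <- c(idx, max(a, prevEnd + 1L):b)
    prevEnd <- b
  }
  unique(idx)
}

#' Blank stimulation artifacts with matched noise
#'
#' Replaces the first \code{blankMs} milliseconds after each stimulation pulse
#' with Gaussian noise whose standard deviation matches the electrode's
#' off-pulse noise level (robust RMS via the median absolute deviation).
#' Samples outside the blanking windows are untouched. Overlapping windows
#' are merged with a warning.
#'
#' @param trace a \linkS4class{VoltageTrace}.
#' @param blankMs blanking window after each pulse, in ms (default 8.25).
#' @param seed integer seed for the replacement noise.
#' @return A \linkS4class{VoltageTrace}.
#' @export
blankArtifact <- function(trace, blankMs = 8.25, seed = 1L) {
  if (!length(trace@pulseTimes)) return(trace)
  idx <- blankIndices(trace, blankMs)
  off <- trace@samples[-idx]
  sigma <- robustRMS(off - stats::median(off))
  set.seed(as.integer(seed))
  out <- trace@samples
  out[idx] <- stats::median(off) + stats::rnorm(length(idx), 0, sigma)
  voltageTrace(out, trace@sampleRate, trace@pulseTimes)
}

#' Subtract slow artifact decay with a per-segment polynomial fit
#'
#' Within each inter-pulse segment (samples between consecutive pulse onsets,
#' excluding the blanked window after the segment's opening pulse) a
#' least-squares polynomial of the given order is fitted and subtracted,
#' removing the lingering capacitive decay while preserving fast spikes.
#' With no pulses the whole trace is one segment.
#'
#' @param trace a \linkS4class{VoltageTrace}.
#' @param order polynomial order (default 7).
#' @param blankMs blanked window excluded from the fit, in ms.
#' @return A \linkS4class{VoltageTrace} with the fits subtracted.
#' @export
detrendDecay <- function(trace, order = 7L, blankMs = 8.25) {
  sr <- trace@sampleRate
  n <- length(trace@samples)
  out <- trace@samples
  bounds <- unique(c(1L, floor(trace@pulseTimes * sr) + 1L, n + 1L))
  bounds <- sort(bounds[bounds >= 1L & bounds <= n + 1L])
  blanked <- if (length(trace@pulseTimes))
    blankIndices(trace, blankMs) else integer()
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- bounds[s]:(bounds[s + 1L] - 1L)
    fitIdx <- setdiff(seg, blanked)
    if (length(fitIdx) <= order + 1L) {
      warning("segment too short for polynomial fit; skipped")
      next
    }
    x <- (fitIdx - seg[1L]) / length(seg)   # scaled for conditioning
    po <- stats::poly(x, degree = order)    # orthogonal basis
    fit <- stats::lm.fit(cbind(1, po), trace@samples[fitIdx])
    xa <- (seg - seg[1L]) / length(seg)
    pred <- cbind(1, stats::predict(po, xa)) %*% fit$coefficients
    out[seg] <- trace@samples[seg] - as.numeric(pred)
  }
  voltageTrace(out, sr, trace@pulseTimes)
}

#' Detect spikes by negative threshold crossing
#'
#' A negative deflection exceeding \code{thresholdSD} times the trace's
#' robust RMS noise is considered a spike; the spike time is the local
#' minimum of each sub-threshold excursion, and events closer than
#' \code{mergeMs} are merged into the deeper one.
#'
#' @param trace a detrended \linkS4class{VoltageTrace}.
#' @param thresholdSD threshold in noise SDs (default 3).
#' @param mergeMs refractory merge window in ms (default 1).
#' @param cellId identifier for the resulting train.
#' @return A \linkS4class{SpikeTrain}.
#' @export
detectSpikes <- function(trace, thresholdSD = 3, mergeMs = 1,
                         cellId = "electrode") {
  x <- trace@samples
  sr <- trace@sampleRate
  durS <- length(x) / sr
  sigma <- robustRMS(x)
  if (sigma == 0) return(spikeTrain(numeric(), max(durS, 1e-9), cellId))
  thr <- -thresholdSD * sigma
  below <- x < thr
  if (!any(below)) return(spikeTrain(numeric(), durS, cellId))
  # group contiguous sub-threshold runs; take each run's minimum
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.min(x[seg])]
  }, integer(1L))
  # merge events within the refractory window, keeping the deeper one
  peaks <- peaks[order(peaks)]
  mergeSamp <- mergeMs / 1000 * sr
  kept <- integer()
  for (p in peaks) {
    if (length(kept) && (p - kept[length(kept)]) < mergeSamp) {
      if (x[p] < x[kept[length(kept)]]) kept[length(kept)] <- p
    } else kept <- c(kept, p)
  }
  spikeTrain((kept - 0.5) / sr, durS, cellId)
}

#' Estimate spike-train contamination from refractory violations
#'
#' Fraction of inter-spike intervals shorter than the refractory period,
#' divided by the fraction expected from a rate-matched homogeneous Poisson
#' process, clipped to [0, 1]. A perfectly isolated cell with a dead time
#' longer than the refractory window scores 0; a train indistinguishable from
#' Poisson scores 1.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param refractoryMs refractory period in ms (default 1.5).
#' @return Estimated contaminating fraction in [0, 1].
#' @export
estimateContamination <- function(train, refractoryMs = 1.5) {
  st <- spikeTimes(train)
  if (length(st) < 2L) return(0)
  isi <- diff(st)
  tref <- refractoryMs / 1000
  fObs <- mean(isi < tref)
  rate <- length(st) / duration(train)
  fPois <- 1 - exp(-rate * tref)
  if (fPois <= 0) return(0)
  min(1, max(0, fObs / fPois))
}
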