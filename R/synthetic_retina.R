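#' Construct a ground-truth linear-nonlinear cell
#'
#' @param cellId identifier.
#' @param polarity "ON" or "OFF".
#' @param center receptive-field centre \code{c(row, col)} in stimulus pixels.
#' @param sigmaCenter,sigmaSurround centre/surround Gaussian SDs (pixels).
#' @param surroundWeight integrated surround strength relative to the centre.
#' @param temporalFilter biphasic temporal kernel (oldest lag first); built by
#'   \code{\link{biphasicKernel}} when NULL.
#' @param depthFrames temporal filter depth when \code{temporalFilter} is NULL.
#' @param frameRate stimulus frame rate (Hz) used to time the default kernel.
#' @param fast use the faster, weaker kernel typical of electrically evoked
#'   responses.
#' @param threshold,gain rectifier: rate = gain * max(0, drive - threshold) Hz.
#' @param baselineRate spontaneous rate (Hz).
#' @param noiseRatio fraction of spikes to replace with random timing.
#' @param deadTime absolute refractory dead time in seconds (0 = none).
#' @return A \linkS4class{GroundTruthCell}.
#' @export
groundTruthCell <- function(cellId = "cell", polarity = "ON",
                            center = c(5, 5), sigmaCenter = 1.2,
                            sigmaSurround = 2.4, surroundWeight = 0.35,
                            temporalFilter = NULL, depthFrames = 24L,
                            frameRate = 30, fast = FALSE,
                            threshold = 0.2, gain = 60, baselineRate = 1,
                            noiseRatio = 0, deadTime = 0) {
  if (is.null(temporalFilter))
    temporalFilter <- biphasicKernel(depthFrames, frameRate, fast = fast)
  new("GroundTruthCell", cellId = as.character(cellId), polarity = polarity,
      center = as.numeric(center), sigmaCenter = sigmaCenter,
      sigmaSurround = sigmaSurround, surroundWeight = surroundWeight,
      temporalFilter = as.numeric(temporalFilter), threshold = threshold,
      gain = gain, baselineRate = baselineRate, noiseRatio = noiseRatio,
      deadTime = deadTime)
}

#' Biphasic temporal kernel
#'
#' Difference of two gamma-shaped lobes, returned oldest lag first and scaled
#' to unit peak. The \code{fast} variant halves both time constants and the
#' amplitude, emulating the faster but weaker kinetics of electrically evoked
#' spike-triggered averages.
#'
#' @param depthFrames kernel length in frames.
#' @param frameRate frame rate (Hz).
#' @param tau1,tau2 positive/negative lobe time constants (s).
#' @param lobeRatio amplitude of the second (older, opposite-sign) lobe.
#' @param fast shorten and weaken the kernel.
#' @return Numeric vector of length \code{depthFrames}.
#' @export
biphasicKernel <- function(depthFrames = 24L, frameRate = 30,
                           tau1 = 0.08, tau2 = 0.16, lobeRatio = 0.6,
                           fast = FALSE) {
  amp <- 1
  if (fast) { tau1 <- tau1 / 2; tau2 <- tau2 / 2; amp <- 0.5 }
  # time before the spike at each lag (oldest lag first)
  tts <- (depthFrames:1 - 0.5) / frameRate
  lobe <- function(t, tau, n = 4) (t / tau)^n * exp(-n * (t / tau - 1))
  k <- lobe(tts, tau1) - lobeRatio * lobe(tts, tau2)
  amp * k / max(abs(k))
}

#' Full spatiotemporal filter of a ground-truth cell
#'
#' Separable kernel: difference-of-Gaussians spatial profile times the
#' biphasic temporal kernel, negated for OFF cells, normalized to unit L2
#' norm over the canvas.
#'
#' @param cell a \linkS4class{GroundTruthCell}.
#' @param canvas \code{c(height, width)} of the stimulus in pixels.
#' @return Array \code{depth x height x width}.
#' @export
cellKernel <- function(cell, canvas) {
  H <- canvas[1L]; W <- canvas[2L]
  dr <- outer(seq_len(H) - cell@center[1L], rep(1, W))
  dc <- outer(rep(1, H), seq_len(W) - cell@center[2L])
  d2 <- dr^2 + dc^2
  sc2 <- cell@sigmaCenter^2; ss2 <- cell@sigmaSurround^2
  spatial <- exp(-d2 / (2 * sc2)) -
    cell@surroundWeight * (sc2 / ss2) * exp(-d2 / (2 * ss2))
  k <- outer(cell@temporalFilter, spatial)
  dim(k) <- c(length(cell@temporalFilter), H, W)
  if (cell@polarity == "OFF") k <- -k
  k / sqrt(sum(k^2))
}

# per-frame generator signal: drive[t] uses the depth frames strictly
# preceding frame t (the same alignment the STA recovers); first `depth`
# entries are NA
cellDrive <- function(kernel, stimMatrix) {
  depth <- dim(kernel)[1L]
  Wl <- matrix(kernel, nrow = depth)
  Tn <- nrow(stimMatrix)
  if (Tn <= depth) stop("stimulus shorter than the filter depth")
  M <- stimMatrix %*% t(Wl)                       # T x depth
  drive <- rep(NA_real_, Tn)
  idx <- (depth + 1L):Tn
  acc <- numeric(length(idx))
  for (l in seq_len(depth)) acc <- acc + M[idx - (depth - l + 1L), l]
  drive[idx] <- acc
  drive
}

#' Simulate a cell's spike train in response to a stimulus movie
#'
#' Per-frame rates follow the linear-nonlinear cascade
#' rate = gain * max(0, w . s - threshold) + baseline, with the stimulus
#' expressed as contrast about its mean. Spike counts per frame are Poisson
#' and spike times are jittered uniformly within the frame. If the cell has a
#' positive dead time, spikes violating it are thinned.
#'
#' @param cell a \linkS4class{GroundTruthCell}.
#' @param stimulus a \linkS4class{StimulusMovie} longer than the filter depth.
#' @param seed integer seed.
#' @return A \linkS4class{SpikeTrain}.
#' @export
simulateCell <- function(cell, stimulus, seed = 1L) {
  frames <- stimFrames(stimulus)
  if (length(frames) == 0L) stop("empty stimulus")
  S <- flattenFrames(frames) - mean(frames)
  kern <- cellKernel(cell, dim(frames)[2:3])
  drive <- cellDrive(kern, S)
  fr <- frameRate(stimulus)
  rate <- cell@gain * pmax(0, drive - cell@threshold) + cell@baselineRate
  rate[is.na(rate)] <- cell@baselineRate
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(rate), rate / fr)
  hot <- which(counts > 0L)
  times <- (rep(hot, counts[hot]) - 1L + stats::runif(sum(counts))) / fr
  times <- sort(times)
  if (cell@deadTime > 0 && length(times) > 1L)
    times <- enforceDeadTime(times, cell@deadTime)
  spikeTrain(times, duration = length(rate) / fr, cellId = cell@cellId)
}

enforceDeadTime <- function(times, deadTime) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= deadTime) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' Replace a fraction of spikes with randomly timed spikes
#'
#' Removes a fraction \code{nr} (the noise ratio) of the spikes uniformly at
#' random and adds replacement spikes from a homogeneous Poisson process over
#' the full recording, with expected count equal to the number removed, so
#' the mean rate is preserved in expectation.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param nr noise ratio in [0, 1].
#' @param seed integer seed.
#' @return A \linkS4class{SpikeTrain}.
#' @export
injectNoise <- function(train, nr, seed = 1L) {
  if (nr < 0 || nr > 1) stop("nr must lie in [0, 1]")
  if (nr == 0) return(train)
  st <- spikeTimes(train)
  n <- length(st)
  set.seed(as.integer(seed))
  nRemove <- round(nr * n)
  keep <- if (nRemove > 0) st[-sample.int(n, nRemove)] else st
  nAdd <- stats::rpois(1L, nRemove)
  added <- stats::runif(nAdd, 0, duration(train))
  spikeTrain(c(keep, added), duration(train), cellId(train))
}

#' Build a ground-truth RGC population
#'
#' Receptive-field centres tile the canvas on a jittered grid with alternating
#' ON/OFF polarity. Presets emulate the two retina types studied:
#' \describe{
#'   \item{"LE"}{healthy (Long-Evans-like): dense mosaic, low noise ratio,
#'     population size drawn from \{49, 49, 21, 20\}.}
#'   \item{"RCS"}{degenerate (RCS-like): sparse mosaic restricted to a central
#'     implant region, high noise ratio, fast weak temporal kernels,
#'     population size drawn from \{19, 14, 13, 9\}.}
#'   \item{"demo"}{20 cells, moderate noise, for quick end-to-end runs.}
#'   \item{"mosaic"}{dense complete mosaic (100 cells, small receptive
#'     fields, low noise) emulating the full RGC sheet rather than an
#'     MEA-sampled subset; used for letter-resolution experiments where the
#'     letter must be tiled by several cells per stroke.}
#' }
#'
#' @param preset "LE", "RCS" or "demo".
#' @param canvas \code{c(height, width)} in stimulus pixels.
#' @param nCells population size; when NULL, drawn from the preset's counts.
#' @param noiseRatio per-cell noise ratio; NULL uses the preset default
#'   (LE 0.1, RCS 0.8, demo 0.2).
#' @param frameRate stimulus frame rate (Hz) for the temporal kernels.
#' @param seed integer seed.
#' @param deadTime optional absolute refractory dead time (s) for every cell.
#' @return List of \linkS4class{GroundTruthCell}.
#' @export
buildPopulation <- function(preset = c("demo", "LE", "RCS", "mosaic"),
                            canvas = c(20, 20), nCells = NULL,
                            noiseRatio = NULL, frameRate = 30,
                            seed = 1L, deadTime = 0) {
  preset <- match.arg(preset)
  set.seed(as.integer(seed))
  if (is.null(nCells))
    nCells <- switch(preset,
      LE   = sample(c(49L, 49L, 21L, 20L), 1L),
      RCS  = sample(c(19L, 14L, 13L, 9L), 1L),
      demo = 20L,
      mosaic = 100L)
  if (nCells < 1L) stop("cell count must be >= 1")
  if (is.null(noiseRatio))
    noiseRatio <- switch(preset, LE = 0.1, RCS = 0.8, demo = 0.2,
                         mosaic = 0.1)
  fast <- preset == "RCS"
  # RCS mosaics are confined to the implant footprint at the canvas centre
  if (preset == "RCS") {
    lo <- canvas / 4 + 0.5; hi <- canvas * 3 / 4 + 0.5
  } else {
    lo <- c(1.5, 1.5); hi <- canvas - 0.5
  }
  k <- ceiling(sqrt(nCells))
  gr <- seq(lo[1L], hi[1L], length.out = k)
  gc <- seq(lo[2L], hi[2L], length.out = k)
  centers <- expand.grid(row = gr, col = gc)[seq_len(nCells), ]
  spacing <- max(diff(gr)[1L], 0.5)
  jit <- matrix(stats::runif(2L * nCells, -0.3, 0.3) * spacing, ncol = 2L)
  lapply(seq_len(nCells), function(i) {
    groundTruthCell(
      cellId = sprintf("%s_%02d", preset, i),
      polarity = if (i %% 2L == 0L) "OFF" else "ON",
      center = pmin(pmax(as.numeric(centers[i, ]) + jit[i, ], 1), canvas),
      sigmaCenter = if (preset == "mosaic") stats::runif(1, 0.7, 0.9)
                    else stats::runif(1, 1.0, 1.5),
      sigmaSurround = if (preset == "mosaic") stats::runif(1, 1.6, 2.0)
                      else stats::runif(1, 2.2, 3.0),
      frameRate = frameRate, fast = fast,
      baselineRate = if (preset == "RCS") 2 else 1,
      noiseRatio = noiseRatio, deadTime = deadTime)
  })
}

#' Simulate spike trains for a whole population
#'
#' Runs \code{\link{simulateCell}} for every cell and, when
#' \code{applyNoise = TRUE}, replaces each cell's own \code{noiseRatio}
#' fraction of spikes with random timing via \code{\link{injectNoise}}.
#'
#' @param cells list of \linkS4class{GroundTruthCell}.
#' @param stimulus a \linkS4class{StimulusMovie}.
#' @param seed master seed; each cell consumes a named substream.
#' @param applyNoise apply each cell's noise ratio.
#' @return Named list of \linkS4class{SpikeTrain}.
#' @export
simulatePopulation <- function(cells, stimulus, seed = 1L, applyNoise = TRUE) {
  out <- lapply(cells, function(cell) {
    tr <- simulateCell(cell, stimulus, seed = subSeed(seed, cell@cellId))
    if (applyNoise && cell@noiseRatio > 0)
      tr <- injectNoise(tr, cell@noiseRatio,
                        seed = subSeed(seed, paste0("noise_", cell@cellId)))
    tr
  })
  names(out) <- vapply(cells, cellId, character(1L))
  out
}
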