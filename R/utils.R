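#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Every stochastic stage consumes a named substream of the experiment master
#' seed, so any stage can be re-run in isolation. The derivation is a small
#' integer hash of the label folded into the master seed, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stream character label of the substream.
#' @return An integer seed.
#' @export
subSeed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(as.character(stream)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Gaussian smoothing kernel truncated at +/- 4 sigma, normalized to sum 1
gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# same-length convolution with edge renormalization (avoids edge droop)
smoothTrace <- function(x, sigma) {
  k <- gaussKernel(sigma)
  if (length(k) == 1L) return(x)
  h <- (length(k) - 1L) %/% 2L
  n <- length(x)
  num <- stats::filter(c(rep(0, h), x, rep(0, h)), k, sides = 2)
  den <- stats::filter(c(rep(0, h), rep(1, n), rep(0, h)), k, sides = 2)
  as.numeric(num[(h + 1L):(h + n)] / den[(h + 1L):(h + n)])
}

# Pearson correlation returning NA for zero-variance inputs rather than erroring
safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# flatten a T x H x W array into a T x (H*W) matrix (row-major voxel order)
flattenFrames <- function(frames) {
  d <- dim(frames)
  matrix(frames, nrow = d[1L], ncol = d[2L] * d[3L])
}

# robust RMS via median absolute deviation (Gaussian-consistent)
robustRMS <- function(x) stats::mad(x, center = stats::median(x))

#' Construct a SpikeTrain
#'
#' @param spikeTimes numeric spike times in seconds (sorted internally; exact
#'   duplicates are collapsed).
#' @param duration recording duration in seconds.
#' @param cellId cell identifier.
#' @return A \linkS4class{SpikeTrain}.
#' @export
spikeTrain <- function(spikeTimes, duration, cellId = "cell") {
  st <- sort(unique(as.numeric(spikeTimes)))
  st <- st[st >= 0 & st < duration]
  new("SpikeTrain", cellId = as.character(cellId), spikeTimes = st,
      duration = as.numeric(duration))
}

#' Bin a spike train into per-frame counts
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param rate bin rate in Hz (bins of width 1/rate starting at t = 0).
#' @param nBins number of bins; defaults to \code{floor(duration * rate)}.
#' @return Integer vector of counts.
#' @export
binSpikes <- function(train, rate, nBins = NULL) {
  if (is.null(nBins)) nBins <- floor(duration(train) * rate)
  idx <- floor(spikeTimes(train) * rate) + 1L
  idx <- idx[idx >= 1L & idx <= nBins]
  tabulate(idx, nbins = nBins)
}
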