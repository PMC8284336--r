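#' @import methods
NULL

#' StimulusMovie: a spatiotemporal stimulus
#'
#' Frame stack presented to the retina, stored time-major as a
#' \code{time x height x width} array of intensities in \code{[0, 1]}.
#' Binary white-noise movies contain only 0 and 1; Landolt-C movies contain
#' quantized greyscale levels.
#'
#' @slot frames numeric 3-D array, \code{time x height x width}, values in [0,1].
#' @slot frameRate frames per second (Hz).
#' @slot pixelPitch pixel width on the retina (micrometres).
#' @slot modality \code{"visual"} or \code{"electrical"}.
#' @export
setClass("StimulusMovie",
  representation(frames = "array", frameRate = "numeric",
                 pixelPitch = "numeric", modality = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-D (time x height x width) array")
    if (length(object@frames) &&
        (min(object@frames) < 0 || max(object@frames) > 1))
      msg <- c(msg, "intensities must lie in [0, 1]")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (!object@modality %in% c("visual", "electrical"))
      msg <- c(msg, "modality must be 'visual' or 'electrical'")
    if (length(msg)) msg else TRUE
  })

#' SpikeTrain: sorted spike times for one cell
#'
#' @slot cellId character identifier.
#' @slot spikeTimes strictly increasing spike times in seconds, in
#'   \code{[0, duration)}.
#' @slot duration recording duration in seconds.
#' @export
setClass("SpikeTrain",
  representation(cellId = "character", spikeTimes = "numeric",
                 duration = "numeric"),
  validity = function(object) {
    msg <- character()
    st <- object@spikeTimes
    if (length(object@duration) != 1L || object@duration <= 0)
      msg <- c(msg, "duration must be a single positive number")
    if (length(st)) {
      if (is.unsorted(st, strictly = TRUE))
        msg <- c(msg, "spikeTimes must be strictly increasing")
      if (st[1L] < 0 || st[length(st)] >= object@duration)
        msg <- c(msg, "spikeTimes must lie in [0, duration)")
    }
    if (length(msg)) msg else TRUE
  })

#' VoltageTrace: a raw single-electrode recording
#'
#' @slot samples voltage samples in microvolts.
#' @slot sampleRate samples per second (Hz), typically 20000.
#' @slot pulseTimes sorted stimulation-pulse onset times in seconds.
#' @export
setClass("VoltageTrace",
  representation(samples = "numeric", sampleRate = "numeric",
                 pulseTimes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be positive")
    pt <- object@pulseTimes
    if (length(pt)) {
      if (is.unsorted(pt)) msg <- c(msg, "pulseTimes must be sorted")
      dur <- length(object@samples) / object@sampleRate
      if (min(pt) < 0 || max(pt) > dur)
        msg <- c(msg, "pulseTimes must lie within the trace")
    }
    if (length(msg)) msg else TRUE
  })

#' GroundTruthCell: parametric linear-nonlinear ganglion cell
#'
#' A simulated RGC with a separable spatiotemporal filter: a
#' difference-of-Gaussians spatial profile times a biphasic temporal kernel,
#' followed by a rectifying nonlinearity and Poisson spike generation.
#' \code{noiseRatio} is the fraction of driven spikes replaced by randomly
#' timed (spontaneous) spikes.
#'
#' @slot cellId character identifier.
#' @slot polarity \code{"ON"} or \code{"OFF"}; an OFF cell's filter is the
#'   negated ON filter.
#' @slot center receptive-field centre, \code{c(row, col)} in stimulus pixels.
#' @slot sigmaCenter,sigmaSurround centre/surround Gaussian widths (pixels).
#' @slot surroundWeight relative amplitude of the antagonistic surround.
#' @slot temporalFilter biphasic kernel over \code{filter depth} frames,
#'   ordered oldest lag first.
#' @slot threshold,gain rectifier parameters: rate = gain * max(0, drive - threshold).
#' @slot baselineRate spontaneous rate in Hz added to the driven rate.
#' @slot noiseRatio fraction in [0, 1] of spikes replaced by random timing.
#' @slot deadTime absolute refractory dead time in seconds (0 disables).
#' @export
setClass("GroundTruthCell",
  representation(cellId = "character", polarity = "character",
                 center = "numeric", sigmaCenter = "numeric",
                 sigmaSurround = "numeric", surroundWeight = "numeric",
                 temporalFilter = "numeric", threshold = "numeric",
                 gain = "numeric", baselineRate = "numeric",
                 noiseRatio = "numeric", deadTime = "numeric"),
  prototype(deadTime = 0),
  validity = function(object) {
    msg <- character()
    if (!object@polarity %in% c("ON", "OFF"))
      msg <- c(msg, "polarity must be 'ON' or 'OFF'")
    if (object@noiseRatio < 0 || object@noiseRatio > 1)
      msg <- c(msg, "noiseRatio must lie in [0, 1]")
    if (object@baselineRate < 0)
      msg <- c(msg, "baselineRate must be >= 0")
    if (length(object@center) != 2L)
      msg <- c(msg, "center must be c(row, col)")
    if (length(msg)) msg else TRUE
  })

#' STA: spike-triggered average kernel
#'
#' Mean of the \code{depthFrames} stimulus frames preceding each spike,
#' ordered oldest lag first (lag \code{depthFrames} is the frame immediately
#' before the spike). \code{cropBox} is the small region around the kernel
#' peak (by default 3 px x 3 px x 4 frames) used for correlation-curve
#' analyses.
#'
#' @slot kernel numeric array \code{depthFrames x height x width}.
#' @slot depthFrames temporal depth (frames).
#' @slot spikeCountUsed number of spikes entering the average.
#' @slot cropBox list with integer vectors \code{rows}, \code{cols},
#'   \code{lags} indexing the crop region.
#' @slot stimulusMean mean intensity of the driving stimulus.
#' @export
setClass("STA",
  representation(kernel = "array", depthFrames = "integer",
                 spikeCountUsed = "integer", cropBox = "list",
                 stimulusMean = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@kernel)
    if (length(d) != 3L) msg <- c(msg, "kernel must be 3-D")
    else {
      if (d[1L] != object@depthFrames)
        msg <- c(msg, "kernel depth must equal depthFrames")
      cb <- object@cropBox
      if (length(cb)) {
        if (!all(c("rows", "cols", "lags") %in% names(cb)))
          msg <- c(msg, "cropBox needs rows, cols, lags")
        else if (any(cb$rows < 1 | cb$rows > d[2L]) ||
                 any(cb$cols < 1 | cb$cols > d[3L]) ||
                 any(cb$lags < 1 | cb$lags > d[1L]))
          msg <- c(msg, "cropBox must lie within kernel bounds")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' TimeCourse: temporal STA profile at the receptive-field centre
#'
#' @slot values mean-subtracted kernel values per frame lag at the spatial
#'   peak (oldest lag first).
#' @slot peakValue signed value of the largest-magnitude lag.
#' @slot snr |peak| over the RMS of the 10 earliest lags.
#' @export
setClass("TimeCourse",
  representation(values = "numeric", peakValue = "numeric", snr = "numeric"),
  validity = function(object) {
    if (length(object@values) < 1L) "values must be non-empty" else TRUE
  })

#' LNModel: linear filter plus static nonlinearity
#'
#' @slot kernel spatiotemporal filter (the training-segment STA, mean-subtracted).
#' @slot nlInput generator-signal grid (bin centres) of the nonlinearity lookup.
#' @slot nlRate firing rate (Hz) at each grid point; interpolated linearly,
#'   extrapolated as constant.
#' @slot frameRate stimulus frame rate the model was fitted at (Hz).
#' @slot cellId cell identifier.
#' @export
setClass("LNModel",
  representation(kernel = "array", nlInput = "numeric", nlRate = "numeric",
                 frameRate = "numeric", cellId = "character"),
  validity = function(object) {
    if (length(object@nlInput) != length(object@nlRate))
      "nlInput and nlRate must have equal length" else TRUE
  })

#' CCCCurve: characteristic correlation curve
#'
#' Pearson correlation between the full-spike STA and the STA computed from
#' the first \code{n} spikes, on the cropped kernel region, as a function of
#' the normalized spike fraction \code{n/N}.
#'
#' @slot fractions normalized spike counts n/N (increasing; last equals 1).
#' @slot correlations CCC values; the last is exactly 1.
#' @slot auc area under the curve over n/N in [0, 1].
#' @slot spikeCount total number of usable spikes N.
#' @export
setClass("CCCCurve",
  representation(fractions = "numeric", correlations = "numeric",
                 auc = "numeric", spikeCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@fractions) != length(object@correlations))
      msg <- c(msg, "fractions and correlations must match in length")
    if (length(object@fractions) &&
        abs(object@fractions[length(object@fractions)] - 1) > 1e-12)
      msg <- c(msg, "last fraction must equal 1")
    if (length(msg)) msg else TRUE
  })

#' NoiseFamily: reference CCCs at graded injected noise ratios
#'
#' @slot referenceId id of the reference cell.
#' @slot nrGrid increasing noise ratios in [0, 1].
#' @slot curves list of CCCCurve, one per grid point (seed-averaged AUCs in
#'   \code{aucs}).
#' @slot aucs mean AUC per grid point.
#' @export
setClass("NoiseFamily",
  representation(referenceId = "character", nrGrid = "numeric",
                 curves = "list", aucs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@nrGrid, strictly = TRUE))
      msg <- c(msg, "nrGrid must be strictly increasing")
    if (length(object@aucs) != length(object@nrGrid))
      msg <- c(msg, "one AUC per grid point required")
    if (length(msg)) msg else TRUE
  })

#' ResponseTemplate: per-orientation population rate template
#'
#' Mean firing rates in 5 ms bins over a 30 ms response window, per cell,
#' concatenated across cells into one vector for decoding.
#'
#' @slot orientation one of "up", "down", "left", "right".
#' @slot rates matrix \code{nCells x nBins} of mean rates (Hz).
#' @slot binWidth bin width in seconds (default 0.005).
#' @export
setClass("ResponseTemplate",
  representation(orientation = "character", rates = "matrix",
                 binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@orientation %in% c("up", "down", "left", "right"))
      msg <- c(msg, "orientation must be up/down/left/right")
    if (length(object@rates) && min(object@rates) < 0)
      msg <- c(msg, "rates must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' DecodingResult: outcome of a batch of decoding trials
#'
#' @slot trueOrientation,decodedOrientation per-trial labels.
#' @slot accuracy fraction of correctly decoded trials.
#' @slot config list describing the condition (nCells, cSizePx, nFlashes, seed).
#' @export
setClass("DecodingResult",
  representation(trueOrientation = "character",
                 decodedOrientation = "character",
                 accuracy = "numeric", config = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@trueOrientation) != length(object@decodedOrientation))
      msg <- c(msg, "label vectors must match in length")
    if (object@accuracy < 0 || object@accuracy > 1)
      msg <- c(msg, "accuracy must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' CNNModel: two-block convolutional encoding model
#'
#' Architecture: 2 x [2-D convolution -> parametric ReLU -> batch
#' normalization -> dropout] -> flatten -> dense, with a softplus output so
#' predicted Poisson rates are positive. Trained with Adam on a Poisson
#' negative log-likelihood plus L2 (weights) and L1 (output) penalties.
#'
#' @slot config hyperparameter list (see \code{\link{cnnConfig}}).
#' @slot params list of trained parameter arrays.
#' @slot lossHistory mean training loss per epoch.
#' @slot inputDim c(channels, height, width) of the stimulus window.
#' @slot nCells number of output units.
#' @export
setClass("CNNModel",
  representation(config = "list", params = "list", lossHistory = "numeric",
                 inputDim = "integer", nCells = "integer"))
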