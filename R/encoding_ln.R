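#' Contiguous train/test/discard split of a recording
#'
#' The default protocol uses a 20/20/60 train-test-discard split: the first
#' fifth of the frames trains the model, the second fifth tests it, the rest
#' is discarded. The five-fold cross-validation variant partitions the
#' recording into five equal sections and uses section \code{fold} for
#' training and the next section (cyclically) for testing.
#'
#' @param nFrames total number of frames.
#' @param trainFraction,testFraction fractions of the recording (defaults 0.2
#'   and 0.2; the remainder is discarded).
#' @param fold NULL for the default split, or an integer 1..5 selecting a
#'   cross-validation fold.
#' @return List with integer vectors \code{train} and \code{test}.
#' @export
trainTestSplit <- function(nFrames, trainFraction = 0.2, testFraction = 0.2,
                           fold = NULL) {
  nFrames <- as.integer(nFrames)
  if (is.null(fold)) {
    nTrain <- as.integer(floor(nFrames * trainFraction))
    nTest <- as.integer(floor(nFrames * testFraction))
    list(train = seq_len(nTrain), test = nTrain + seq_len(nTest))
  } else {
    k <- 5L
    fold <- as.integer(fold)
    if (fold < 1L || fold > k) stop("fold must be in 1..5")
    size <- nFrames %/% k
    sec <- function(i) ((i - 1L) * size + 1L):(i * size)
    list(train = sec(fold), test = sec(fold %% k + 1L))
  }
}

#' Fit a linear-nonlinear encoding model
#'
#' The linear filter is the spike-triggered average over the training
#' segment (mean-subtracted). The static nonlinearity is estimated by binning
#' the generator signal (filter output) into quantile bins and averaging the
#' observed per-frame spike counts in each bin, giving a monotone lookup that
#' is linearly interpolated and constantly extrapolated.
#'
#' @param stimulus a \linkS4class{StimulusMovie}.
#' @param train a \linkS4class{SpikeTrain} recorded under it.
#' @param split a \code{\link{trainTestSplit}}; defaults to 20/20/60.
#' @param depthFrames filter depth (default 24).
#' @param nBins number of quantile bins for the nonlinearity (default 25).
#' @param minSpikes minimum training spikes (default 100).
#' @return An \linkS4class{LNModel}.
#' @export
fitLN <- function(stimulus, train, split = NULL, depthFrames = 24L,
                  nBins = 25L, minSpikes = 100L) {
  frames <- stimFrames(stimulus)
  Tn <- dim(frames)[1L]
  fr <- frameRate(stimulus)
  if (is.null(split)) split <- trainTestSplit(Tn)
  trIdx <- split$train
  # spikes whose frame falls in the training segment
  tEnd <- max(trIdx) / fr; tStart <- (min(trIdx) - 1L) / fr
  st <- spikeTimes(train)
  stTr <- st[st >= tStart & st < tEnd]
  if (length(stTr) < minSpikes)
    stop(sprintf("only %d training spikes (< %d); segment too sparse to fit",
                 length(stTr), minSpikes))
  sub <- spikeTrain(stTr, duration(train), cellId(train))
  sta <- computeSTA(sub, stimulus, depthFrames)
  kern <- sta@kernel - sta@stimulusMean
  # generator signal and observed counts on the training segment
  S <- flattenFrames(frames) - mean(frames)
  g <- cellDrive(kern, S)
  counts <- binSpikes(train, fr, nBins = Tn)
  ok <- trIdx[!is.na(g[trIdx])]
  gTr <- g[ok]; cTr <- counts[ok]
  qs <- unique(stats::quantile(gTr, probs = seq(0, 1, length.out = nBins + 1L)))
  bins <- cut(gTr, qs, include.lowest = TRUE)
  nlInput <- tapply(gTr, bins, mean)
  nlRate <- tapply(cTr, bins, mean) * fr
  keep <- !is.na(nlInput)
  new("LNModel", kernel = kern, nlInput = as.numeric(nlInput[keep]),
      nlRate = pmax(0, as.numeric(nlRate[keep])), frameRate = fr,
      cellId = cellId(train))
}

#' Predict a firing-rate trace from an LN model
#'
#' Applies the linear filter to the (mean-subtracted) stimulus and maps the
#' generator signal through the fitted nonlinearity. The first
#' \code{depth} frames, which lack a full filter window, are filled with the
#' mean predicted rate.
#'
#' @param model an \linkS4class{LNModel}.
#' @param stimulus a \linkS4class{StimulusMovie}.
#' @return Nonnegative numeric rate (Hz) per frame.
#' @export
predictRate <- function(model, stimulus) {
  frames <- stimFrames(stimulus)
  S <- flattenFrames(frames) - mean(frames)
  g <- cellDrive(model@kernel, S)
  r <- stats::approx(model@nlInput, model@nlRate, xout = g, rule = 2)$y
  if (length(model@nlInput) == 1L) r <- rep(model@nlRate, length(g))
  r[is.na(g)] <- mean(r, na.rm = TRUE)
  pmax(0, r)
}

#' Correlate a predicted rate trace with an observed spike train
#'
#' With non-repeating stimuli there are no trial averages to correlate
#' against, so each spike is broadened with a Gaussian of sigma = 2 stimulus
#' frames (applied identically to the binned observed counts and the
#' prediction, truncated at 4 sigma) and the Pearson correlation is computed
#' over the evaluation segment.
#'
#' @param pred predicted rate per frame (full recording grid).
#' @param train observed \linkS4class{SpikeTrain}.
#' @param frameRate frame rate of the prediction grid (Hz).
#' @param segment integer frame indices to score (default: all frames).
#' @param sigmaFrames Gaussian broadening SD in frames (default 2).
#' @return Pearson r, or NA if either trace has zero variance.
#' @export
evaluateModel <- function(pred, train, frameRate, segment = NULL,
                          sigmaFrames = 2) {
  obs <- binSpikes(train, frameRate, nBins = length(pred))
  if (is.null(segment)) segment <- seq_along(pred)
  ps <- smoothTrace(pred, sigmaFrames)[segment]
  os <- smoothTrace(obs, sigmaFrames)[segment]
  safeCor(ps, os)
}

#' Five-fold cross-validated LN evaluation
#'
#' @param stimulus a \linkS4class{StimulusMovie}.
#' @param train a \linkS4class{SpikeTrain}.
#' @param folds number of folds (default 5).
#' @param ... passed to \code{\link{fitLN}}.
#' @return data.frame with columns \code{fold} and \code{r}.
#' @export
crossValidateLN <- function(stimulus, train, folds = 5L, ...) {
  Tn <- nFrames(stimulus)
  out <- lapply(seq_len(folds), function(k) {
    sp <- trainTestSplit(Tn, fold = k)
    m <- fitLN(stimulus, train, split = sp, ...)
    r <- evaluateModel(predictRate(m, stimulus), train,
                       frameRate(stimulus), segment = sp$test)
    data.frame(fold = k, r = r)
  })
  do.call(rbind, out)
}
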