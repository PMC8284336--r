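#' Characteristic correlation curve of a spike train
#'
#' For each n on a (log-spaced) grid up to the total spike count N, the STA
#' from the first n spikes (chronological order) is correlated with the
#' full-spike STA over the cropped kernel region (3 px x 3 px x 4 frames
#' around the peak). Prefix STAs are accumulated with a running mean so the
#' cost is O(N x box). The last point (n/N = 1) is exactly 1. A noiseless
#' responder gives a flat curve at 1; a purely spontaneous cell follows
#' sqrt(n/N).
#'
#' @param train a \linkS4class{SpikeTrain} with at least 2 usable spikes.
#' @param stimulus the evoking \linkS4class{StimulusMovie}.
#' @param cropBox crop region (list with rows/cols/lags); when NULL it is
#'   derived from the train's own full STA.
#' @param depthFrames STA depth (default 24).
#' @param maxPoints maximum number of curve points (log-spaced; default 200).
#' @param extendToZero AUC convention near n/N = 0: "constant" extends the
#'   first defined correlation, "zero" drops to 0.
#' @return A \linkS4class{CCCCurve}.
#' @export
computeCCC <- function(train, stimulus, cropBox = NULL, depthFrames = 24L,
                       maxPoints = 200L, extendToZero = c("constant", "zero")) {
  extendToZero <- match.arg(extendToZero)
  depthFrames <- as.integer(depthFrames)
  if (is.null(cropBox))
    cropBox <- computeSTA(train, stimulus, depthFrames)@cropBox
  vals <- spikeCropValues(train, stimulus, cropBox, depthFrames)
  N <- nrow(vals)
  if (N < 2L) stop("need at least 2 usable spikes")
  full <- colMeans(vals)
  if (stats::sd(full) == 0) {
    return(new("CCCCurve", fractions = 1, correlations = NA_real_,
               auc = NA_real_, spikeCount = as.integer(N)))
  }
  grid <- sort(unique(c(round(exp(seq(0, log(N),
                                      length.out = min(maxPoints, N)))), N)))
  csum <- apply(vals, 2L, cumsum)
  corr <- vapply(grid, function(n) safeCor(csum[n, ] / n, full), numeric(1L))
  corr[length(corr)] <- 1
  fr <- grid / N
  auc <- cccAUC(fr, corr, extendToZero)
  new("CCCCurve", fractions = fr, correlations = corr, auc = auc,
      spikeCount = as.integer(N))
}

# per-spike stimulus values over the cropped STA region: N x box matrix
spikeCropValues <- function(train, stimulus, cropBox, depthFrames) {
  frames <- stimFrames(stimulus)
  Tn <- dim(frames)[1L]
  S <- flattenFrames(frames)
  H <- dim(frames)[2L]
  pix <- as.vector(outer(cropBox$rows, (cropBox$cols - 1L) * H, `+`))
  fidx <- spikeFrameIndex(train, frameRate(stimulus))
  fidx <- fidx[fidx > depthFrames & fidx <= Tn]
  cols <- lapply(cropBox$lags, function(l)
    S[fidx - (depthFrames - l + 1L), pix, drop = FALSE])
  do.call(cbind, cols)
}

# trapezoidal AUC with the stated convention at n/N -> 0
cccAUC <- function(fractions, correlations, extendToZero = "constant") {
  if (anyNA(correlations)) return(NA_real_)
  if (fractions[1L] > 0) {
    c0 <- if (extendToZero == "constant") correlations[1L] else 0
    fractions <- c(0, fractions)
    correlations <- c(c0, correlations)
  }
  trapz(fractions, correlations)
}

#' Area under a characteristic correlation curve
#'
#' Trapezoidal integral of the CCC over n/N in [0, 1], extending the curve
#' from its smallest defined fraction to zero with its first value
#' (constant-extension convention; applied consistently to every curve, so
#' noise-ratio matching is insensitive to the choice).
#'
#' @param curve a \linkS4class{CCCCurve}.
#' @param extendToZero "constant" (default) or "zero".
#' @return The AUC.
#' @export
computeAUC <- function(curve, extendToZero = c("constant", "zero")) {
  extendToZero <- match.arg(extendToZero)
  cccAUC(curve@fractions, curve@correlations, extendToZero)
}

#' Select the reference cell with the median AUC
#'
#' The reference for noise matching is the visually stimulated cell with the
#' median AUC; on even counts the lower median is taken so the reference is
#' always an actual cell.
#'
#' @param aucs numeric AUCs of candidate cells (NAs dropped).
#' @param ids optional identifiers aligned with \code{aucs}.
#' @return The selected id (or index when \code{ids} is NULL).
#' @export
selectReferenceCell <- function(aucs, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(aucs)
  ok <- !is.na(aucs)
  aucs <- aucs[ok]; ids <- ids[ok]
  if (!length(aucs)) stop("no cells with a valid AUC")
  ord <- order(aucs)
  ids[ord[ceiling(length(aucs) / 2)]]
}

#' Build a family of noise-injected correlation curves
#'
#' Injects each noise ratio on the grid into the reference cell's spike train
#' (averaging AUCs over several seeds) and computes the CCC of each injected
#' train with the reference's own crop box, yielding the lookup family used
#' to convert a measured AUC into a noise-ratio estimate.
#'
#' @param reference the reference cell's \linkS4class{SpikeTrain}.
#' @param stimulus the evoking \linkS4class{StimulusMovie}.
#' @param nrGrid increasing noise ratios (default 0 to 1 in steps of 0.1).
#' @param nSeeds number of injection seeds averaged per grid point.
#' @param seed master seed.
#' @param depthFrames STA depth.
#' @return A \linkS4class{NoiseFamily}.
#' @export
buildNoiseFamily <- function(reference, stimulus,
                             nrGrid = seq(0, 1, by = 0.1), nSeeds = 3L,
                             seed = 1L, depthFrames = 24L) {
  cb <- computeSTA(reference, stimulus, depthFrames)@cropBox
  curves <- vector("list", length(nrGrid))
  aucs <- numeric(length(nrGrid))
  for (i in seq_along(nrGrid)) {
    vals <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
      inj <- injectNoise(reference, nrGrid[i],
                         seed = subSeed(seed, sprintf("nr%g_s%d", nrGrid[i], s)))
      cc <- computeCCC(inj, stimulus, cropBox = cb, depthFrames = depthFrames)
      vals[s] <- cc@auc
      if (s == 1L) curves[[i]] <- cc
    }
    aucs[i] <- mean(vals, na.rm = TRUE)
  }
  new("NoiseFamily", referenceId = cellId(reference), nrGrid = nrGrid,
      curves = curves, aucs = aucs)
}

#' Estimate a cell's noise ratio by AUC matching
#'
#' Finds the family curve whose AUC is most similar to the query curve's AUC.
#' By default the estimate is refined by linear interpolation between the two
#' bracketing grid points; \code{method = "nearest"} reproduces the strict
#' nearest-grid rule. Query AUCs outside the family range are clamped to the
#' boundary with a warning.
#'
#' @param curve a \linkS4class{CCCCurve} (or a bare AUC value).
#' @param family a \linkS4class{NoiseFamily}.
#' @param method "interpolate" (default) or "nearest".
#' @return Estimated noise ratio in [0, 1].
#' @export
matchNoiseRatio <- function(curve, family, method = c("interpolate", "nearest")) {
  method <- match.arg(method)
  query <- if (methods::is(curve, "CCCCurve")) curve@auc else as.numeric(curve)
  if (is.na(query)) stop("query curve has no defined AUC")
  if (length(family@nrGrid) < 2L) stop("family needs at least 2 grid points")
  aucs <- family@aucs
  if (query > max(aucs) || query < min(aucs)) {
    warning("query AUC outside the family range; clamped to the boundary")
    query <- min(max(query, min(aucs)), max(aucs))
  }
  if (method == "nearest")
    return(family@nrGrid[which.min(abs(aucs - query))])
  ord <- order(aucs)
  stats::approx(aucs[ord], family@nrGrid[ord], xout = query,
                ties = mean, rule = 2)$y
}
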