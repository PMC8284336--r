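#' Input strength of a stimulus block through a cell's filter
#'
#' Plain inner product of the spatiotemporal filter with an aligned stimulus
#' block of the same dimensions.
#'
#' @param w filter array (depth x H x W), e.g. an STA kernel.
#' @param block stimulus block array of identical dimensions.
#' @return Scalar strength.
#' @export
inputStrength <- function(w, block) {
  if (!identical(dim(w), dim(block)))
    stop("filter and block dimensions differ")
  sum(w * block)
}

#' Align a letter movie with a filter's temporal window
#'
#' Returns the trailing \code{depth} frames of the movie, optionally
#' resampling the time axis first (linear interpolation per pixel) when the
#' decoder's cells were mapped at a different frame rate (e.g. 20 Hz
#' electrical filters driven by a 30 Hz letter movie).
#'
#' @param movie a \linkS4class{StimulusMovie}.
#' @param depth number of trailing frames to keep.
#' @param targetRate resample to this frame rate first (NULL = keep native).
#' @return Array \code{depth x H x W}.
#' @export
alignStimulusBlock <- function(movie, depth, targetRate = NULL) {
  frames <- stimFrames(movie)
  d <- dim(frames)
  if (!is.null(targetRate) && targetRate != frameRate(movie)) {
    nNew <- max(depth, round(d[1L] / frameRate(movie) * targetRate))
    tOld <- (seq_len(d[1L]) - 0.5) / frameRate(movie)
    tNew <- (seq_len(nNew) - 0.5) / targetRate
    S <- apply(flattenFrames(frames), 2L, function(col)
      stats::approx(tOld, col, xout = tNew, rule = 2)$y)
    frames <- array(S, dim = c(nNew, d[2L], d[3L]))
    d <- dim(frames)
  }
  if (d[1L] < depth) stop("movie shorter than the filter depth")
  frames[(d[1L] - depth + 1L):d[1L], , , drop = FALSE]
}

#' Find white-noise blocks matching a target input strength
#'
#' Scans every block of \code{depth} consecutive frames (stride 1) of the
#' white-noise movie and returns the k blocks whose filter drive w . s is
#' closest to the target strength w . s-hat, ranked by ascending residual.
#'
#' @param whiteNoise a \linkS4class{StimulusMovie}.
#' @param w filter array (depth x H x W) matching the movie's spatial size.
#' @param targetStrength the target drive.
#' @param k number of blocks to return (default 500).
#' @param disjoint require non-overlapping blocks (greedy selection).
#' @return List with \code{starts} (frame indices), \code{residuals}
#'   (nondecreasing) and \code{strengths}.
#' @export
findMatchingBlocks <- function(whiteNoise, w, targetStrength, k = 500L,
                               disjoint = FALSE) {
  frames <- stimFrames(whiteNoise)
  depth <- dim(w)[1L]
  S <- flattenFrames(frames)
  strengths <- blockStrengths(S, w)
  nBlocks <- length(strengths)
  if (k > nBlocks) stop(sprintf("k = %d exceeds the %d available blocks",
                                k, nBlocks))
  resid <- abs(strengths - targetStrength)
  ord <- order(resid)
  if (disjoint) {
    chosen <- integer()
    for (t in ord) {
      if (!length(chosen) || all(abs(chosen - t) >= depth))
        chosen <- c(chosen, t)
      if (length(chosen) == k) break
    }
    ord <- chosen
  } else ord <- ord[seq_len(k)]
  list(starts = ord, residuals = resid[ord], strengths = strengths[ord])
}

# drive of every consecutive-frame block: strength[t] = sum_l S[t+l-1,].W[l,]
blockStrengths <- function(S, w) {
  depth <- dim(w)[1L]
  Wl <- matrix(w, nrow = depth)
  Tn <- nrow(S)
  M <- S %*% t(Wl)
  nBlocks <- Tn - depth + 1L
  acc <- numeric(nBlocks)
  idx <- seq_len(nBlocks)
  for (l in seq_len(depth)) acc <- acc + M[idx + l - 1L, l]
  acc
}

#' Build per-orientation population response templates
#'
#' For each orientation, the pixelated letter movie is rendered, each cell's
#' filter picks its own 500 best-matching white-noise blocks (per-cell
#' matching), and the cell's observed spiking in the 30 ms after each block
#' is averaged in 5 ms bins. Per-cell rate rows are stacked into one
#' template per orientation.
#'
#' @param kernels list of per-cell filter arrays (depth x H x W).
#' @param trains list of matching \linkS4class{SpikeTrain} on the white noise.
#' @param whiteNoise the white-noise \linkS4class{StimulusMovie}.
#' @param sizePx Landolt-C diameter in pixels (default 14).
#' @param windowMs response window after each block (default 30).
#' @param binMs bin width (default 5).
#' @param k matched blocks per cell (default 500).
#' @param landoltArgs extra arguments passed to \code{\link{landoltSpec}}.
#' @return Named list of four \linkS4class{ResponseTemplate} (up, down,
#'   left, right).
#' @export
buildTemplates <- function(kernels, trains, whiteNoise, sizePx = 14,
                           windowMs = 30, binMs = 5, k = 500L,
                           landoltArgs = list()) {
  frames <- stimFrames(whiteNoise)
  canvas <- dim(frames)[2:3]
  depth <- dim(kernels[[1L]])[1L]
  fr <- frameRate(whiteNoise)
  nBins <- as.integer(round(windowMs / binMs))
  binW <- binMs / 1000
  orientations <- c("up", "down", "left", "right")
  S <- flattenFrames(frames)
  strengthsPerCell <- lapply(kernels, function(w) blockStrengths(S, w))
  out <- lapply(orientations, function(ori) {
    spec <- do.call(landoltSpec, c(list(orientation = ori, sizePx = sizePx,
                                        canvas = canvas), landoltArgs))
    movie <- generateLandoltC(spec, frameRate = fr,
                              pixelPitch = pixelPitch(whiteNoise),
                              modality = modality(whiteNoise))
    block <- alignStimulusBlock(movie, depth, targetRate = fr)
    rates <- matrix(0, length(kernels), nBins)
    for (ci in seq_along(kernels)) {
      target <- inputStrength(kernels[[ci]], block)
      resid <- abs(strengthsPerCell[[ci]] - target)
      starts <- order(resid)[seq_len(min(k, length(resid)))]
      endT <- (starts + depth - 1L) / fr
      st <- spikeTimes(trains[[ci]])
      counts <- numeric(nBins)
      for (b in seq_len(nBins)) {
        lo <- endT + (b - 1L) * binW
        counts[b] <- sum(findInterval(lo + binW, st) - findInterval(lo, st))
      }
      rates[ci, ] <- counts / length(starts) / binW
    }
    new("ResponseTemplate", orientation = ori, rates = rates, binWidth = binW)
  })
  names(out) <- orientations
  out
}

#' Simulate one decoding trial from a template
#'
#' Each time bin's spike count is a Poisson draw with mean equal to the
#' template rate times the bin width, summed over independent presentations
#' (flashes).
#'
#' @param template a \linkS4class{ResponseTemplate}.
#' @param nFlashes number of presentations accumulated (default 1).
#' @param seed optional integer seed (NULL continues the current RNG stream).
#' @return Integer vector of per-bin counts (cells concatenated).
#' @export
simulateTrial <- function(template, nFlashes = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lam <- templateVector(template) * template@binWidth * nFlashes
  stats::rpois(length(lam), lam)
}

#' Decode a trial by template correlation
#'
#' The trial count vector is Pearson-correlated with each orientation's
#' template; the highest r wins. Ties (and zero-variance trials) are broken
#' uniformly at random from the current RNG stream.
#'
#' @param trial count vector from \code{\link{simulateTrial}}.
#' @param templates named list of four \linkS4class{ResponseTemplate}.
#' @return The decoded orientation label.
#' @export
decodeTrial <- function(trial, templates) {
  rs <- vapply(templates, function(tp) {
    r <- safeCor(trial, templateVector(tp))
    if (is.na(r)) -Inf else r
  }, numeric(1L))
  if (all(!is.finite(rs))) return(names(templates)[sample.int(4L, 1L)])
  best <- which(rs == max(rs))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  names(templates)[best]
}

#' Run a batch of decoding trials with random orientations
#'
#' @param templates named list of four \linkS4class{ResponseTemplate}.
#' @param nTrials number of trials.
#' @param nFlashes presentations per trial.
#' @param seed integer seed.
#' @param config extra condition metadata stored in the result.
#' @return A \linkS4class{DecodingResult}.
#' @export
runDecodingTrials <- function(templates, nTrials = 10000L, nFlashes = 1L,
                              seed = 1L, config = list()) {
  set.seed(as.integer(seed))
  oris <- names(templates)
  truth <- oris[sample.int(4L, nTrials, replace = TRUE)]
  decoded <- character(nTrials)
  for (i in seq_len(nTrials)) {
    trial <- simulateTrial(templates[[truth[i]]], nFlashes)
    decoded[i] <- decodeTrial(trial, templates)
  }
  new("DecodingResult", trueOrientation = truth,
      decodedOrientation = decoded, accuracy = mean(truth == decoded),
      config = c(config, list(nFlashes = nFlashes, seed = seed)))
}

# restrict templates to a subset of cells
subsetTemplates <- function(templates, cellIdx) {
  lapply(templates, function(tp)
    new("ResponseTemplate", orientation = tp@orientation,
        rates = tp@rates[cellIdx, , drop = FALSE], binWidth = tp@binWidth))
}

#' Decoding-accuracy experiments along cell-count, letter-size or flash axes
#'
#' Reproduces the three experiment axes:
#' \describe{
#'   \item{"n_cells"}{letter fixed at 14 px; cells added in rank order of
#'     their independent single-cell decoding accuracy.}
#'   \item{"c_size"}{all cells; letter size varied over the grid.}
#'   \item{"n_flashes"}{all cells; presentations per trial varied.}
#' }
#'
#' @param kernels,trains,whiteNoise as in \code{\link{buildTemplates}}.
#' @param axis "n_cells", "c_size" or "n_flashes".
#' @param grid axis values.
#' @param nTrials trials per grid point (default 10000).
#' @param seed master seed; every grid point uses a named substream.
#' @param cSizePx letter size for the n_cells and n_flashes axes (default 14).
#' @param nFlashes presentations for the n_cells and c_size axes (default 1).
#' @param rankTrials trials used to rank single cells (n_cells axis).
#' @param k matched blocks per cell.
#' @return List with \code{summary} (data.frame axisValue/accuracy/nTrials)
#'   and \code{results} (list of \linkS4class{DecodingResult}).
#' @export
runExperiment <- function(kernels, trains, whiteNoise,
                          axis = c("n_cells", "c_size", "n_flashes"),
                          grid, nTrials = 10000L, seed = 1L, cSizePx = 14,
                          nFlashes = 1L, rankTrials = 300L, k = 500L) {
  axis <- match.arg(axis)
  if (!length(grid)) stop("grid must be nonempty")
  results <- list()
  if (axis == "c_size") {
    for (g in seq_along(grid)) {
      tpl <- buildTemplates(kernels, trains, whiteNoise, sizePx = grid[g],
                            k = k)
      results[[g]] <- runDecodingTrials(
        tpl, nTrials, nFlashes, seed = subSeed(seed, paste0("size", grid[g])),
        config = list(cSizePx = grid[g], nCells = length(kernels)))
    }
  } else {
    tpl <- buildTemplates(kernels, trains, whiteNoise, sizePx = cSizePx, k = k)
    if (axis == "n_cells") {
      singles <- vapply(seq_along(kernels), function(ci) {
        accuracy(runDecodingTrials(subsetTemplates(tpl, ci), rankTrials,
                                   nFlashes,
                                   seed = subSeed(seed, paste0("rank", ci))))
      }, numeric(1L))
      rank <- order(singles, decreasing = TRUE)
      for (g in seq_along(grid)) {
        idx <- rank[seq_len(min(grid[g], length(kernels)))]
        results[[g]] <- runDecodingTrials(
          subsetTemplates(tpl, idx), nTrials, nFlashes,
          seed = subSeed(seed, paste0("cells", grid[g])),
          config = list(nCells = length(idx), cSizePx = cSizePx))
      }
    } else {
      for (g in seq_along(grid)) {
        results[[g]] <- runDecodingTrials(
          tpl, nTrials, nFlashes = grid[g],
          seed = subSeed(seed, paste0("flashes", grid[g])),
          config = list(nCells = length(kernels), cSizePx = cSizePx))
      }
    }
  }
  summary <- data.frame(axis = axis, axisValue = grid,
                        accuracy = vapply(results, accuracy, numeric(1L)),
                        nTrials = nTrials)
  list(summary = summary, results = results)
}
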