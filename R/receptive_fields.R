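#' Compute the spike-triggered average of a spike train
#'
#' Mean of the \code{depthFrames} stimulus frames strictly preceding each
#' spike's frame, oldest lag first. Spikes too early to have a full preceding
#' window are skipped; the number of spikes actually used is recorded. The
#' crop box (3 px x 3 px x 4 frames around the kernel peak) is attached for
#' correlation-curve analyses.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param stimulus the \linkS4class{StimulusMovie} that evoked it.
#' @param depthFrames temporal depth of the average (default 24).
#' @return An \linkS4class{STA}.
#' @export
computeSTA <- function(train, stimulus, depthFrames = 24L) {
  depthFrames <- as.integer(depthFrames)
  frames <- stimFrames(stimulus)
  Tn <- dim(frames)[1L]
  fidx <- spikeFrameIndex(train, frameRate(stimulus))
  fidx <- fidx[fidx > depthFrames & fidx <= Tn]
  if (!length(fidx)) stop("no usable spikes with a full preceding window")
  S <- flattenFrames(frames)
  P <- ncol(S)
  kern <- array(0, dim = c(depthFrames, dim(frames)[2L], dim(frames)[3L]))
  km <- matrix(0, nrow = depthFrames, ncol = P)
  for (l in seq_len(depthFrames))
    km[l, ] <- colMeans(S[fidx - (depthFrames - l + 1L), , drop = FALSE])
  kern[] <- km
  sMean <- mean(frames)
  sta <- new("STA", kernel = kern, depthFrames = depthFrames,
             spikeCountUsed = length(fidx), cropBox = list(),
             stimulusMean = sMean)
  sta@cropBox <- defaultCropBox(sta)
  sta
}

# frame index containing each spike (frame f spans [(f-1)/rate, f/rate))
spikeFrameIndex <- function(train, rate) {
  floor(spikeTimes(train) * rate) + 1L
}

#' Default crop box around the STA peak
#'
#' The peak voxel is the arg-max of |kernel - stimulus mean| over all voxels,
#' ties broken by earliest lag then row-major order. The box is 3 px x 3 px
#' spatially centred on the peak and 4 frames ending at the peak lag, shifted
#' where needed to stay inside the kernel.
#'
#' @param sta an \linkS4class{STA}.
#' @param boxPx spatial extent (default 3).
#' @param boxFrames temporal extent (default 4).
#' @return List with integer vectors \code{rows}, \code{cols}, \code{lags}
#'   and the peak voxel \code{peak = c(lag, row, col)}.
#' @export
defaultCropBox <- function(sta, boxPx = 3L, boxFrames = 4L) {
  a <- abs(sta@kernel - sta@stimulusMean)
  d <- dim(a)
  cand <- which(a == max(a), arr.ind = TRUE)      # cols: lag, row, col
  cand <- cand[order(cand[, 1L], cand[, 2L], cand[, 3L]), , drop = FALSE]
  pk <- cand[1L, ]
  span <- function(centre, size, lo, hi, anchorEnd = FALSE) {
    size <- min(size, hi - lo + 1L)
    start <- if (anchorEnd) centre - size + 1L else centre - size %/% 2L
    start <- min(max(lo, start), hi - size + 1L)
    start:(start + size - 1L)
  }
  list(rows = span(pk[2L], boxPx, 1L, d[2L]),
       cols = span(pk[3L], boxPx, 1L, d[3L]),
       lags = span(pk[1L], boxFrames, 1L, d[1L], anchorEnd = TRUE),
       peak = as.integer(pk))
}

#' Extract the STA time course at the receptive-field centre
#'
#' Temporal profile of the kernel at the spatial peak pixel (or the mean over
#' the crop box's spatial extent), with the stimulus mean subtracted so a
#' featureless STA gives an all-zero time course.
#'
#' @param sta an \linkS4class{STA}.
#' @param spatialAverage average over the crop box instead of the single
#'   peak pixel.
#' @return A \linkS4class{TimeCourse}.
#' @export
extractTimeCourse <- function(sta, spatialAverage = FALSE) {
  cb <- sta@cropBox
  if (spatialAverage) {
    v <- apply(sta@kernel[, cb$rows, cb$cols, drop = FALSE], 1L, mean)
  } else {
    v <- sta@kernel[, cb$peak[2L], cb$peak[3L]]
  }
  v <- v - sta@stimulusMean
  pk <- v[which.max(abs(v))]
  tc <- new("TimeCourse", values = v, peakValue = pk, snr = NA_real_)
  tc@snr <- computeSNR(tc)
  tc
}

#' Signal-to-noise ratio of a time course
#'
#' |peak| divided by the RMS of the 10 time-course values farthest from the
#' spike (the 10 earliest lags). Cells below SNR 3 are conventionally
#' excluded from analysis.
#'
#' @param tc a \linkS4class{TimeCourse} of length >= 11.
#' @return SNR (Inf when the noise RMS is zero).
#' @export
computeSNR <- function(tc) {
  v <- tc@values
  if (length(v) < 11L) stop("time course must have at least 11 lags")
  noise <- sqrt(mean(v[1:10]^2))
  pk <- abs(v[which.max(abs(v))])
  if (noise == 0) return(Inf)
  pk / noise
}

#' Classify a cell as ON or OFF from its time course
#'
#' The sign of the lobe nearest the spike time sets the label: positive = ON,
#' negative = OFF. Under subretinal anodic electrical stimulation of the
#' healthy retina the photoreceptor terminals are depolarized, which acts
#' like a visual OFF stimulus, so the label is inverted: a visual ON cell of
#' a healthy retina appears as an electrical OFF cell.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param modality "visual" or "electrical".
#' @param retinaType "LE" (healthy) or "RCS" (degenerate); the inversion rule
#'   applies only to healthy-retina electrical recordings.
#' @param eps absolute amplitude below which the cell is left unclassified.
#' @return "ON", "OFF", or NA when ambiguous.
#' @export
classifyPolarity <- function(tc, modality = "visual", retinaType = "LE",
                             eps = 1e-9) {
  v <- tc@values
  amp <- max(abs(v))
  if (amp < eps) return(NA_character_)
  # local extrema (interior sign changes of the first difference + endpoints)
  dv <- diff(v)
  ext <- c(1L, which(dv[-1L] * dv[-length(dv)] <= 0) + 1L, length(v))
  ext <- ext[abs(v[ext]) >= 0.25 * amp]
  if (!length(ext)) return(NA_character_)
  lobe <- v[ext[length(ext)]]                     # nearest the spike
  label <- if (lobe > 0) "ON" else "OFF"
  if (modality == "electrical" && retinaType %in% c("LE", "healthy"))
    label <- if (label == "ON") "OFF" else "ON"
  label
}

#' Apply the cell-selection criteria with an audit log
#'
#' Filters a per-cell table on contamination (< 10%), time-course SNR
#' (>= 3) and, for healthy-retina comparisons, soma-under-implant and
#' dual-responsiveness flags. Every exclusion is logged with the criterion
#' that caused it; applying the filter twice changes nothing.
#'
#' @param records data.frame with columns \code{cellId}, \code{contamination},
#'   \code{snr}, and optionally \code{underImplant}, \code{dualResponsive}.
#' @param maxContamination exclusion threshold on contamination (default 0.10).
#' @param minSNR inclusion threshold on SNR (default 3).
#' @param requireUnderImplant,requireDualResponsive enforce the healthy-retina
#'   region and dual-modality criteria.
#' @return List with \code{records} (kept rows) and \code{audit}
#'   (cellId, criterion, decision).
#' @export
selectCells <- function(records, maxContamination = 0.10, minSNR = 3,
                        requireUnderImplant = FALSE,
                        requireDualResponsive = FALSE) {
  audit <- data.frame(cellId = character(), criterion = character(),
                      decision = character(), stringsAsFactors = FALSE)
  if (!nrow(records)) return(list(records = records, audit = audit))
  fail <- function(flag, criterion) {
    flag[is.na(flag)] <- TRUE
    if (any(flag))
      audit <<- rbind(audit, data.frame(
        cellId = records$cellId[flag], criterion = criterion,
        decision = "excluded", stringsAsFactors = FALSE))
    flag
  }
  drop <- fail(records$contamination >= maxContamination, "contamination")
  drop <- drop | fail(records$snr < minSNR, "snr")
  if (requireUnderImplant)
    drop <- drop | fail(!records$underImplant, "under_implant")
  if (requireDualResponsive)
    drop <- drop | fail(!records$dualResponsive, "dual_responsive")
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept))
    audit <- rbind(audit, data.frame(cellId = kept$cellId, criterion = "all",
                                     decision = "kept",
                                     stringsAsFactors = FALSE))
  list(records = kept, audit = audit)
}

#' Fit a 2-D Gaussian ellipse to the peak-lag receptive field
#'
#' Moment-based initialization (weighted centroid and covariance of the
#' rectified peak-lag frame) refined by Nelder-Mead least squares on an
#' elliptical Gaussian. Non-convergence is flagged, not fatal, and the
#' moment estimates are returned in that case.
#'
#' @param sta an \linkS4class{STA}.
#' @return List with \code{center} (row, col), \code{sigmaMajor},
#'   \code{sigmaMinor}, \code{angle} (radians), \code{amplitude},
#'   \code{converged}.
#' @export
fitRFEllipse <- function(sta) {
  pk <- sta@cropBox$peak
  f <- sta@kernel[pk[1L], , ] - sta@stimulusMean
  if (f[pk[2L], pk[3L]] < 0) f <- -f
  w <- pmax(f, 0)
  if (sum(w) == 0) stop("featureless peak frame")
  H <- nrow(w); W <- ncol(w)
  rs <- row(w); cs <- col(w)
  tot <- sum(w)
  mu <- c(sum(rs * w), sum(cs * w)) / tot
  crr <- sum((rs - mu[1L])^2 * w) / tot
  ccc <- sum((cs - mu[2L])^2 * w) / tot
  crc <- sum((rs - mu[1L]) * (cs - mu[2L]) * w) / tot
  S <- matrix(c(crr, crc, crc, ccc), 2L)
  eg <- eigen(S, symmetric = TRUE)
  init <- c(amp = max(w), mur = mu[1L], muc = mu[2L],
            ls1 = log(sqrt(max(eg$values[1L], 1e-4))),
            ls2 = log(sqrt(max(eg$values[2L], 1e-4))),
            ang = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]))
  model <- function(p) {
    ca <- cos(p[6L]); sa <- sin(p[6L])
    u <- (rs - p[2L]) * ca + (cs - p[3L]) * sa
    v <- -(rs - p[2L]) * sa + (cs - p[3L]) * ca
    p[1L] * exp(-0.5 * ((u / exp(p[4L]))^2 + (v / exp(p[5L]))^2))
  }
  obj <- function(p) sum((f - model(p))^2)
  fit <- tryCatch(stats::optim(init, obj, control = list(maxit = 2000)),
                  error = function(e) NULL)
  converged <- !is.null(fit) && fit$convergence == 0
  p <- if (converged) fit$par else init
  s1 <- exp(p[4L]); s2 <- exp(p[5L])
  list(center = c(row = unname(p[2L]), col = unname(p[3L])),
       sigmaMajor = max(s1, s2), sigmaMinor = min(s1, s2),
       angle = unname(p[6L]) %% pi, amplitude = unname(p[1L]),
       converged = converged)
}
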