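#' Generate a spatiotemporal binary white-noise movie
#'
#' Each pixel in each frame is independently bright with probability
#' \code{pBright} (default 0.5, the balanced checkerboard used for
#' receptive-field mapping). Visual stimulation uses 30 Hz frames of 60 um
#' pixels; electrical stimulation uses 20 Hz frames of 70 um pixels.
#'
#' @param shape integer vector \code{c(T, H, W)}: frames, height, width.
#' @param frameRate frames per second (Hz).
#' @param pBright probability a pixel is bright, in [0, 1].
#' @param pixelPitch pixel width on the retina (um).
#' @param modality \code{"visual"} or \code{"electrical"}.
#' @param seed integer seed; identical seeds give identical movies.
#' @return A \linkS4class{StimulusMovie} with values in \{0, 1\}.
#' @examples
#' mov <- generateWhiteNoise(c(100, 8, 8), frameRate = 30, seed = 1)
#' mean(stimFrames(mov))
#' @export
generateWhiteNoise <- function(shape, frameRate = 30, pBright = 0.5,
                               pixelPitch = 60, modality = "visual",
                               seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("shape must be three positive integers c(T, H, W)")
  if (pBright < 0 || pBright > 1) stop("pBright must lie in [0, 1]")
  set.seed(as.integer(seed))
  vals <- stats::rbinom(prod(shape), 1L, pBright)
  frames <- array(as.numeric(vals), dim = shape)
  new("StimulusMovie", frames = frames, frameRate = frameRate,
      pixelPitch = pixelPitch, modality = modality)
}

#' Landolt-C geometry in continuous stimulus-pixel units
#'
#' In the Sloan/Landolt convention the gap and the ring stroke are each 1/5 of
#' the letter diameter. The renderer works on a supersampled raster where
#' these are exact continuous lengths; \code{gapPx} is the integer gap extent
#' at stimulus resolution (rounded, minimum 1).
#'
#' @param sizePx letter (outer) diameter in stimulus pixels.
#' @return List with \code{outerRadius}, \code{innerRadius}, \code{gapWidth},
#'   \code{strokeWidth} (continuous, stimulus-pixel units) and \code{gapPx}.
#' @export
landoltGeometry <- function(sizePx) {
  if (sizePx < 2) stop("sizePx must be >= 2")
  gap <- sizePx / 5
  list(outerRadius = sizePx / 2, innerRadius = sizePx / 2 - gap,
       gapWidth = gap, strokeWidth = gap, gapPx = max(1L, as.integer(round(gap))))
}

#' Specification of a pixelated Landolt-C presentation
#'
#' @param orientation gap direction: "up", "down", "left" or "right".
#' @param sizePx letter diameter in stimulus pixels (>= 2).
#' @param canvas \code{c(height, width)} of the stimulus in pixels.
#' @param greyLevels number of evenly spaced quantization levels (default 8).
#' @param nDarkFrames all-dark lead-in frames (default 19).
#' @param nBrightFrames frames displaying the letter (default 5).
#' @param center letter centre \code{c(row, col)}; defaults to the canvas centre.
#' @param ringLevel,bgLevel intensities of the ring and of the background/gap
#'   within bright frames (defaults: dark ring 0 on bright background 1).
#' @return A list of class \code{"LandoltSpec"}.
#' @export
landoltSpec <- function(orientation = "up", sizePx = 14, canvas = c(20, 20),
                        greyLevels = 8L, nDarkFrames = 19L, nBrightFrames = 5L,
                        center = NULL, ringLevel = 0, bgLevel = 1) {
  orientation <- match.arg(orientation, c("up", "down", "left", "right"))
  if (sizePx < 2) stop("sizePx must be >= 2")
  if (is.null(center)) center <- (canvas + 1) / 2
  if (sizePx > min(canvas)) stop("letter exceeds canvas")
  structure(list(orientation = orientation, sizePx = sizePx, canvas = canvas,
                 greyLevels = as.integer(greyLevels),
                 nDarkFrames = as.integer(nDarkFrames),
                 nBrightFrames = as.integer(nBrightFrames),
                 center = center, ringLevel = ringLevel, bgLevel = bgLevel),
            class = "LandoltSpec")
}

# render a single Landolt-C image at stimulus resolution:
# anti-aliased supersampled annulus, block-averaged, then quantized
renderLandoltImage <- function(spec, supersample = 8L) {
  geom <- landoltGeometry(spec$sizePx)
  H <- spec$canvas[1L]; W <- spec$canvas[2L]; up <- as.integer(supersample)
  # high-resolution pixel-centre coordinates in stimulus-pixel units;
  # spec$center is in pixel-index units (pixel i spans i-1..i, centre i-0.5)
  ctr <- spec$center - 0.5
  rr <- (seq_len(H * up) - 0.5) / up
  cc <- (seq_len(W * up) - 0.5) / up
  dr <- outer(rr - ctr[1L], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - ctr[2L])
  rad <- sqrt(dr^2 + dc^2)
  ring <- rad <= geom$outerRadius & rad >= geom$innerRadius
  half <- geom$gapWidth / 2
  gapMask <- switch(spec$orientation,
    up    = abs(dc) <= half & dr < 0,
    down  = abs(dc) <= half & dr > 0,
    left  = abs(dr) <= half & dc < 0,
    right = abs(dr) <= half & dc > 0)
  img <- matrix(spec$bgLevel, nrow = H * up, ncol = W * up)
  img[ring & !gapMask] <- spec$ringLevel
  # block-average down to stimulus resolution
  blk <- matrix(0, nrow = H, ncol = W)
  for (i in seq_len(H)) {
    rows <- ((i - 1L) * up + 1L):(i * up)
    sub <- img[rows, , drop = FALSE]
    csum <- colSums(sub)
    blk[i, ] <- tapply(csum, rep(seq_len(W), each = up), sum) / up^2
  }
  # quantize to greyLevels evenly spaced values, ties rounded half-up
  L <- spec$greyLevels
  q <- floor(blk * (L - 1) + 0.5) / (L - 1)
  pmin(pmax(q, 0), 1)
}

#' Generate a pixelated Landolt-C movie
#'
#' The first \code{nDarkFrames} frames are all dark; the remaining
#' \code{nBrightFrames} frames display the letter at a fixed position.
#' The continuous letter is rendered on a supersampled raster, block-averaged
#' to stimulus pixels, and each pixel rounded to the nearest of
#' \code{greyLevels} evenly spaced greyscale levels.
#'
#' @param spec a \code{\link{landoltSpec}}.
#' @param frameRate frames per second (Hz).
#' @param pixelPitch pixel pitch on the retina (um).
#' @param modality \code{"visual"} or \code{"electrical"}.
#' @param supersample supersampling factor for anti-aliased rendering.
#' @return A \linkS4class{StimulusMovie} of
#'   \code{nDarkFrames + nBrightFrames} frames.
#' @examples
#' mov <- generateLandoltC(landoltSpec("up", sizePx = 10, canvas = c(20, 20)))
#' dim(stimFrames(mov))
#' @export
generateLandoltC <- function(spec, frameRate = 30, pixelPitch = 60,
                             modality = "visual", supersample = 8L) {
  img <- renderLandoltImage(spec, supersample)
  total <- spec$nDarkFrames + spec$nBrightFrames
  frames <- array(0, dim = c(total, spec$canvas[1L], spec$canvas[2L]))
  for (f in (spec$nDarkFrames + 1L):total) frames[f, , ] <- img
  new("StimulusMovie", frames = frames, frameRate = frameRate,
      pixelPitch = pixelPitch, modality = modality)
}
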