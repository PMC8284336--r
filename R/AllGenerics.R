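#' @include AllClasses.R
NULL

#' Accessors for stimulus and spike objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of the matching class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stimFrames", function(object) standardGeneric("stimFrames"))
#' @rdname accessors
#' @export
setMethod("stimFrames", "StimulusMovie", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "StimulusMovie", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setMethod("pixelPitch", "StimulusMovie", function(object) object@pixelPitch)

#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setMethod("modality", "StimulusMovie", function(object) object@modality)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "StimulusMovie", function(object) dim(object@frames)[1L])

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@spikeTimes)

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setMethod("duration", "SpikeTrain", function(object) object@duration)

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(object) length(object@spikeTimes))

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setMethod("cellId", "SpikeTrain", function(object) object@cellId)
#' @rdname accessors
#' @export
setMethod("cellId", "GroundTruthCell", function(object) object@cellId)

#' @rdname accessors
#' @export
setGeneric("staKernel", function(object) standardGeneric("staKernel"))
#' @rdname accessors
#' @export
setMethod("staKernel", "STA", function(object) object@kernel)
#' @rdname accessors
#' @export
setMethod("staKernel", "LNModel", function(object) object@kernel)

#' @rdname accessors
#' @export
setGeneric("cropBox", function(object) standardGeneric("cropBox"))
#' @rdname accessors
#' @export
setMethod("cropBox", "STA", function(object) object@cropBox)

#' @rdname accessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setMethod("aucValue", "CCCCurve", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("templateVector", function(object) standardGeneric("templateVector"))
#' @rdname accessors
#' @export
setMethod("templateVector", "ResponseTemplate",
          function(object) as.vector(t(object@rates)))

setMethod("show", "StimulusMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("StimulusMovie: %d frames of %d x %d px, %g Hz, %g um pitch, %s\n",
              d[1L], d[2L], d[3L], object@frameRate, object@pixelPitch,
              object@modality))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (%.2f Hz)\n",
              object@cellId, length(object@spikeTimes), object@duration,
              length(object@spikeTimes) / object@duration))
})

setMethod("show", "STA", function(object) {
  d <- dim(object@kernel)
  cat(sprintf("STA: %d x %d x %d kernel from %d spikes\n",
              d[1L], d[2L], d[3L], object@spikeCountUsed))
})

setMethod("show", "CCCCurve", function(object) {
  cat(sprintf("CCCCurve: %d points, N = %d spikes, AUC = %.4f\n",
              length(object@fractions), object@spikeCount, object@auc))
})

setMethod("show", "NoiseFamily", function(object) {
  cat(sprintf("NoiseFamily (reference '%s'): NR grid [%s]\n  AUCs [%s]\n",
              object@referenceId,
              paste(format(object@nrGrid), collapse = ", "),
              paste(format(round(object@aucs, 3)), collapse = ", ")))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d trials, accuracy %.3f\n",
              length(object@trueOrientation), object@accuracy))
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel: input %s, %d output cell(s), %d epochs trained\n",
              paste(object@inputDim, collapse = "x"), object@nCells,
              length(object@lossHistory)))
})
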