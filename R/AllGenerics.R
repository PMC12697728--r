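#' Number of images in an object
#' @param x object with an image dimension.
#' @return integer count.
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' Image identifiers
#' @param x object carrying image labels.
#' @return character vector.
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' Layer identifier(s)
#' @param x object carrying layer labels.
#' @return character vector (length 1 for single-layer objects).
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))

#' Pixel array of a stimulus set
#' @param x a [StimulusSet-class].
#' @return images x height x width x 3 array.
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' Declared pixel range
#' @param x a [StimulusSet-class].
#' @return numeric length-2 (min, max).
#' @export
setGeneric("pixelRange", function(x) standardGeneric("pixelRange"))

#' Beta coefficient matrix (images x in-mask voxels)
#' @param x a [BetaMaps-class].
#' @return numeric matrix.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Brain mask
#' @param x an object with a voxel grid.
#' @return logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Statistic values of a map
#' @param x a [StatMap-class].
#' @return numeric vector aligned with `which(maskArray(x))`.
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))

#' Trial table of a sequence
#' @param x a [TrialSequence-class].
#' @return data.frame of trials.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' Total run duration in seconds
#' @param x a [TrialSequence-class].
#' @return numeric scalar.
#' @export
setGeneric("runLength", function(x) standardGeneric("runLength"))

## ---- methods -------------------------------------------------------------

#' @describeIn nImages images in a stimulus set
#' @export
setMethod("nImages", "StimulusSet", function(x) dim(x@pixels)[1])
#' @describeIn nImages images covered by an RSM
#' @export
setMethod("nImages", "LayerRSM", function(x) nrow(x@values))
#' @describeIn nImages images in a beta map
#' @export
setMethod("nImages", "BetaMaps", function(x) nrow(x@values))

#' @describeIn imageIds labels of a stimulus set
#' @export
setMethod("imageIds", "StimulusSet", function(x) x@imageIds)
#' @describeIn imageIds labels of a beta map
#' @export
setMethod("imageIds", "BetaMaps", function(x) x@imageIds)

#' @describeIn layerIds layer of one RSM
#' @export
setMethod("layerIds", "LayerRSM", function(x) x@layerId)
#' @describeIn layerIds layers of a second-order matrix
#' @export
setMethod("layerIds", "SecondOrderMatrix", function(x) x@layerIds)
#' @describeIn layerIds layers of a model adapter
#' @export
setMethod("layerIds", "ModelAdapter", function(x) x@layerIds)
#' @describeIn layerIds layers of an overlap matrix
#' @export
setMethod("layerIds", "OverlapMatrix", function(x) x@layerIds)

#' @describeIn pixelArray pixel data
#' @export
setMethod("pixelArray", "StimulusSet", function(x) x@pixels)
#' @describeIn pixelRange declared range
#' @export
setMethod("pixelRange", "StimulusSet", function(x) x@range)

#' @describeIn betaValues coefficient matrix
#' @export
setMethod("betaValues", "BetaMaps", function(x) x@values)
#' @describeIn maskArray mask of a beta map
#' @export
setMethod("maskArray", "BetaMaps", function(x) x@mask)
#' @describeIn maskArray mask of a statistic map
#' @export
setMethod("maskArray", "StatMap", function(x) x@mask)
#' @describeIn statValues values of a statistic map
#' @export
setMethod("statValues", "StatMap", function(x) x@values)

#' @describeIn trials trial table
#' @export
setMethod("trials", "TrialSequence", function(x) x@trials)
#' @describeIn runLength run duration
#' @export
setMethod("runLength", "TrialSequence", function(x) x@runLength)

#' Coerce package matrices to base matrices
#'
#' `as.matrix` on [LayerRSM-class], [SecondOrderMatrix-class],
#' [OverlapMatrix-class] and [DesignMatrix-class] returns the underlying
#' numeric matrix with dimnames set from the stored identifiers.
#'
#' @param x the object to coerce.
#' @param ... ignored.
#' @return numeric matrix.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "LayerRSM", function(x, ...) x@values)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "SecondOrderMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@layerIds, x@layerIds)
  m
})
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "OverlapMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@layerIds, x@layerIds)
  m
})
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "DesignMatrix", function(x, ...) {
  m <- x@values
  colnames(m) <- x@regressorIds
  m
})

setMethod("show", "StimulusSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("StimulusSet: %d images, %dx%dx%d, range [%g, %g]\n",
              d[1], d[2], d[3], d[4], object@range[1], object@range[2]))
})
setMethod("show", "LayerRSM", function(object) {
  cat(sprintf("LayerRSM '%s': %d x %d images\n", object@layerId,
              nrow(object@values), ncol(object@values)))
})
setMethod("show", "SecondOrderMatrix", function(object) {
  cat(sprintf("SecondOrderMatrix: %d layers, off-diagonal sum of squares %.4g\n",
              nrow(object@values), orthogonalityCost(object)))
})
setMethod("show", "ModelAdapter", function(object) {
  cat(sprintf("ModelAdapter: %d layers (%s), input %s\n",
              length(object@layerIds),
              paste(utils::head(object@layerIds, 3), collapse = ", "),
              paste(object@inputDim, collapse = "x")))
})
setMethod("show", "TrialSequence", function(object) {
  cat(sprintf("TrialSequence: %d trials (%d targets), %.1f s\n",
              nrow(object@trials), sum(object@trials$is_target),
              object@runLength))
})
setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors, TR %.2f s\n",
              nrow(object@values), ncol(object@values), object@trS))
})
setMethod("show", "BetaMaps", function(object) {
  cat(sprintf("BetaMaps '%s': %d images x %d in-mask voxels (grid %s)\n",
              object@runId, nrow(object@values), ncol(object@values),
              paste(dim(object@mask), collapse = "x")))
})
setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap '%s': %d in-mask voxels (%d undefined)\n",
              object@statisticName, length(object@values),
              sum(is.na(object@values))))
})
setMethod("show", "OverlapMatrix", function(object) {
  cat(sprintf("OverlapMatrix: %d layers, %d undefined rows\n",
              nrow(object@values), sum(apply(object@values, 1,
                                             function(r) all(is.na(r))))))
})
setMethod("show", "SynthesisTrace", function(object) {
  n <- length(object@costPerIteration)
  cat(sprintf("SynthesisTrace: %d iterations, cost %.4g -> %.4g\n", n,
              orthogonalityCost(object@initialSom),
              orthogonalityCost(object@finalSom)))
})
setMethod("show", "GroundTruthSpec", function(object) {
  cat(sprintf("GroundTruthSpec: grid %s, %d regions, %d participants x %d runs\n",
              paste(object@gridShape, collapse = "x"), length(object@regions),
              object@nParticipants, object@nRuns))
})
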