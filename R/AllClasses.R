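#' @import methods
NULL

.almostSymmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

#' StimulusSet: an ordered collection of fixed-size RGB images
#'
#' Container for a set of images being optimized or presented, stored as an
#' `n_images x height x width x 3` numeric array with a declared value range.
#' All synthesis operations keep every pixel inside `pixelRange` after each
#' optimizer step.
#'
#' @slot pixels four-dimensional numeric array, images x height x width x 3.
#' @slot imageIds character vector of image labels, one per image.
#' @slot range numeric length-2 vector, the declared (min, max) pixel range.
#' @export
setClass("StimulusSet",
  representation(pixels = "array", imageIds = "character", range = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 4L || d[4] != 3L)
      return("pixels must be an n_images x height x width x 3 array")
    if (d[1] < 2L)
      return("a stimulus set needs at least 2 images")
    if (length(object@imageIds) != d[1])
      return("imageIds length must equal the number of images")
    if (anyDuplicated(object@imageIds))
      return("imageIds must be unique")
    if (length(object@range) != 2L || object@range[1] >= object@range[2])
      return("range must be (min, max) with min < max")
    rng <- range(object@pixels)
    tol <- 1e-9 * diff(object@range)
    if (rng[1] < object@range[1] - tol || rng[2] > object@range[2] + tol)
      return("pixel values fall outside the declared range")
    TRUE
  })

#' Construct a StimulusSet
#'
#' @param pixels images x height x width x 3 numeric array.
#' @param imageIds optional image labels; defaults to `img01, img02, ...`.
#' @param range declared pixel value range, default `c(0, 1)`.
#' @return A [StimulusSet-class] object.
#' @export
stimulusSet <- function(pixels, imageIds = NULL, range = c(0, 1)) {
  if (is.null(imageIds))
    imageIds <- sprintf("img%02d", seq_len(dim(pixels)[1]))
  new("StimulusSet", pixels = pixels, imageIds = imageIds, range = range)
}

#' LayerRSM: representational similarity matrix for one layer
#'
#' An `n x n` matrix of Pearson correlations between the activation patterns
#' evoked by each pair of images in one model layer (or one searchlight).
#'
#' @slot values symmetric unit-diagonal correlation matrix.
#' @slot layerId identifier of the source layer.
#' @export
setClass("LayerRSM",
  representation(values = "matrix", layerId = "character"),
  validity = function(object) {
    v <- object@values
    if (!.almostSymmetric(v)) return("RSM must be a symmetric square matrix")
    if (max(abs(diag(v) - 1)) > 1e-8) return("RSM diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-8) return("RSM entries must lie in [-1, 1]")
    TRUE
  })

#' Construct a LayerRSM
#' @param values symmetric correlation matrix with unit diagonal.
#' @param layerId layer identifier.
#' @return A [LayerRSM-class] object.
#' @export
layerRSM <- function(values, layerId = "layer") {
  values <- (values + t(values)) / 2
  diag(values) <- 1
  new("LayerRSM", values = values, layerId = as.character(layerId))
}

#' SecondOrderMatrix: layer-by-layer similarity of representational geometries
#'
#' An `L x L` matrix of Pearson correlations between the vectorized upper
#' triangles of `L` layer RSMs. Its off-diagonal sum of squares is the
#' synthesis cost minimized by [orthogonalizePhase()].
#'
#' @slot values symmetric unit-diagonal correlation matrix over layers.
#' @slot layerIds layer identifiers.
#' @export
setClass("SecondOrderMatrix",
  representation(values = "matrix", layerIds = "character"),
  validity = function(object) {
    v <- object@values
    if (!.almostSymmetric(v)) return("second-order matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-8) return("entries must lie in [-1, 1]")
    if (length(object@layerIds) != nrow(v)) return("layerIds length mismatch")
    TRUE
  })

#' ModelAdapter: contract exposing a convolutional network
#'
#' Any network usable by this package is wrapped in an adapter exposing (i) an
#' ordered set of named layers, (ii) an activation function returning one
#' flattened unit-activation pattern per (layer, image), and (iii) a
#' vector-Jacobian product: given the gradient of a scalar loss with respect to
#' each layer's activations, return its gradient with respect to the input
#' pixels. Adapters for arbitrary backends (including external deep-learning
#' runtimes) can be registered via [registerAdapter()].
#'
#' @slot layerIds ordered unique layer identifiers.
#' @slot activationFn `function(pixels)` returning a named list (one entry per
#'   layer) of `n_images x n_units` matrices.
#' @slot gradientFn `function(pixels, gradActs)` where `gradActs` is a named
#'   list of `n_images x n_units` gradient matrices (entries may be omitted or
#'   zero); returns an array shaped like `pixels`.
#' @slot inputDim expected input dimensions `c(height, width, 3)`.
#' @slot channels named list: for each layer, a list of integer vectors giving
#'   the flattened unit indices of each feature channel (may be empty for
#'   layers without channel structure).
#' @export
setClass("ModelAdapter",
  representation(layerIds = "character", activationFn = "function",
                 gradientFn = "function", inputDim = "integer",
                 channels = "list"),
  validity = function(object) {
    if (length(object@layerIds) < 1L) return("adapter needs at least 1 layer")
    if (anyDuplicated(object@layerIds)) return("layerIds must be unique")
    if (length(object@inputDim) != 3L) return("inputDim must be (h, w, c)")
    TRUE
  })

#' Construct a ModelAdapter
#' @param layerIds ordered unique layer identifiers.
#' @param activationFn see [ModelAdapter-class].
#' @param gradientFn see [ModelAdapter-class].
#' @param inputDim input dimensions `c(height, width, channels)`.
#' @param channels per-layer channel unit-index lists (optional).
#' @return A [ModelAdapter-class] object.
#' @export
modelAdapter <- function(layerIds, activationFn, gradientFn,
                         inputDim, channels = list()) {
  new("ModelAdapter", layerIds = as.character(layerIds),
      activationFn = activationFn, gradientFn = gradientFn,
      inputDim = as.integer(inputDim), channels = channels)
}

#' TrialSequence: one run's constrained pseudo-random presentation order
#'
#' Each trial records the image shown, its onset and duration in seconds, and
#' whether it was an attention-target trial. Invariants: no two consecutive
#' trials share an image, each image appears exactly `n_reps` times, onsets
#' strictly increase.
#'
#' @slot trials data.frame with columns image_id, onset_s, duration_s,
#'   is_target.
#' @slot runLength total run duration in seconds.
#' @export
setClass("TrialSequence",
  representation(trials = "data.frame", runLength = "numeric"),
  validity = function(object) {
    tr <- object@trials
    need <- c("image_id", "onset_s", "duration_s", "is_target")
    if (!all(need %in% names(tr))) return("trials missing required columns")
    if (nrow(tr) >= 2L) {
      if (any(tr$image_id[-1] == tr$image_id[-nrow(tr)]))
        return("back-to-back repetition of an image")
      if (any(diff(tr$onset_s) <= 0)) return("onsets must strictly increase")
    }
    if (nrow(tr) > 0 && object@runLength < max(tr$onset_s + tr$duration_s))
      return("runLength shorter than the final trial offset")
    TRUE
  })

#' DesignMatrix: HRF-convolved regressors sampled at volume times
#'
#' @slot values `n_volumes x n_regressors` numeric matrix.
#' @slot trS repetition time in seconds.
#' @slot regressorIds image identifiers, one per column.
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", trS = "numeric", regressorIds = "character"),
  validity = function(object) {
    if (ncol(object@values) != length(object@regressorIds))
      return("one regressor id per column required")
    if (!all(is.finite(object@values))) return("design entries must be finite")
    if (object@trS <= 0) return("trS must be positive")
    TRUE
  })

#' BetaMaps: per-image voxelwise GLM coefficients over a masked grid
#'
#' The substrate of every searchlight analysis: one beta coefficient per
#' (image, in-mask voxel) for one run (or run average). Voxel columns are
#' ordered by the linear index of the in-mask voxels in the 3D grid
#' (column-major, as returned by `which(mask)`).
#'
#' @slot values `n_images x n_voxels` numeric matrix (in-mask voxels only).
#' @slot imageIds image identifiers, one per row.
#' @slot mask logical 3D array marking in-mask voxels.
#' @slot runId run identifier.
#' @export
setClass("BetaMaps",
  representation(values = "matrix", imageIds = "character",
                 mask = "array", runId = "character"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (ncol(object@values) != sum(object@mask))
      return("one beta column per in-mask voxel required")
    if (nrow(object@values) != length(object@imageIds))
      return("one imageId per row required")
    if (!all(is.finite(object@values))) return("betas must be finite")
    TRUE
  })

#' Construct a BetaMaps object
#' @param values `n_images x n_voxels` matrix of betas for in-mask voxels.
#' @param mask logical 3D array; if missing, a flat `n_voxels x 1 x 1` grid.
#' @param imageIds image labels; defaults to `img01, ...`.
#' @param runId run identifier.
#' @return A [BetaMaps-class] object.
#' @export
betaMaps <- function(values, mask = NULL, imageIds = NULL, runId = "run1") {
  if (is.null(mask))
    mask <- array(TRUE, dim = c(ncol(values), 1L, 1L))
  if (is.null(imageIds))
    imageIds <- sprintf("img%02d", seq_len(nrow(values)))
  new("BetaMaps", values = values, imageIds = imageIds,
      mask = mask, runId = runId)
}

#' StatMap: one searchlight statistic per in-mask voxel
#'
#' Values are aligned with `which(mask)`. Centers where the statistic is
#' undefined (e.g. searchlight smaller than 2 voxels, degenerate null) are
#' stored as `NA`, never silently zero-filled.
#'
#' @slot values numeric vector, one entry per in-mask voxel (NA = undefined).
#' @slot mask logical 3D array.
#' @slot statisticName label of the statistic.
#' @export
setClass("StatMap",
  representation(values = "numeric", mask = "array", statisticName = "character"),
  validity = function(object) {
    if (length(object@values) != sum(object@mask))
      return("one value per in-mask voxel required")
    TRUE
  })

#' OverlapMatrix: asymmetric layer-by-layer significant-voxel sharing ratios
#'
#' Entry (m, n) is |M intersect N| / |M| for the significant-voxel sets of
#' layers m (base) and n. Rows for layers with no significant voxels are
#' undefined (NA) and excluded from summary means.
#'
#' @slot values `L x L` matrix in `[0, 1]` with NA rows for empty base maps.
#' @slot layerIds layer identifiers.
#' @export
setClass("OverlapMatrix",
  representation(values = "matrix", layerIds = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("overlap matrix must be square")
    if (length(object@layerIds) != nrow(v)) return("layerIds length mismatch")
    ok <- v[!is.na(v)]
    if (length(ok) && (min(ok) < -1e-12 || max(ok) > 1 + 1e-12))
      return("defined overlap ratios must lie in [0, 1]")
    TRUE
  })

#' SynthesisTrace: record of one orthogonalization run
#'
#' @slot costPerIteration cost after each pixel update (length = iterations).
#' @slot initialSom second-order matrix before the first update.
#' @slot finalSom second-order matrix after the last update.
#' @slot finalImages the optimized stimulus set.
#' @export
setClass("SynthesisTrace",
  representation(costPerIteration = "numeric",
                 initialSom = "SecondOrderMatrix",
                 finalSom = "SecondOrderMatrix",
                 finalImages = "StimulusSet"))

#' GroundTruthSpec: layout of a synthetic brain with known layer geometry
#'
#' Describes a 3D voxel grid in which disjoint regions carry the
#' representational geometry of designated model layers at a given
#' signal-to-noise level, shared across runs within participant and jittered
#' across participants.
#'
#' @slot gridShape 3D grid dimensions.
#' @slot regions list of `list(voxels = <linear indices>, layerId = <chr>,
#'   signalScale = <num>)`; regions must be disjoint and inside the grid.
#' @slot noiseSd per-run i.i.d. noise standard deviation.
#' @slot nParticipants,nRuns counts.
#' @slot participantSd between-participant pattern jitter SD.
#' @slot seed integer master seed.
#' @export
setClass("GroundTruthSpec",
  representation(gridShape = "integer", regions = "list", noiseSd = "numeric",
                 nParticipants = "integer", nRuns = "integer",
                 participantSd = "numeric", seed = "integer"),
  validity = function(object) {
    ng <- prod(object@gridShape)
    vox <- unlist(lapply(object@regions, `[[`, "voxels"))
    if (length(vox)) {
      if (any(vox < 1 | vox > ng)) return("region voxels outside the grid")
      if (anyDuplicated(vox)) return("regions must be disjoint")
    }
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@nParticipants < 1 || object@nRuns < 1)
      return("need at least one participant and one run")
    TRUE
  })

#' Construct a GroundTruthSpec
#' @param gridShape 3D grid dimensions, default `c(24, 24, 24)`.
#' @param regions list of `list(voxels, layerId, signalScale)` records.
#' @param noiseSd run-level noise SD (default 0.5).
#' @param nParticipants,nRuns counts (defaults 8 participants, 8 runs).
#' @param participantSd between-participant pattern jitter SD (default 0.2).
#' @param seed master seed.
#' @return A [GroundTruthSpec-class] object.
#' @export
groundTruthSpec <- function(gridShape = c(24L, 24L, 24L), regions = list(),
                            noiseSd = 0.5, nParticipants = 8L, nRuns = 8L,
                            participantSd = 0.2, seed = 1L) {
  new("GroundTruthSpec", gridShape = as.integer(gridShape), regions = regions,
      noiseSd = noiseSd, nParticipants = as.integer(nParticipants),
      nRuns = as.integer(nRuns), participantSd = participantSd,
      seed = as.integer(seed))
}
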