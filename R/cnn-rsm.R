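#' Extract layer-wise activation patterns for a stimulus set
#'
#' Runs every image through the adapter's network and returns one flattened
#' unit-activation pattern per (layer, image). Deterministic for fixed inputs.
#'
#' @param adapter a [ModelAdapter-class].
#' @param stimuli a [StimulusSet-class] sized to `adapter`'s input resolution.
#' @param layers optional subset of layer identifiers (default: all).
#' @return Named list, one `n_images x n_units` matrix per layer.
#' @export
extractActivations <- function(adapter, stimuli, layers = NULL) {
  stopifnot(is(adapter, "ModelAdapter"), is(stimuli, "StimulusSet"))
  layers <- layers %||% adapter@layerIds
  unknown <- setdiff(layers, adapter@layerIds)
  if (length(unknown))
    stop("unknown layer id(s): ", paste(unknown, collapse = ", "))
  px <- pixelArray(stimuli)
  if (!all(dim(px)[2:4] == adapter@inputDim))
    stop(sprintf("input shape mismatch: stimuli are %s, adapter expects %s",
                 paste(dim(px)[2:4], collapse = "x"),
                 paste(adapter@inputDim, collapse = "x")))
  acts <- adapter@activationFn(px)
  if (!all(layers %in% names(acts)))
    stop("adapter activationFn did not return all requested layers")
  acts <- acts[layers]
  n <- dim(px)[1]
  for (l in layers) {
    if (nrow(acts[[l]]) != n)
      stop("activation pattern count does not match image count in layer ", l)
  }
  acts
}

#' Pearson-correlation RSM from activation patterns
#'
#' Correlates every pair of rows (one activation pattern per image) to build
#' the representational similarity matrix.
#'
#' @param patterns `n_images x n_units` numeric matrix, `n_units >= 2`.
#' @param layerId label stored on the result.
#' @return A [LayerRSM-class].
#' @export
computeRSM <- function(patterns, layerId = "layer") {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2L)
    stop("need at least 2 units per pattern to correlate")
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: zero-variance activation pattern (row ",
         paste(which(sds == 0), collapse = ", "), ")")
  r <- stats::cor(t(patterns))
  layerRSM(r, layerId)
}

#' Strict upper triangle of an RSM, row-major
#'
#' Vectorizes an RSM in the package's fixed order: diagonal excluded, rows
#' scanned left to right, i.e. (1,2), (1,3), ..., (1,n), (2,3), ... This
#' ordering is a format guarantee consumed by every downstream regression.
#'
#' @param rsm a [LayerRSM-class] or symmetric matrix, `n >= 3`.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
upperTriangle <- function(rsm) {
  m <- if (is(rsm, "LayerRSM")) rsm@values else as.matrix(rsm)
  n <- nrow(m)
  if (n < 3L)
    stop("RSM too small: need n >= 3 images for a usable triangle")
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric unit-diagonal matrix from a triangle vector
#'
#' Inverse of [upperTriangle()] (row-major strict upper triangle).
#'
#' @param v triangle vector of length `n(n-1)/2`.
#' @param n matrix size.
#' @param diagValue value for the diagonal (default 1).
#' @return `n x n` symmetric matrix.
#' @export
fromUpperTriangle <- function(v, n, diagValue = 1) {
  if (length(v) != n * (n - 1) / 2)
    stop("triangle length does not match n(n-1)/2")
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diagValue
  m
}

#' Second-order layer-by-layer similarity matrix
#'
#' Entry (i, j) is the Pearson correlation between the upper-triangle vectors
#' of layer i's and layer j's RSMs: how alike the two representational
#' geometries are.
#'
#' @param rsms list of [LayerRSM-class] objects over the same images, `L >= 2`.
#' @return A [SecondOrderMatrix-class].
#' @export
secondOrderMatrix <- function(rsms) {
  if (length(rsms) < 2L) stop("need at least 2 layer RSMs")
  ns <- vapply(rsms, nImages, integer(1))
  if (length(unique(ns)) != 1L) stop("all RSMs must cover the same images")
  V <- vapply(rsms, upperTriangle, numeric(ns[1] * (ns[1] - 1) / 2))
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: constant RSM upper triangle in layer ",
         paste(vapply(rsms[sds == 0], layerIds, character(1)), collapse = ", "))
  S <- stats::cor(V)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  ids <- vapply(rsms, layerIds, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  new("SecondOrderMatrix", values = S, layerIds = ids)
}

#' Orthogonalization cost of a second-order matrix
#'
#' Sum of squared off-diagonal entries (both triangles). Zero if and only if
#' every pair of layer RSMs is perfectly decorrelated; this is the synthesis
#' objective minimized in pixel space.
#'
#' @param som a [SecondOrderMatrix-class] or square numeric matrix.
#' @return Nonnegative scalar.
#' @export
orthogonalityCost <- function(som) {
  m <- if (is(som, "SecondOrderMatrix")) som@values else as.matrix(som)
  sum(m^2) - sum(diag(m)^2)
}

#' Mean off-diagonal second-order correlation
#'
#' Summary used to compare synthesized sets against natural baselines: the
#' mean of the off-diagonal second-order correlations, over all layer pairs or
#' only adjacent layers (entries one off the diagonal).
#'
#' @param som a [SecondOrderMatrix-class] or square matrix.
#' @param mode `"all_offdiag"` or `"adjacent"`.
#' @return Scalar mean correlation.
#' @export
meanOffDiagonal <- function(som, mode = c("all_offdiag", "adjacent")) {
  mode <- match.arg(mode)
  m <- if (is(som, "SecondOrderMatrix")) som@values else as.matrix(som)
  L <- nrow(m)
  sel <- if (mode == "all_offdiag") {
    row(m) != col(m)
  } else {
    abs(row(m) - col(m)) == 1
  }
  mean(m[sel])
}
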