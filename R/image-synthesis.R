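#' Synthesis configuration
#'
#' Bundles the tunable parameters of the two-phase pixel optimization. The
#' default profile is the full-scale one (16 images, 28,800 diversification
#' iterations, 1,800 orthogonalization iterations); `profile = "test"` selects
#' a desk-scale profile (8 images, 200 + 200 iterations) sized for the small
#' random CNN.
#'
#' @param nImages number of images to synthesize.
#' @param phase1Iters channel-diversification (activation-maximization) steps.
#' @param phase2Iters RSM-orthogonalization steps.
#' @param stepSize gradient step size in pixel units (gradients are
#'   max-normalized per step, so this is the largest per-pixel change).
#' @param rgbBreadthWeight weight of the RGB-breadth penalty encouraging a
#'   broad distribution of values in each color channel.
#' @param seed integer seed controlling noise init and channel sampling.
#' @param targetChannels optional list of `list(layer, channel)` per image;
#'   default: seeded sampling of distinct channels from `channelLayer`.
#' @param channelLayer layer whose feature channels are maximized in phase 1;
#'   default: the adapter's last layer.
#' @param range declared pixel range.
#' @param profile `"full"` (default, the 28,800 + 1,800 iteration regime) or `"test"`.
#' @return A list of class `SynthesisConfig`.
#' @export
synthesisConfig <- function(nImages = 16L, phase1Iters = 28800L,
                            phase2Iters = 1800L, stepSize = 0.02,
                            rgbBreadthWeight = 0.1, seed = 1L,
                            targetChannels = NULL, channelLayer = NULL,
                            range = c(0, 1), profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (profile == "test" && missing(nImages)) nImages <- 8L
  if (profile == "test" && missing(phase1Iters)) phase1Iters <- 200L
  if (profile == "test" && missing(phase2Iters)) phase2Iters <- 200L
  stopifnot(nImages >= 2, phase1Iters >= 0, phase2Iters >= 0, stepSize > 0,
            rgbBreadthWeight >= 0)
  if (!is.null(targetChannels) && length(targetChannels) != nImages)
    stop("need one target channel per image")
  structure(list(nImages = as.integer(nImages),
                 phase1Iters = as.integer(phase1Iters),
                 phase2Iters = as.integer(phase2Iters),
                 stepSize = stepSize, rgbBreadthWeight = rgbBreadthWeight,
                 seed = as.integer(seed), targetChannels = targetChannels,
                 channelLayer = channelLayer, range = range),
            class = "SynthesisConfig")
}

#' Initialize a stimulus set as seeded uniform noise
#'
#' @param config a [synthesisConfig()].
#' @param adapter a [ModelAdapter-class] (supplies the input resolution).
#' @return A [StimulusSet-class] of i.i.d. uniform pixels in the declared
#'   range, reproducible from `config$seed`.
#' @export
initNoise <- function(config, adapter) {
  d <- adapter@inputDim
  px <- withSeed(config$seed,
    array(stats::runif(config$nImages * prod(d), config$range[1],
                       config$range[2]),
          dim = c(config$nImages, d)))
  stimulusSet(px, range = config$range)
}

.clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Resolve the per-image target channels: seeded sampling of distinct feature
# channels from the configured layer (default: the adapter's last layer).
.resolveTargets <- function(config, adapter) {
  if (!is.null(config$targetChannels)) return(config$targetChannels)
  layer <- config$channelLayer %||% utils::tail(adapter@layerIds, 1)
  chans <- adapter@channels[[layer]]
  if (is.null(chans) || !length(chans))
    stop("adapter exposes no channel structure for layer ", layer)
  nc <- length(chans)
  picks <- withSeed(config$seed + 1L,
                    sample(nc, config$nImages, replace = config$nImages > nc))
  lapply(picks, function(ch) list(layer = layer, channel = ch))
}

# Gradient of the RGB-breadth penalty (-mean over channels of the pixel SD
# within that channel) with respect to one image's pixels.
.breadthGrad <- function(img) {
  g <- array(0, dim = dim(img))
  for (ch in 1:3) {
    x <- img[, , ch]
    s <- stats::sd(x)
    if (s > 0) g[, , ch] <- -(x - mean(x)) / ((length(x) - 1) * s) / 3
  }
  g
}

#' Phase 1: channel diversification
#'
#' Gradient descent on a per-image loss equal to minus the mean activation of
#' that image's target feature channel plus the weighted RGB-breadth penalty.
#' Drives each image toward expressing one learned feature while keeping a
#' broad distribution of RGB values; pixels are clamped to the declared range
#' after every step.
#'
#' @param stimuli starting [StimulusSet-class].
#' @param adapter a [ModelAdapter-class].
#' @param config a [synthesisConfig()].
#' @return The optimized [StimulusSet-class].
#' @export
diversifyPhase <- function(stimuli, adapter, config) {
  if (config$phase1Iters == 0L) return(stimuli)
  targets <- .resolveTargets(config, adapter)
  px <- pixelArray(stimuli)
  n <- dim(px)[1]
  layers <- unique(vapply(targets, `[[`, character(1), "layer"))
  for (it in seq_len(config$phase1Iters)) {
    gradActs <- list()
    acts <- adapter@activationFn(px)
    loss <- 0
    for (i in seq_len(n)) {
      tg <- targets[[i]]
      idx <- adapter@channels[[tg$layer]][[tg$channel]]
      if (is.null(gradActs[[tg$layer]]))
        gradActs[[tg$layer]] <- matrix(0, n, ncol(acts[[tg$layer]]))
      gradActs[[tg$layer]][i, idx] <- -1 / length(idx)
      loss <- loss - mean(acts[[tg$layer]][i, idx])
    }
    if (!is.finite(loss))
      stop("non-finite channel loss at iteration ", it,
           "; reduce stepSize or check the adapter")
    g <- adapter@gradientFn(px, gradActs)
    for (i in seq_len(n)) {
      gi <- g[i, , , ] + config$rgbBreadthWeight * .breadthGrad(px[i, , , ])
      mx <- max(abs(gi))
      if (mx > 0) gi <- gi / mx
      px[i, , , ] <- .clamp(px[i, , , ] - config$stepSize * gi, config$range)
    }
  }
  stimulusSet(px, imageIds = imageIds(stimuli), range = config$range)
}

# Cost and activation-space gradient of the orthogonalization objective.
# Chain: activations -> per-layer RSM (Pearson over unit patterns) -> upper
# triangles -> second-order correlations -> off-diagonal sum of squares.
.costAndGradActs <- function(acts, layerIds) {
  L <- length(acts)
  n <- nrow(acts[[1]])
  rsms <- lapply(seq_len(L), function(l) computeRSM(acts[[l]], layerIds[l]))
  som <- secondOrderMatrix(rsms)
  S <- som@values
  V <- vapply(rsms, upperTriangle, numeric(n * (n - 1) / 2))
  gradActs <- vector("list", L)
  names(gradActs) <- layerIds
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (k in seq_len(L)) {
    gv <- numeric(nrow(V))
    for (l in seq_len(L)) {
      if (l == k) next
      cg <- corrGradX(V[, k], V[, l])
      gv <- gv + 4 * S[k, l] * cg$grad
    }
    # scatter triangle gradient onto RSM entries (row-major upper triangle),
    # then through each Pearson entry onto the two activation rows involved
    gR <- fromUpperTriangle(gv, n, diagValue = 0) / 2  # symmetric split
    A <- acts[[k]]
    gA <- matrix(0, n, ncol(A))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      wgt <- gR[i, j] * 2   # both (i,j) and (j,i) halves flow through r_ij
      if (wgt == 0) next
      gA[i, ] <- gA[i, ] + wgt * corrGradX(A[i, ], A[j, ])$grad
      gA[j, ] <- gA[j, ] + wgt * corrGradX(A[j, ], A[i, ])$grad
    }
    gradActs[[k]] <- gA
  }
  list(cost = orthogonalityCost(som), som = som, gradActs = gradActs)
}

#' Phase 2: joint RSM orthogonalization
#'
#' Simultaneously updates the pixels of all images by gradient descent on the
#' orthogonalization cost (off-diagonal sum of squares of the second-order
#' layer-by-layer correlation matrix). Gradients are backpropagated through
#' the Pearson correlations analytically and through the network via the
#' adapter's vector-Jacobian contract; steps are max-normalized and pixels
#' clamped to the declared range. If a degenerate (zero-variance) RSM is hit
#' mid-run the affected state is restarted from fresh seeded noise and the
#' restart logged.
#'
#' @param stimuli starting [StimulusSet-class] (typically the phase-1 output).
#' @param adapter a [ModelAdapter-class] exposing at least 2 layers.
#' @param config a [synthesisConfig()].
#' @return A [SynthesisTrace-class] with the per-iteration cost, the initial
#'   and final second-order matrices, and the final images.
#' @export
orthogonalizePhase <- function(stimuli, adapter, config) {
  if (length(adapter@layerIds) < 2L)
    stop("orthogonalization needs an adapter with >= 2 layers")
  px <- pixelArray(stimuli)
  evalState <- function(px) {
    acts <- adapter@activationFn(px)
    .costAndGradActs(acts, adapter@layerIds)
  }
  restartCount <- 0L
  safeEval <- function(px) {
    repeat {
      res <- tryCatch(evalState(px), error = function(e) e)
      if (!inherits(res, "error")) return(list(px = px, state = res))
      if (!grepl("degenerate", conditionMessage(res)))
        stop(res)
      restartCount <<- restartCount + 1L
      if (restartCount > 10L) stop("too many degenerate restarts: ",
                                   conditionMessage(res))
      message("degenerate RSM encountered; restarting from fresh noise (",
              restartCount, ")")
      px <- pixelArray(initNoise(
        synthesisConfig(nImages = config$nImages, seed = config$seed +
                          1000L + restartCount, range = config$range),
        adapter))
    }
  }
  sv <- safeEval(px)
  px <- sv$px
  state <- sv$state
  initialSom <- state$som
  costs <- numeric(config$phase2Iters)
  for (it in seq_len(config$phase2Iters)) {
    g <- adapter@gradientFn(px, state$gradActs)
    mx <- max(abs(g))
    if (mx > 0) g <- g / mx
    px <- .clamp(px - config$stepSize * g, config$range)
    sv <- safeEval(px)
    px <- sv$px
    state <- sv$state
    costs[it] <- state$cost
  }
  new("SynthesisTrace", costPerIteration = costs, initialSom = initialSom,
      finalSom = state$som,
      finalImages = stimulusSet(px, imageIds = imageIds(stimuli),
                                range = config$range))
}

#' Random-subset baseline of second-order correlations
#'
#' Draws `nSets` random subsets of `setSize` images from an image library,
#' pushes each subset through the adapter, and returns the mean off-diagonal
#' (and adjacent-layer) second-order correlation per subset. This is the
#' comparison distribution against which a synthesized set's orthogonality is
#' judged.
#'
#' @param adapter a [ModelAdapter-class].
#' @param library a [StimulusSet-class] pool with at least `setSize` images.
#' @param setSize images per subset.
#' @param nSets number of subsets.
#' @param seed sampling seed.
#' @return data.frame with columns `set`, `mean_offdiag`, `mean_adjacent`.
#' @export
naturalBaseline <- function(adapter, library, setSize, nSets, seed = 1L) {
  nlib <- nImages(library)
  if (nlib < setSize) stop("image library smaller than setSize")
  px <- pixelArray(library)
  draws <- withSeed(seed, replicate(nSets, sample(nlib, setSize),
                                    simplify = FALSE))
  res <- vapply(draws, function(ix) {
    sub <- array(px[ix, , , , drop = FALSE], dim = c(setSize, dim(px)[2:4]))
    acts <- adapter@activationFn(sub)
    rsms <- lapply(names(acts), function(l) computeRSM(acts[[l]], l))
    som <- secondOrderMatrix(rsms)
    c(meanOffDiagonal(som, "all_offdiag"), meanOffDiagonal(som, "adjacent"))
  }, numeric(2))
  data.frame(set = seq_len(nSets), mean_offdiag = res[1, ],
             mean_adjacent = res[2, ])
}
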