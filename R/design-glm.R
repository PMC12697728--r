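#' Constrained pseudo-random trial sequence
#'
#' Builds one run's presentation order: each image appears exactly `nReps`
#' times with no back-to-back repetition, inter-stimulus intervals are drawn
#' with equal probability from the jitter set, and a fixed proportion of
#' trials is flagged as attention targets. Orders are sampled sequentially:
#' each trial is drawn from the images with remaining presentations
#' (excluding the previous image), weighted by remaining count; dead ends
#' restart the sequence, with a bounded retry budget so infeasible
#' constraint sets fail constructively.
#'
#' @param nImages number of distinct images (default 16).
#' @param nReps presentations per image (default 5).
#' @param stimDurS stimulus duration in seconds (default 1.5).
#' @param isiChoicesS jitter set in seconds (default `c(1.5, 3, 4.5)`).
#' @param targetRate proportion of trials flagged as targets (default 0.1;
#'   the flagged count is `ceiling(targetRate * nTrials)`).
#' @param seed integer seed.
#' @param maxRetries retry budget for the no-repeat constraint.
#' @return A [TrialSequence-class].
#' @export
generateSequence <- function(nImages = 16L, nReps = 5L, stimDurS = 1.5,
                             isiChoicesS = c(1.5, 3, 4.5), targetRate = 0.1,
                             seed = 1L, maxRetries = 10000L) {
  nImages <- as.integer(nImages); nReps <- as.integer(nReps)
  nTrials <- nImages * nReps
  if (nTrials < 2L) stop("need at least 2 trials")
  ids <- sprintf("img%02d", seq_len(nImages))
  withSeed(seed, {
    drawOrder <- function() {
      counts <- rep(nReps, nImages)
      out <- character(nTrials)
      prev <- 0L
      for (t in seq_len(nTrials)) {
        avail <- which(counts > 0L)
        avail <- avail[avail != prev]
        if (!length(avail)) return(NULL)
        pick <- if (length(avail) == 1L) avail else
          sample(avail, 1L, prob = counts[avail])
        out[t] <- ids[pick]
        counts[pick] <- counts[pick] - 1L
        prev <- pick
      }
      out
    }
    order <- NULL
    for (try in seq_len(maxRetries)) {
      cand <- drawOrder()
      if (!is.null(cand)) { order <- cand; break }
    }
    if (is.null(order))
      stop("could not satisfy the no-back-to-back constraint after ",
           maxRetries, " retries (infeasible for nImages = ", nImages,
           ", nReps = ", nReps, ")")
    isis <- sample(isiChoicesS, nTrials - 1L, replace = TRUE)
    onsets <- c(0, cumsum(stimDurS + isis))
    nTargets <- ceiling(targetRate * nTrials)
    targetIdx <- sample(nTrials, nTargets)
    trialsDf <- data.frame(image_id = order, onset_s = onsets,
                           duration_s = stimDurS,
                           is_target = seq_len(nTrials) %in% targetIdx,
                           stringsAsFactors = FALSE)
    new("TrialSequence", trials = trialsDf,
        runLength = onsets[nTrials] + stimDurS)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities in the canonical parameterization
#' (response delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
#' ratio 1/6), peak-normalized so the maximum response is 1.
#'
#' @param tS time points in seconds (must be >= 0).
#' @param peakDelay,undershootDelay gamma delay parameters in seconds.
#' @param peakDisp,undershootDisp dispersion (gamma scale) parameters.
#' @param ratio undershoot attenuation (response is divided by this).
#' @return HRF values at `tS`, max 1 over a dense reference grid.
#' @export
doubleGammaHRF <- function(tS, peakDelay = 6, undershootDelay = 16,
                           peakDisp = 1, undershootDisp = 1, ratio = 6) {
  if (any(tS < 0)) stop("tS must be nonnegative")
  raw <- function(t)
    stats::dgamma(t, shape = peakDelay / peakDisp, scale = peakDisp) -
      stats::dgamma(t, shape = undershootDelay / undershootDisp,
                    scale = undershootDisp) / ratio
  ref <- max(raw(seq(0, 32, by = 0.01)))
  raw(tS) / ref
}

#' HRF-convolved design matrix for one run
#'
#' Builds a boxcar (onset, duration) time course per image on a fine time
#' grid, convolves it with the double-gamma HRF, and samples the result at
#' volume acquisition times `t = volume_index * TR` (no slice-timing offsets).
#'
#' @param trialSeq a [TrialSequence-class].
#' @param trS repetition time in seconds (default 1.5).
#' @param nVolumes number of volumes; default covers the run plus a 24 s HRF
#'   tail.
#' @param imageIds regressor order; default: sorted unique ids in `seq`.
#' @param dt fine-grid resolution in seconds.
#' @param ... HRF parameter overrides passed to [doubleGammaHRF()].
#' @return A [DesignMatrix-class] (one column per image).
#' @export
buildDesign <- function(trialSeq, trS = 1.5, nVolumes = NULL, imageIds = NULL,
                        dt = 0.05, ...) {
  tr <- trials(trialSeq)
  if (is.null(imageIds))
    imageIds <- sort(unique(tr$image_id))
  if (is.null(nVolumes))
    nVolumes <- ceiling((runLength(trialSeq) + 24) / trS)
  nVolumes <- as.integer(nVolumes)
  if (nrow(tr) > 0 && max(tr$onset_s + tr$duration_s) > nVolumes * trS)
    stop("trial extends past the run end (", nVolumes * trS, " s)")
  tEnd <- nVolumes * trS
  grid <- seq(0, tEnd, by = dt)
  hk <- doubleGammaHRF(seq(0, 32, by = dt), ...)
  X <- matrix(0, nVolumes, length(imageIds))
  volT <- (seq_len(nVolumes) - 1L) * trS
  volIdx <- round(volT / dt) + 1L
  for (j in seq_along(imageIds)) {
    ev <- tr[tr$image_id == imageIds[j], , drop = FALSE]
    if (nrow(ev) == 0L) next
    box <- numeric(length(grid))
    for (k in seq_len(nrow(ev))) {
      on <- ev$onset_s[k]; off <- on + ev$duration_s[k]
      box[grid >= on & grid < off] <- 1
    }
    conv <- stats::convolve(box, rev(hk), type = "open")[seq_along(grid)] * dt
    X[, j] <- conv[volIdx]
  }
  new("DesignMatrix", values = X, trS = trS, regressorIds = imageIds)
}

#' Mass-univariate GLM beta estimation
#'
#' Ordinary least squares per voxel with an intercept nuisance column:
#' `bold = design %*% beta + intercept + error`. Returns the image
#' coefficients only.
#'
#' @param bold `n_volumes x n_voxels` BOLD matrix (in-mask voxels).
#' @param design a [DesignMatrix-class] with full column rank.
#' @param mask optional logical 3D array matching `ncol(bold)` in-mask count.
#' @param runId run label for the result.
#' @return A [BetaMaps-class] (`n_images x n_voxels`).
#' @export
fitGLM <- function(bold, design, mask = NULL, runId = "run1") {
  X <- cbind(as.matrix(design), `(intercept)` = 1)
  if (nrow(X) != nrow(bold))
    stop("bold and design disagree on the number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear regressor(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, bold)
  betas <- coefs[seq_len(ncol(X) - 1L), , drop = FALSE]
  betaMaps(unname(betas), mask = mask, imageIds = design@regressorIds,
           runId = runId)
}
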