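# Layer-to-brain mapping: leave-one-participant-out (LOPO) cross-validated
# regression of searchlight RSM triangles on model-layer RSM triangles,
# permutation-null z-scoring, the residual orthogonalization method, and
# sign-flip max-statistic group inference.

# slope+intercept OLS of y on x, prediction at x0; returns out-of-sample R^2
# of pred against held-out vector h. R^2 = 1 - SS_res/SS_tot and may be
# negative out of sample (never clipped: clipping would bias the null).
.simpleFitR2 <- function(x, y, x0, h) {
  vx <- stats::var(x)
  if (vx == 0) stop("degenerate predictor: zero variance")
  b <- stats::cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  pred <- a + b * x0
  sst <- sum((h - mean(h))^2)
  if (sst == 0) stop("degenerate held-out vector: zero variance")
  1 - sum((h - pred)^2) / sst
}

#' Leave-one-participant-out layer fit
#'
#' For each held-out participant: average the remaining participants'
#' searchlight triangle vectors entrywise, fit a slope+intercept regression
#' predicting that average from the layer's triangle vector, predict with the
#' fitted weights, and score the prediction against the held-out
#' participant's vector with out-of-sample `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param slVectors `n_participants x m` matrix of searchlight RSM upper
#'   triangles (one row per participant), `n_participants >= 3`.
#' @param layerVector length-`m` layer RSM upper triangle.
#' @return Numeric vector of per-fold (held-out participant) R-squared.
#' @export
lopoFit <- function(slVectors, layerVector) {
  slVectors <- as.matrix(slVectors)
  P <- nrow(slVectors)
  if (P < 3L) stop("need at least 3 participants for LOPO")
  if (ncol(slVectors) != length(layerVector))
    stop("vector length mismatch")
  tot <- colSums(slVectors)
  vapply(seq_len(P), function(p) {
    avg <- (tot - slVectors[p, ]) / (P - 1)
    .simpleFitR2(layerVector, avg, layerVector, slVectors[p, ])
  }, numeric(1))
}

#' Permutation null of the LOPO mean R-squared
#'
#' Each permutation independently shuffles the entries of every participant's
#' searchlight triangle (a fresh shuffle per participant per permutation),
#' reruns the full LOPO procedure, and stores the across-fold mean R-squared.
#'
#' @param slVectors as in [lopoFit()].
#' @param layerVector as in [lopoFit()].
#' @param nPerm number of permutations (default 500).
#' @param seed integer seed.
#' @return Numeric vector of `nPerm` null mean R-squared values.
#' @export
permutationNull <- function(slVectors, layerVector, nPerm = 500L, seed = 1L) {
  slVectors <- as.matrix(slVectors)
  m <- ncol(slVectors)
  withSeed(seed,
    vapply(seq_len(nPerm), function(i) {
      shuf <- t(apply(slVectors, 1, sample))
      mean(lopoFit(shuf, layerVector))
    }, numeric(1)))
}

#' Per-participant permutation z for one layer and one searchlight
#'
#' Converts each participant's true LOPO R-squared into a z-score against the
#' permutation null of the across-fold mean R-squared.
#'
#' @inheritParams permutationNull
#' @return List: `r_squared` (per fold), `null_mean`, `null_sd`, `z` (per
#'   fold), `mean_z` (across-fold mean R-squared z-scored against the null).
#' @export
layerFit <- function(slVectors, layerVector, nPerm = 500L, seed = 1L) {
  r2 <- lopoFit(slVectors, layerVector)
  nul <- permutationNull(slVectors, layerVector, nPerm, seed)
  nm <- mean(nul); ns <- stats::sd(nul)
  if (ns == 0) stop("degenerate permutation null: zero spread")
  list(r_squared = r2, null_mean = nm, null_sd = ns, z = (r2 - nm) / ns,
       mean_z = (mean(r2) - nm) / ns)
}

# Per-participant searchlight triangle vectors: average each participant's
# betas over runs, then correlate within the searchlight.
.participantTriangles <- function(betamapsPerParticipant, cols) {
  t(vapply(betamapsPerParticipant, function(runs) {
    avg <- Reduce(`+`, lapply(runs, betaValues)) / length(runs)
    upperTriangle(computeRSM(avg[, cols, drop = FALSE]))
  }, numeric(nImages(betamapsPerParticipant[[1]][[1]]) *
               (nImages(betamapsPerParticipant[[1]][[1]]) - 1) / 2)))
}

#' Per-participant z map for one model layer
#'
#' At every searchlight center inside the (stability) mask, computes each
#' participant's LOPO R-squared for the layer and z-scores it against the
#' permutation null. Centers outside the mask, or degenerate ones, are
#' undefined (`NA`).
#'
#' @param betamapsPerParticipant list (participants) of lists (runs) of
#'   [BetaMaps-class].
#' @param layerRsm the layer's [LayerRSM-class].
#' @param mask analysis mask (typically the representational-stability mask).
#' @param halfWidth searchlight half-width.
#' @param nPerm permutations per center.
#' @param seed master seed (per-center seeds derived by counter).
#' @param centers optional subset of center linear indices to evaluate.
#' @return List of [StatMap-class] z maps, one per participant.
#' @export
zmapForLayer <- function(betamapsPerParticipant, layerRsm, mask,
                         halfWidth = 3L, nPerm = 500L, seed = 1L,
                         centers = NULL) {
  if (!any(mask)) {
    warning("empty analysis mask: returning empty maps")
    return(lapply(betamapsPerParticipant, function(p)
      new("StatMap", values = numeric(0), mask = mask,
          statisticName = "layer_z")))
  }
  layerVector <- upperTriangle(layerRsm)
  sls <- enumerateSearchlights(mask, halfWidth)
  if (!is.null(centers))
    sls <- Filter(function(s) s$centerId %in% centers, sls)
  inMaskBeta <- which(maskArray(betamapsPerParticipant[[1]][[1]]))
  P <- length(betamapsPerParticipant)
  zs <- matrix(NA_real_, P, length(which(mask)))
  maskIdx <- which(mask)
  for (i in seq_along(sls)) {
    sl <- sls[[i]]
    pos <- match(sl$centerId, maskIdx)
    cols <- match(sl$voxelIds, inMaskBeta)
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) next
    res <- tryCatch({
      tri <- .participantTriangles(betamapsPerParticipant, cols)
      layerFit(tri, layerVector, nPerm, seed = deriveSeed(seed, i))
    }, error = function(e) NULL)
    if (!is.null(res)) zs[, pos] <- res$z
  }
  lapply(seq_len(P), function(p)
    new("StatMap", values = zs[p, ], mask = mask, statisticName = "layer_z"))
}

#' Residual-method layer fit
#'
#' Isolates the variance a target layer uniquely explains: all triangle
#' vectors are z-scored; within each training fold the average searchlight
#' vector is residualized on the other layers' triangles (multiple regression
#' with intercept), the target layer is fit to those residuals, and the
#' held-out participant's vector is residualized with the training-fold
#' coefficients before scoring the prediction with out-of-sample R-squared.
#' Residualization is fold-honest: no coefficients are estimated on the
#' held-out participant.
#'
#' @param slVectors `n_participants x m` searchlight triangle matrix.
#' @param targetVector length-`m` triangle of the layer of interest.
#' @param otherVectors `m x K` matrix of the other layers' triangles
#'   (columns named by layer), or NULL/0-column for no residualization.
#' @return Numeric vector of per-fold R-squared.
#' @export
residualFit <- function(slVectors, targetVector, otherVectors = NULL) {
  .residualFitImpl(slVectors, targetVector, otherVectors)
}

#' Residualize a vector on a predictor set
#'
#' OLS residuals of `y` on the given predictors plus an intercept. The
#' residuals satisfy the normal-equation identity: they are orthogonal to
#' every predictor column and to the intercept.
#'
#' @param y response vector.
#' @param predictors `length(y) x K` matrix (or NULL for intercept only).
#' @return List: `residuals`, `coef` (including intercept), `X` (the design
#'   used, first column the intercept).
#' @export
residualize <- function(y, predictors = NULL) {
  X <- if (is.null(predictors) || NCOL(predictors) == 0L) matrix(1, length(y), 1)
       else cbind(1, as.matrix(predictors))
  beta <- qr.coef(qr(X), y)
  list(residuals = y - as.vector(X %*% beta), coef = beta, X = X)
}

.residualFitImpl <- function(slVectors, targetVector, otherVectors = NULL) {
  slVectors <- as.matrix(slVectors)
  P <- nrow(slVectors)
  if (P < 3L) stop("need at least 3 participants for LOPO")
  m <- ncol(slVectors)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("degenerate vector: zero variance before z-scoring")
    (v - mean(v)) / s
  }
  slZ <- t(apply(slVectors, 1, zscore))
  tgt <- zscore(targetVector)
  if (is.null(otherVectors) || NCOL(otherVectors) == 0L) {
    X <- matrix(1, m, 1)   # intercept only: residualization is centering
  } else {
    others <- apply(as.matrix(otherVectors), 2, zscore)
    nm <- colnames(otherVectors) %||% paste0("predictor", seq_len(ncol(others)))
    X <- cbind(1, others)
    colnames(X) <- c("(intercept)", nm)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("collinear predictors after z-scoring: ",
           paste(dropped, collapse = ", "))
    }
  }
  tot <- colSums(slZ)
  vapply(seq_len(P), function(p) {
    trainAvg <- (tot - slZ[p, ]) / (P - 1)
    rz <- residualize(trainAvg, X[, -1, drop = FALSE])
    heldResid <- slZ[p, ] - as.vector(rz$X %*% rz$coef)
    .simpleFitR2(tgt, rz$residuals, tgt, heldResid)
  }, numeric(1))
}

#' Sign-flip max-statistic group inference
#'
#' One-sample t across participants at every center, with family-wise error
#' control by sign-flip permutation of participants and the maximum statistic
#' over centers (a self-contained substitute for cluster-based corrections
#' such as TFCE; per-participant maps can be exported for external tools).
#' Centers with zero variance and positive mean are treated as significant
#' (infinite evidence); all-NA centers stay undefined.
#'
#' @param zMaps list of per-participant [StatMap-class] (or an
#'   `n_participants x n_centers` matrix), `>= 5` participants.
#' @param alpha family-wise alpha (default 0.05).
#' @param nSignFlips number of sign-flip permutations (default 1000).
#' @param seed integer seed.
#' @return List: `significant` (logical per center), `t` (observed t),
#'   `pFWE` (corrected p per center), `mask` (if StatMaps were supplied).
#' @export
groupInference <- function(zMaps, alpha = 0.05, nSignFlips = 1000L,
                           seed = 1L) {
  mask <- NULL
  if (is.list(zMaps) && is(zMaps[[1]], "StatMap")) {
    mask <- maskArray(zMaps[[1]])
    zMat <- do.call(rbind, lapply(zMaps, statValues))
  } else zMat <- as.matrix(zMaps)
  P <- nrow(zMat)
  if (P < 5L) stop("need at least 5 participants for group inference")
  tStat <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    tv <- mu / (sdv / sqrt(P))
    tv[sdv == 0 & mu > 0] <- Inf
    tv[sdv == 0 & mu <= 0] <- 0
    tv
  }
  tObs <- tStat(zMat)
  ok <- !apply(zMat, 2, function(col) any(is.na(col)))
  maxT <- withSeed(seed, vapply(seq_len(nSignFlips), function(i) {
    s <- sample(c(-1, 1), P, replace = TRUE)
    tp <- tStat(zMat[, ok, drop = FALSE] * s)
    if (length(tp)) max(tp, na.rm = TRUE) else -Inf
  }, numeric(1)))
  pFWE <- rep(NA_real_, length(tObs))
  pFWE[ok] <- vapply(tObs[ok], function(t0)
    (1 + sum(maxT >= t0)) / (1 + nSignFlips), numeric(1))
  sig <- !is.na(pFWE) & pFWE < alpha
  list(significant = sig, t = tObs, pFWE = pFWE, mask = mask)
}

#' Consolidated max-layer labeling
#'
#' Labels each center by the layer whose group t-statistic is largest among
#' layers significant there; ties broken by the lowest layer index. Centers
#' significant for no layer get `NA`.
#'
#' @param groupResults named list (per layer) of [groupInference()] results.
#' @return Character vector of layer labels per center (NA where none).
#' @export
maxLayerMap <- function(groupResults) {
  L <- length(groupResults)
  ids <- names(groupResults) %||% paste0("layer", seq_len(L))
  tMat <- do.call(rbind, lapply(groupResults, `[[`, "t"))
  sMat <- do.call(rbind, lapply(groupResults, `[[`, "significant"))
  tMat[!sMat] <- -Inf
  apply(tMat, 2, function(col) {
    if (all(!is.finite(col))) NA_character_
    else ids[which.max(col)]   # which.max takes the first (lowest) on ties
  })
}
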