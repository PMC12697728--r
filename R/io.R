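# Serialization: labelled CSV for similarity/overlap matrices and traces,
# NIfTI (+ JSON sidecar) for beta maps and statistic maps, FSL-style 3-column
# EV text files for trial sequences, PNG (+ lossless sidecar) for images.

#' Write a labelled matrix as CSV
#'
#' Values are written with 15 significant digits so a round-trip through
#' [readMatrixCSV()] reproduces them to that precision.
#'
#' @param x a [LayerRSM-class], [SecondOrderMatrix-class],
#'   [OverlapMatrix-class], [DesignMatrix-class] or plain matrix.
#' @param path output CSV path.
#' @param ids row/column labels (default: taken from the object).
#' @return Invisibly, `path`.
#' @export
writeMatrixCSV <- function(x, path, ids = NULL) {
  m <- as.matrix(x)
  if (is.null(ids)) {
    ids <- if (is(x, "LayerRSM")) sprintf("img%02d", seq_len(nrow(m)))
           else if (!is.null(rownames(m))) rownames(m)
           else if (!is.null(colnames(m))) colnames(m)
           else sprintf("v%02d", seq_len(nrow(m)))
  }
  fm <- matrix(formatC(m, digits = 15, format = "g"), nrow(m))
  df <- data.frame(id = ids, fm, stringsAsFactors = FALSE)
  names(df) <- c("id", if (ncol(m) == length(ids)) ids else colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled matrix CSV
#'
#' @param path CSV written by [writeMatrixCSV()].
#' @return Numeric matrix with dimnames from the file's labels.
#' @export
readMatrixCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write beta maps as a 4D NIfTI with a JSON sidecar
#'
#' One 3D volume per image (4th dimension = images); out-of-mask voxels are
#' NA. The sidecar records image ids, run id and the mask size.
#'
#' @param betas a [BetaMaps-class].
#' @param path output path (`.nii` or `.nii.gz`); sidecar gets `.json`.
#' @return Invisibly, `path`.
#' @export
writeBetaMapsNIfTI <- function(betas, path) {
  d <- dim(maskArray(betas))
  n <- nImages(betas)
  vol <- array(NA_real_, dim = c(d, n))
  idx <- which(maskArray(betas))
  for (i in seq_len(n)) {
    v3 <- array(NA_real_, dim = d)
    v3[idx] <- betaValues(betas)[i, ]
    vol[, , , i] <- v3
  }
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(image_ids = imageIds(betas),
                            run_id = betas@runId,
                            n_mask_voxels = length(idx)),
                       side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read beta maps written by [writeBetaMapsNIfTI()]
#'
#' @param path NIfTI path with its JSON sidecar alongside.
#' @return A [BetaMaps-class].
#' @export
readBetaMapsNIfTI <- function(path) {
  vol <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  d <- dim(vol)
  mask <- !is.na(vol[, , , 1])
  idx <- which(mask)
  vals <- t(vapply(seq_len(d[4]), function(i) {
    v3 <- vol[, , , i]
    v3[idx]
  }, numeric(length(idx))))
  betaMaps(vals, mask = mask, imageIds = side$image_ids,
           runId = side$run_id)
}

#' Write a statistic map as NIfTI
#'
#' Undefined centers are stored as NaN; the JSON sidecar records the
#' statistic name and any parameters passed in `params`.
#'
#' @param map a [StatMap-class].
#' @param path output NIfTI path.
#' @param params optional named list recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
writeStatMapNIfTI <- function(map, path, params = list()) {
  d <- dim(maskArray(map))
  vol <- array(NaN, dim = d)
  v <- statValues(map)
  v[is.na(v)] <- NaN     # undefined centers become NaN, not R's NA payload
  vol[which(maskArray(map))] <- v
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  jsonlite::write_json(c(list(statistic = map@statisticName), params),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a trial sequence as FSL-style EV files
#'
#' One whitespace-delimited 3-column file (onset, duration, weight 1) per
#' image, named `<prefix>_<image_id>.txt`.
#'
#' @param trialSeq a [TrialSequence-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"ev"`).
#' @return Invisibly, the written paths.
#' @export
writeSequenceEV <- function(trialSeq, dir, prefix = "ev") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- trials(trialSeq)
  ids <- sort(unique(tr$image_id))
  paths <- vapply(ids, function(id) {
    ev <- tr[tr$image_id == id, c("onset_s", "duration_s")]
    ev$weight <- 1
    p <- file.path(dir, paste0(prefix, "_", id, ".txt"))
    utils::write.table(format(ev, digits = 10), p, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write a stimulus set as PNGs plus a lossless sidecar
#'
#' Each image is written as an 8-bit PNG (pixels rescaled from the declared
#' range) for viewing, and the exact floating-point state is written to one
#' `.rds` sidecar so reloading does not quantize the optimization state.
#'
#' @param stimuli a [StimulusSet-class].
#' @param dir output directory.
#' @param prefix file-name prefix (default `"stim"`).
#' @return Invisibly, `dir`.
#' @export
writeStimulusSet <- function(stimuli, dir, prefix = "stim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- pixelArray(stimuli)
  rg <- pixelRange(stimuli)
  for (i in seq_len(nImages(stimuli))) {
    img <- (px[i, , , ] - rg[1]) / (rg[2] - rg[1])
    png::writePNG(img, file.path(dir, paste0(prefix, "_",
                                             imageIds(stimuli)[i], ".png")))
  }
  saveRDS(stimuli, file.path(dir, paste0(prefix, "_float.rds")))
  invisible(dir)
}

#' Reload a stimulus set from its lossless sidecar
#'
#' @param dir directory written by [writeStimulusSet()].
#' @param prefix the prefix used when writing.
#' @return The exact [StimulusSet-class] that was written.
#' @export
readStimulusSet <- function(dir, prefix = "stim") {
  readRDS(file.path(dir, paste0(prefix, "_float.rds")))
}
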