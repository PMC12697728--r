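# Configuration-driven workflows chaining the modules: stimulus synthesis;
# design + simulation; stability, layer mapping, residual mapping, overlap.
# Every stage is a thin wrapper over the exported functions; a manifest
# (inputs, outputs, seeds, versions, per-stage timing) makes runs exactly
# reproducible.

.requiredBlocks <- list(
  synth = "synthesis",
  design = "design",
  simulate = c("simulation"),
  stability = c("simulation", "stability"),
  map = c("simulation", "mapping"),
  residual = c("simulation", "mapping"),
  overlap = "overlap",
  demo = character(0))

.validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  wf <- config$workflow
  if (is.null(wf) || !wf %in% names(.requiredBlocks))
    stop("config$workflow must be one of: ",
         paste(names(.requiredBlocks), collapse = ", "))
  missing <- setdiff(.requiredBlocks[[wf]], names(config))
  if (length(missing))
    stop("config missing required block(s) for workflow '", wf, "': ",
         paste(missing, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

.demoAdapter <- function(seed) {
  randomCNNAdapter(inputSize = c(32L, 32L), channels = c(6L, 8L), seed = seed)
}

#' Run a configured workflow
#'
#' Executes one of the package's workflow stages end-to-end, writing all
#' numeric outputs (CSV/JSON/NIfTI/PNG) under `outDir` together with a
#' manifest recording the configuration, master seed, package version and
#' per-stage wall time. Reusing the manifest's config and seed reproduces
#' every numeric output.
#'
#' Workflows: `synth` (noise init, channel diversification, RSM
#' orthogonalization, baseline comparison), `design` (trial sequence + design
#' matrix + EV export), `simulate` (synthetic beta maps), `stability`
#' (simulation + stability map), `map` / `residual` (simulation + layer z
#' maps + group inference), `overlap` (overlap matrix + bootstrap from
#' supplied significant-voxel CSVs), `demo` (a scaled-down chain of
#' synthesis, simulation, stability, mapping and overlap).
#'
#' @param config list or YAML path; must contain `workflow`, a `seed`, and
#'   the parameter blocks the workflow needs.
#' @param outDir output directory (created).
#' @return Invisibly, the manifest list.
#' @export
runWorkflow <- function(config, outDir) {
  config <- .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(workflow = config$workflow, seed = config$seed,
                   package_version = as.character(utils::packageVersion("layerprint")),
                   config = config, stages = list(), outputs = character(0))
  addOutput <- function(p) manifest$outputs <<- c(manifest$outputs, p)
  runStage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      ok = !inherits(res, "error"),
      error = if (inherits(res, "error")) conditionMessage(res) else NULL)
    if (inherits(res, "error")) {
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  wf <- config$workflow
  if (wf %in% c("synth", "demo")) {
    sy <- config$synthesis %||% list()
    adapter <- .demoAdapter(config$seed)
    cfg <- synthesisConfig(
      nImages = sy$n_images %||% 8L,
      phase1Iters = sy$phase1_iters %||% 20L,
      phase2Iters = sy$phase2_iters %||% 40L,
      stepSize = sy$step_size %||% 0.02,
      rgbBreadthWeight = sy$rgb_breadth_weight %||% 0.1,
      seed = config$seed)
    trace <- runStage("synthesis", function() {
      s0 <- initNoise(cfg, adapter)
      s1 <- diversifyPhase(s0, adapter, cfg)
      orthogonalizePhase(s1, adapter, cfg)
    })
    runStage("synthesis_outputs", function() {
      writeStimulusSet(trace@finalImages, file.path(outDir, "images"))
      writeMatrixCSV(trace@finalSom, file.path(outDir, "second_order_final.csv"),
                     ids = layerIds(trace@finalSom))
      writeMatrixCSV(trace@initialSom,
                     file.path(outDir, "second_order_initial.csv"),
                     ids = layerIds(trace@initialSom))
      utils::write.csv(data.frame(iteration = seq_along(trace@costPerIteration),
                                  cost = trace@costPerIteration),
                       file.path(outDir, "synthesis_trace.csv"),
                       row.names = FALSE)
      addOutput(c("images/", "second_order_final.csv",
                  "second_order_initial.csv", "synthesis_trace.csv"))
    })
  }

  if (wf == "design") {
    de <- config$design %||% list()
    trialSeq <- runStage("design", function()
      generateSequence(nImages = de$n_images %||% 16L,
                       nReps = de$n_reps %||% 5L,
                       stimDurS = de$stim_dur_s %||% 1.5,
                       targetRate = de$target_rate %||% 0.1,
                       seed = config$seed))
    runStage("design_outputs", function() {
      writeSequenceEV(trialSeq, file.path(outDir, "ev"))
      X <- buildDesign(trialSeq, trS = de$tr_s %||% 1.5)
      writeMatrixCSV(as.matrix(X), file.path(outDir, "design_matrix.csv"),
                     ids = sprintf("vol%03d", seq_len(nrow(as.matrix(X)))))
      addOutput(c("ev/", "design_matrix.csv"))
    })
  }

  if (wf %in% c("simulate", "stability", "map", "residual", "demo")) {
    si <- config$simulation %||% list()
    grid <- as.integer(si$grid_shape %||% c(14L, 14L, 14L))
    L <- si$n_layers %||% 4L
    nImg <- si$n_images %||% 8L
    rsms <- orthogonalLayerRSMs(L, nImages = nImg, seed = config$seed)
    regionCube <- function(orig, size, grid) {
      g <- expand.grid(x = orig[1]:(orig[1] + size - 1),
                       y = orig[2]:(orig[2] + size - 1),
                       z = orig[3]:(orig[3] + size - 1))
      g$x + (g$y - 1) * grid[1] + (g$z - 1) * grid[1] * grid[2]
    }
    sz <- si$region_size %||% 5L
    regions <- list(
      list(voxels = regionCube(c(2L, 2L, 2L), sz, grid),
           layerId = names(rsms)[1], signalScale = si$signal_scale %||% 1),
      list(voxels = regionCube(grid - sz, sz, grid),
           layerId = names(rsms)[2], signalScale = si$signal_scale %||% 1))
    spec <- groundTruthSpec(gridShape = grid, regions = regions,
                            noiseSd = si$noise_sd %||% 0.5,
                            nParticipants = si$n_participants %||% 6L,
                            nRuns = si$n_runs %||% 4L,
                            participantSd = si$participant_sd %||% 0.2,
                            seed = config$seed)
    sim <- runStage("simulate", function() simulateBetaMaps(spec, rsms))
    runStage("simulate_outputs", function() {
      jsonlite::write_json(list(grid = grid, seed = config$seed,
                                regions = lapply(regions, function(r)
                                  list(layer = r$layerId,
                                       n_voxels = length(r$voxels),
                                       signal_scale = r$signalScale))),
                           file.path(outDir, "ground_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      writeBetaMapsNIfTI(sim$betamaps[[1]][[1]],
                         file.path(outDir, "betas_sub01_run1.nii.gz"))
      addOutput(c("ground_truth.json", "betas_sub01_run1.nii.gz"))
    })

    regionCenters <- vapply(regions, function(r)
      r$voxels[ceiling(length(r$voxels) / 2)], numeric(1))
    if (wf %in% c("stability", "demo")) {
      st <- config$stability %||% list()
      zmap <- runStage("stability", function() {
        mask <- array(FALSE, dim = grid)
        mask[unlist(lapply(regions, `[[`, "voxels"))] <- TRUE
        stabilityMap(sim$betamaps[[1]], mask = mask,
                     halfWidth = st$half_width %||% 2L,
                     nResamples = st$n_resamples %||% 500L,
                     seed = config$seed)
      })
      runStage("stability_outputs", function() {
        writeStatMapNIfTI(zmap, file.path(outDir, "stability_z.nii.gz"),
                          params = list(seed = config$seed))
        addOutput("stability_z.nii.gz")
      })
    }
    if (wf %in% c("map", "residual", "demo")) {
      mp <- config$mapping %||% list()
      mask <- array(FALSE, dim = grid)
      mask[regionCenters] <- TRUE
      useResidual <- wf == "residual"
      mapRes <- runStage(if (useResidual) "residual" else "map", function() {
        lapply(names(rsms), function(lid) {
          if (!useResidual) {
            maps <- zmapForLayer(sim$betamaps, rsms[[lid]], mask,
                                 halfWidth = mp$half_width %||% 2L,
                                 nPerm = mp$n_perm %||% 100L,
                                 seed = config$seed)
            do.call(rbind, lapply(maps, statValues))
          } else {
            others <- vapply(rsms[setdiff(names(rsms), lid)], upperTriangle,
                             numeric(nImg * (nImg - 1) / 2))
            sls <- enumerateSearchlights(mask, mp$half_width %||% 2L)
            inMaskBeta <- which(maskArray(sim$betamaps[[1]][[1]]))
            t(vapply(sls, function(sl) {
              cols <- match(sl$voxelIds, inMaskBeta)
              tri <- .participantTriangles(sim$betamaps, cols)
              residualFit(tri, upperTriangle(rsms[[lid]]), others)
            }, numeric(length(sim$betamaps))))
          }
        })
      })
      names(mapRes) <- names(rsms)
      group <- runStage("group_inference", function()
        lapply(mapRes, groupInference,
               alpha = mp$alpha %||% 0.05,
               nSignFlips = mp$n_sign_flips %||% 500L,
               seed = config$seed))
      runStage("mapping_outputs", function() {
        df <- do.call(rbind, lapply(names(group), function(lid)
          data.frame(layer = lid,
                     center = which(mask),
                     t = group[[lid]]$t,
                     pFWE = group[[lid]]$pFWE,
                     significant = group[[lid]]$significant)))
        utils::write.csv(df, file.path(outDir, "layer_mapping.csv"),
                         row.names = FALSE)
        addOutput("layer_mapping.csv")
      })
      if (wf == "demo") {
        runStage("overlap", function() {
          sig <- lapply(group, function(g) which(mask)[g$significant])
          om <- overlapMatrix(sig)
          writeMatrixCSV(om, file.path(outDir, "overlap_matrix.csv"),
                         ids = layerIds(om))
          addOutput("overlap_matrix.csv")
        })
      }
    }
  }

  if (wf == "overlap") {
    ov <- config$overlap %||% list()
    runStage("overlap", function() {
      sigs <- lapply(ov$sig_map_files, function(f)
        utils::read.csv(f)$voxel)
      names(sigs) <- ov$layer_ids %||% paste0("layer", seq_along(sigs))
      om <- overlapMatrix(sigs)
      writeMatrixCSV(om, file.path(outDir, "overlap_matrix.csv"),
                     ids = layerIds(om))
      res <- list(mean_offdiag = meanOverlap(om, "all_offdiag"),
                  mean_adjacent = meanOverlap(om, "adjacent"))
      jsonlite::write_json(res, file.path(outDir, "overlap_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      addOutput(c("overlap_matrix.csv", "overlap_summary.json"))
    })
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
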