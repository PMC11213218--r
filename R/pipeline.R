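## End-to-end pipeline: simulate -> fit-nms -> train-som -> pnms -> validate,
## driven by a single YAML configuration and a single global seed from which
## every stage's seed is derived deterministically.

#' Default run configuration
#'
#' Returns the full configuration list the pipeline consumes; the same
#' structure is read from YAML by [readRunConfig()]. A commented template is
#' shipped at `system.file("extdata", "default_config.yaml",
#' package = "pnmsDCE")`.
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
  list(
    paths = list(output_dir = "pnms_out"),
    grid = list(n_frames = 400L, spacing_s = 1.55, injection_time_s = 60,
                exclude_frames = 20L),
    aif = list(peak = 3, alpha = 3, time_to_peak_s = 12,
               recirc_fraction = 0.3, recirc_rise_s = 30,
               washout_tau_s = 300),
    phantom = list(dim = c(32L, 32L, 3L), core_radius = 5, rim_radius = 8,
                   vp_range = c(0.01, 0.04), ktrans_range = c(0.05, 0.3),
                   kep_range = c(0.5, 2.5), noise_sd = 0.05),
    cohort = list(n_animals = 12L),
    nms = list(confidence_level = 0.95, kep_bounds = c(1e-3, 5)),
    som = list(rows = 8L, cols = 8L, initial_radius = 3,
               ordering_steps = 100L, max_epochs = 250L, init = "linear"),
    pnms = list(tau = 0.5, kep_floor = 1e-3),
    cv = list(k = 3L, train_fraction = 0.66, n_boot = 10000L),
    seed = 1L,
    log_level = "info"
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML file and merges it over [defaultRunConfig()]; unknown fields
#' are rejected and invalid values reported with the offending field named.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("unknown config section: ", sec)
      if (is.list(cfg[[sec]])) {
        for (key in names(user[[sec]])) {
          if (!key %in% names(cfg[[sec]]))
            stop("unknown config field: ", sec, "$", key)
          cfg[[sec]][[key]] <- user[[sec]][[key]]
        }
      } else cfg[[sec]] <- user[[sec]]
    }
  }
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @param config configuration list to validate.
#' @export
validateRunConfig <- function(config) {
  bad <- function(field, why) stop("invalid config: ", field, " ", why,
                                   call. = FALSE)
  if (config$pnms$tau <= 0 || config$pnms$tau > 1)
    bad("pnms$tau", "must lie in (0, 1]")
  if (config$nms$confidence_level <= 0 || config$nms$confidence_level >= 1)
    bad("nms$confidence_level", "must lie in (0, 1)")
  if (config$cv$k < 2) bad("cv$k", "must be >= 2")
  if (config$cv$k > config$cohort$n_animals)
    bad("cv$k", "must not exceed cohort$n_animals")
  if (config$grid$exclude_frames < 0 ||
      config$grid$exclude_frames * config$grid$spacing_s >=
        config$grid$injection_time_s)
    bad("grid$exclude_frames", "must keep some pre-injection baseline")
  if (config$phantom$noise_sd < 0) bad("phantom$noise_sd", "must be >= 0")
  invisible(TRUE)
}

.logInfo <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[pnmsDCE] ", fmt), ...))
}

.cfgGrid <- function(config) {
  g <- config$grid
  timeGrid(g$n_frames, g$spacing_s, g$injection_time_s, g$exclude_frames)
}

.cfgAIF <- function(config, grid) {
  a <- config$aif
  makeAIF(grid, a$peak, a$alpha, a$time_to_peak_s, a$recirc_fraction,
          a$recirc_rise_s, a$washout_tau_s)
}

.cfgSpec <- function(config) {
  p <- config$phantom
  phantomSpec(p$dim, p$core_radius, p$rim_radius, p$vp_range, p$ktrans_range,
              p$kep_range, p$noise_sd, seed = deriveSeed(config$seed, "phantom"))
}

.cfgSomConfig <- function(config) {
  s <- config$som
  somConfig(s$rows, s$cols, "hexagonal", s$initial_radius, s$ordering_steps,
            s$max_epochs, s$init, seed = deriveSeed(config$seed, "som"))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (cohort generation), `fit-nms` (label and parameter
#' maps), `train-som` (SOM weights, hit map, neuron probability table),
#' `pnms` (probability and averaged-parameter maps), `validate` (nested
#' cross-validation report), or `all`. Every stage writes its artifacts
#' under `outDir` plus a provenance manifest; a rerun with the same
#' configuration and seed is byte-identical.
#'
#' @param config configuration list from [readRunConfig()], or a YAML path.
#' @param stage one of "simulate", "fit-nms", "train-som", "pnms",
#'   "validate", "all".
#' @param outDir output directory (overrides `config$paths$output_dir`).
#' @return named list of in-memory stage results, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), stage = "all",
                        outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  stage <- match.arg(stage, c("simulate", "fit-nms", "train-som", "pnms",
                              "validate", "all"))
  outDir <- outDir %||% config$paths$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "fit-nms", "train-som", "pnms", "validate") else stage

  grid <- .cfgGrid(config)
  aif <- .cfgAIF(config, grid)
  state <- list(grid = grid, aif = aif)

  for (st in stages) {
    state <- switch(st,
      "simulate" = .stageSimulate(config, state, outDir),
      "fit-nms" = .stageFitNMS(config, state, outDir),
      "train-som" = .stageTrainSOM(config, state, outDir),
      "pnms" = .stagePNMS(config, state, outDir),
      "validate" = .stageValidate(config, state, outDir))
  }
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageSimulate <- function(config, state, outDir) {
  seed <- deriveSeed(config$seed, "cohort")
  cohort <- makeCohort(config$cohort$n_animals, .cfgSpec(config),
                       state$grid, state$aif, seed = seed)
  dir <- file.path(outDir, "cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (st in cohort) {
    base <- file.path(dir, st@animalId)
    writeVolume(st@dr1, paste0(base, "_dr1.nii"))
    writeVolume(st@labels, paste0(base, "_labels.nii"))
    writeVolume(st@truth$vp, paste0(base, "_true_vp.nii"))
    files <- c(files, paste0(st@animalId,
                             c("_dr1.nii", "_labels.nii", "_true_vp.nii")))
  }
  writeAIFCsv(state$aif, file.path(dir, "aif.csv"))
  writeAIFJson(state$aif, file.path(dir, "aif.json"))
  writeManifest(outDir, "simulate", config, list(cohort = seed),
                c(files, "aif.csv", "aif.json"))
  .logInfo(config, "simulate: %d animals, %d voxels each",
           length(cohort), sum(cohort[[1]]@mask))
  state$cohort <- cohort
  state
}

.stageFitNMS <- function(config, state, outDir) {
  if (is.null(state$cohort)) stop("fit-nms requires the simulate stage")
  dir <- file.path(outDir, "nms")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  res <- lapply(state$cohort, function(st) {
    r <- fitVolume(st, confidenceLevel = config$nms$confidence_level,
                   kepBounds = config$nms$kep_bounds)
    base <- file.path(dir, st@animalId)
    writeVolume(r@labelMap, paste0(base, "_labels.nii"))
    for (nm in c("vpM1", "vpM2", "ktransM2", "vpM3", "ktransM3", "kepM3"))
      writeVolume(r@maps[[nm]], paste0(base, "_", nm, ".nii"))
    r
  })
  files <- list.files(dir)
  writeManifest(outDir, "fit-nms", config, list(), files)
  .logInfo(config, "fit-nms: %d animals fit", length(res))
  state$nms <- res
  state
}

.stageTrainSOM <- function(config, state, outDir) {
  if (is.null(state$nms)) stop("train-som requires the fit-nms stage")
  profiles <- do.call(rbind, lapply(state$cohort, .studyProfiles))
  labels <- unlist(lapply(state$nms, function(r) r@labelMap[r@mask]),
                   use.names = FALSE)
  cfg <- .cfgSomConfig(config)
  som <- batchTrain(profiles, cfg)
  hm <- computeHitMap(som, profiles, labels)
  tab <- neuronProbabilities(hm, som)
  dir <- file.path(outDir, "som")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSOM(som, file.path(dir, "som.json"))
  writeHitMapCsv(hm, cfg, file.path(dir, "hitmap.csv"))
  utils::write.csv(
    data.frame(neuron = seq_len(nrow(tab@probs)), p1 = tab@probs[, 1],
               p2 = tab@probs[, 2], p3 = tab@probs[, 3],
               n_hits = tab@nHits, borrowed_from = tab@provenance),
    file.path(dir, "neuron_probabilities.csv"), row.names = FALSE)
  writeManifest(outDir, "train-som", config, list(som = cfg@seed),
                list.files(dir))
  .logInfo(config, "train-som: %d profiles, %d epochs (%s)",
           nrow(profiles), som@epochsTrained,
           if (som@converged) "converged" else "epoch limit")
  state$som <- som
  state$probTable <- tab
  state
}

.stagePNMS <- function(config, state, outDir) {
  if (is.null(state$som)) stop("pnms requires the train-som stage")
  dir <- file.path(outDir, "pnms")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- vector("list", length(state$cohort))
  for (i in seq_along(state$cohort)) {
    st <- state$cohort[[i]]
    pv <- voxelProbabilities(st, state$som, state$probTable,
                             tau = config$pnms$tau)
    maps <- pnmsParameterMaps(state$nms[[i]], pv, config$pnms$kep_floor)
    base <- file.path(dir, st@animalId)
    for (m in 1:3)
      writeVolume(pv@probs[, , , m], sprintf("%s_p%d.nii", base, m))
    writeVolume(maps@vp, paste0(base, "_vp_pct.nii"))
    writeVolume(maps@ktrans, paste0(base, "_ktrans_per_min.nii"))
    writeVolume(maps@ve, paste0(base, "_ve_pct.nii"))
    writeFusedRGB(pv, dir, paste0(st@animalId, "_rgb"))
    res[[i]] <- list(probs = pv, maps = maps)
  }
  writeManifest(outDir, "pnms", config, list(), list.files(dir))
  .logInfo(config, "pnms: maps written for %d animals", length(res))
  state$pnms <- res
  state
}

.stageValidate <- function(config, state, outDir) {
  if (is.null(state$nms)) stop("validate requires the fit-nms stage")
  report <- runNestedCV(state$cohort, k = config$cv$k,
                        trainFraction = config$cv$train_fraction,
                        somCfg = .cfgSomConfig(config),
                        confidenceLevel = config$nms$confidence_level,
                        tau = config$pnms$tau,
                        kepFloor = config$pnms$kep_floor,
                        seed = config$seed, nmsResults = state$nms,
                        nBoot = config$cv$n_boot)
  dir <- file.path(outDir, "validation")
  writeEvaluationReport(report, dir)
  writeManifest(outDir, "validate", config,
                list(folds = deriveSeed(config$seed, "folds")),
                list.files(dir))
  .logInfo(config, "validate: DSC m2 = %.3f, m3 = %.3f",
           report@summary$dsc_m2$mean, report@summary$dsc_m3$mean)
  state$report <- report
  state
}
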