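# Experiment configuration, neurogram-set generation, end-to-end
# orchestration and bundled fixtures.

#' Experiment configuration
#'
#' @slot preset "paper" or "desk".
#' @slot nTalkers,utterancesPerDigit Stimulus-grid dimensions.
#' @slot noiseLevels Noise levels in dB SPL.
#' @slot speechDbSpl Speech presentation level.
#' @slot nCF CF-grid size.
#' @slot fiberScale Multiplier on the Table-style fiber distributions.
#' @slot baseChannels,batchSize Network size parameters.
#' @slot phase1Budget,phase2Budget Training samples per phase.
#' @slot nFolds Cross-validation folds.
#' @slot seed Master seed.
#' @export
setClass("ExperimentConfig", representation(
  preset = "character", nTalkers = "integer", utterancesPerDigit = "integer",
  noiseLevels = "numeric", speechDbSpl = "numeric", nCF = "integer",
  fiberScale = "numeric", baseChannels = "integer", batchSize = "integer",
  phase1Budget = "integer", phase2Budget = "integer", nFolds = "integer",
  seed = "integer"))

#' Create an experiment configuration
#'
#' The "paper" preset reproduces the printed design (225 talkers, 2
#' utterances per digit, noise 0-100 dB SPL in 5 dB steps - 94,500 stimuli -
#' 128 CFs, 100 fibers/CF, 250,000-sample phases, batch 256, 10 folds). The
#' "desk" preset is a single-CPU reduction (10 talkers, 7 noise levels
#' spanning SNR +30..-30 dB, 32 CFs, fibers scaled to [2,2,6]/[0,0,5],
#' 20,000-sample phases, batch 64, 3 folds) that preserves every contract.
#'
#' @param preset "desk" or "paper".
#' @param seed Master seed.
#' @param ... Named overrides of any slot.
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(preset = c("desk", "paper"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") list(
    nTalkers = 225L, utterancesPerDigit = 2L, noiseLevels = seq(0, 100, 5),
    speechDbSpl = 70, nCF = 128L, fiberScale = 1, baseChannels = 16L,
    batchSize = 256L, phase1Budget = 250000L, phase2Budget = 250000L,
    nFolds = 10L)
  else list(
    nTalkers = 10L, utterancesPerDigit = 1L,
    noiseLevels = 70 - c(30, 20, 10, 0, -10, -20, -30),
    speechDbSpl = 70, nCF = 32L, fiberScale = 0.1, baseChannels = 8L,
    batchSize = 64L, phase1Budget = 20000L, phase2Budget = 20000L,
    nFolds = 3L)
  over <- list(...)
  base[names(over)] <- over
  methods::new("ExperimentConfig", preset = preset,
               nTalkers = as.integer(base$nTalkers),
               utterancesPerDigit = as.integer(base$utterancesPerDigit),
               noiseLevels = sort(as.numeric(base$noiseLevels)),
               speechDbSpl = base$speechDbSpl, nCF = as.integer(base$nCF),
               fiberScale = base$fiberScale,
               baseChannels = as.integer(base$baseChannels),
               batchSize = as.integer(base$batchSize),
               phase1Budget = as.integer(base$phase1Budget),
               phase2Budget = as.integer(base$phase2Budget),
               nFolds = as.integer(base$nFolds), seed = as.integer(seed))
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf(
    "ExperimentConfig '%s': %d talkers x %d utt x 10 digits x %d levels; %d CFs; seed %d\n",
    object@preset, object@nTalkers, object@utterancesPerDigit,
    length(object@noiseLevels), object@nCF, object@seed))
})

#' Content hash of a configuration
#'
#' @param config An [ExperimentConfig-class].
#' @return MD5 hex string of the serialized configuration.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  sl <- methods::slotNames(config)
  jsonlite::write_json(stats::setNames(lapply(sl, function(s)
    methods::slot(config, s)), sl), tmp, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Generate the finalized neurogram set for one cochlear state
#'
#' Synthesizes each manifest row's token (cached per talker/digit/utterance),
#' calibrates it, mixes the row's noise, runs the periphery under `state`,
#' and finalizes (trims to 70 frames, z-scores). Reproducible given the
#' manifest seeds.
#'
#' @param manifest Manifest from [buildStimulusGrid()].
#' @param talkers List of [TalkerProfile-class] covering the manifest ids.
#' @param state A [CochlearState-class].
#' @param prepared Optional [preparePeriphery()] output for the state's grid.
#' @param verbose Print progress every 100 rows.
#' @return A [NeurogramSet-class] aligned with the manifest rows.
#' @export
generateNeurogramSet <- function(manifest, talkers, state, prepared = NULL,
                                 verbose = FALSE) {
  if (is.null(prepared)) prepared <- preparePeriphery(state@cfGrid)
  nCF <- length(state@cfGrid@cfs)
  n <- nrow(manifest)
  out <- array(0, c(nCF, 70L, n))
  tokenCache <- new.env(parent = emptyenv())
  byId <- stats::setNames(talkers, vapply(talkers, function(t) as.character(t@id),
                                          character(1)))
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    key <- sprintf("t%d_d%d_u%d_l%g", row$talker_id, row$digit, row$utterance,
                   row$speech_db)
    tok <- tokenCache[[key]]
    if (is.null(tok)) {
      tok <- synthesizeDigit(row$digit, byId[[as.character(row$talker_id)]],
                             levelDbSpl = row$speech_db,
                             utterance = row$utterance)
      tokenCache[[key]] <- tok
    }
    stim <- mixWithNoise(tok, row$noise_db, seed = row$seed)
    ng <- finalizeNeurogram(generateNeurogram(stim, state,
                                              seed = deriveSeed(row$seed, "poisson"),
                                              prepared = prepared))
    out[, , i] <- ng@values
    if (verbose && i %% 100L == 0L)
      message("  neurogram ", i, "/", n, " (", state@id, ")")
  }
  meta <- manifest
  meta$state_id <- state@id
  methods::new("NeurogramSet", values = out, meta = meta,
               cfGrid = state@cfGrid, frameRate = 100)
}

#' Run a digit-in-noise experiment end to end
#'
#' Builds the stimulus grid and talker pool, generates neurogram sets for the
#' NH reference state and each requested degraded state, trains the phase-1
#' NH-baseline per fold, runs the requested phase-2 paradigms, and reduces
#' everything to psychometric curves, sigmoid fits and 50%-SNR thresholds.
#' Fully deterministic given the configuration seed.
#'
#' @param config An [ExperimentConfig-class].
#' @param stateIds Character ids of degraded states to study (names of
#'   [table1States()] of the config's grid); NULL for the NH-only study.
#' @param paradigms Character names of phase-2 paradigms to run on each
#'   degraded state.
#' @param folds Integer fold indices (0-based) to run; NULL = all configured.
#' @param outDir Optional output directory (manifest CSV, accuracy CSV, fit
#'   JSON, run log JSON).
#' @param verbose Emit progress messages.
#' @return List: `config`, `manifest`, `nhCurve` ([PsychometricCurve-class]),
#'   `nhFit`, `nhThreshold`, and per-state results (`states`) with paradigm
#'   accuracy tables, pooled curves, fits, thresholds, and trained networks
#'   of the last fold.
#' @export
runExperiment <- function(config, stateIds = NULL,
                          paradigms = c("nh_control", "unconstrained",
                                        "constrained"),
                          folds = NULL, outDir = NULL, verbose = FALSE) {
  seed <- config@seed
  grid <- cfGrid(config@nCF)
  allStates <- table1States(grid, config@fiberScale)
  nhState <- allStates[[1]]   # NH audiogram, MOCR 20 dB, healthy fibers
  talkers <- makeTalkers(config@nTalkers, seed = deriveSeed(seed, "talkers"))
  manifest <- buildStimulusGrid(config@nTalkers, config@utterancesPerDigit,
                                config@noiseLevels, config@speechDbSpl,
                                seed = deriveSeed(seed, "grid"))
  prepared <- preparePeriphery(grid)
  if (verbose) message("generating NH neurograms (", nrow(manifest), ")")
  nhSet <- generateNeurogramSet(manifest, talkers, nhState, prepared, verbose)
  stateSets <- list()
  for (sid in stateIds) {
    if (!sid %in% names(allStates)) stop("unknown state id: ", sid)
    if (verbose) message("generating neurograms for state ", sid)
    stateSets[[sid]] <- generateNeurogramSet(manifest, talkers,
                                             allStates[[sid]], prepared, verbose)
  }
  allFolds <- makeFolds(manifest, config@nFolds, seed = deriveSeed(seed, "folds"))
  if (is.null(folds)) folds <- seq_len(config@nFolds) - 1L
  netCfg <- networkConfig(c(config@nCF, 70L), baseChannels = config@baseChannels,
                          batchSize = config@batchSize)
  nhTables <- list(); baselines <- list()
  stateResults <- stats::setNames(vector("list", length(stateIds)), stateIds)
  for (sid in stateIds)
    stateResults[[sid]] <- list(tables = stats::setNames(
      lapply(paradigms, function(p) list()), paradigms))
  for (f in folds) {
    fold <- allFolds[[f + 1L]]
    if (verbose) message("fold ", f, ": phase-1 NH baseline")
    baseline <- trainBaseline(netCfg, nhSet, fold, config@phase1Budget,
                              seed = deriveSeed(seed, paste0("bl", f)))
    baselines[[as.character(f)]] <- baseline
    nhTables[[length(nhTables) + 1L]] <-
      evaluateBySnr(baseline, nhSet, foldRows(fold, nhSet@meta, "test"))
    for (sid in stateIds) {
      for (p in paradigms) {
        if (verbose) message("fold ", f, ": ", sid, " / ", p)
        res <- runParadigm(baseline, paradigm(p), fold, nhSet, stateSets[[sid]],
                           config@phase2Budget,
                           seed = deriveSeed(seed, paste0(sid, p, f)))
        stateResults[[sid]]$tables[[p]][[length(stateResults[[sid]]$tables[[p]]) + 1L]] <-
          res$accuracy
        stateResults[[sid]]$lastNetwork <- res$state
      }
    }
  }
  nhCurve <- poolFoldCurves(nhTables)
  nhFit <- fitSigmoid(nhCurve, "model")
  out <- list(config = config, manifest = manifest, nhCurve = nhCurve,
              nhFit = nhFit, nhThreshold = snrAtAccuracy(nhFit, 0.5),
              nhBaselines = baselines, states = list())
  for (sid in stateIds) {
    st <- list()
    for (p in paradigms) {
      curve <- poolFoldCurves(stateResults[[sid]]$tables[[p]])
      fit <- tryCatch(fitSigmoid(curve, "model"), error = function(e) NULL)
      st[[p]] <- list(tables = stateResults[[sid]]$tables[[p]], curve = curve,
                      fit = fit,
                      threshold = if (!is.null(fit)) snrAtAccuracy(fit, 0.5)
                                  else NA_real_)
    }
    st$lastNetwork <- stateResults[[sid]]$lastNetwork
    out$states[[sid]] <- st
  }
  if (!is.null(outDir)) writeExperiment(out, outDir)
  out
}

# Persist the result bundle: manifest CSV, accuracy CSVs, fits/thresholds
# JSON, and a run log with the config hash.
writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeManifest(result$manifest, file.path(outDir, "manifest.csv"))
  rows <- data.frame(state_id = "NH", paradigm = "baseline",
                     snr_db = result$nhCurve@snrDb,
                     accuracy = result$nhCurve@accuracy,
                     sem = result$nhCurve@sem)
  for (sid in names(result$states))
    for (p in setdiff(names(result$states[[sid]]), "lastNetwork")) {
      cv <- result$states[[sid]][[p]]$curve
      rows <- rbind(rows, data.frame(state_id = sid, paradigm = p,
                                     snr_db = cv@snrDb, accuracy = cv@accuracy,
                                     sem = cv@sem))
    }
  utils::write.csv(rows, file.path(outDir, "accuracy.csv"), row.names = FALSE)
  fits <- list(nh = list(a = result$nhFit@a, b = result$nhFit@b,
                         threshold50 = result$nhThreshold))
  for (sid in names(result$states))
    for (p in setdiff(names(result$states[[sid]]), "lastNetwork")) {
      f <- result$states[[sid]][[p]]$fit
      fits[[paste(sid, p, sep = "|")]] <-
        if (is.null(f)) list(threshold50 = NA) else
        list(a = f@a, b = f@b, threshold50 = result$states[[sid]][[p]]$threshold)
    }
  jsonlite::write_json(fits, file.path(outDir, "fits.json"), digits = NA,
                       auto_unbox = TRUE)
  jsonlite::write_json(list(configHash = configHash(result$config),
                            seed = result$config@seed,
                            preset = result$config@preset,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(outDir, "run.json"), auto_unbox = TRUE)
  invisible(outDir)
}

#' Generate the bundled tiny fixture set
#'
#' 4 talkers x 10 digits (40 tokens), 3 noise levels (SNR +15, 0, -15 dB),
#' 2 cochlear states (NH and NH-audiogram ANF-degraded), 16-CF neurograms:
#' a small, fully in-memory dataset for tests and examples. Byte-identical
#' regeneration given the seed.
#'
#' @param seed Master seed.
#' @return List: `manifest` (120 rows), `talkers`, `states` (2), `sets`
#'   (named list of [NeurogramSet-class]).
#' @export
makeFixtures <- function(seed = 1L) {
  grid <- cfGrid(16L)
  # NH healthy periphery and the NH-audiogram ANF-degraded state
  states <- table1States(grid, fiberScale = 0.1)[c(1, 2)]
  talkers <- makeTalkers(4L, seed = deriveSeed(seed, "talkers"))
  manifest <- buildStimulusGrid(4L, 1L, c(55, 70, 85),
                                seed = deriveSeed(seed, "grid"))
  prepared <- preparePeriphery(grid)
  sets <- lapply(states, function(s)
    generateNeurogramSet(manifest, talkers, s, prepared))
  list(manifest = manifest, talkers = talkers, states = states, sets = sets)
}
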