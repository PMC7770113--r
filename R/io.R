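# Plain-text persistence: single neurograms and network checkpoints as JSON,
# manifests and accuracy tables as CSV.

#' Write a neurogram to JSON
#'
#' Stores the value matrix, CF grid, frame rate, flags and metadata in a
#' single self-describing JSON file.
#'
#' @param ng A [Neurogram-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNeurogram <- function(ng, path) {
  obj <- list(values = ng@values, cfs = ng@cfGrid@cfs, frameRate = ng@frameRate,
              normalized = ng@normalized, degenerate = ng@degenerate,
              metadata = ng@metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a neurogram written by [writeNeurogram()]
#'
#' @param path Input path.
#' @return A [Neurogram-class].
#' @export
readNeurogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  md <- as.list(obj$metadata)
  vals <- obj$values
  if (!is.matrix(vals))
    vals <- matrix(unlist(vals), nrow = length(obj$cfs), byrow = TRUE)
  methods::new("Neurogram", values = vals,
               cfGrid = methods::new("CFGrid", cfs = obj$cfs),
               frameRate = obj$frameRate, normalized = obj$normalized,
               degenerate = obj$degenerate, metadata = md)
}

#' Save a network checkpoint to JSON
#'
#' One group per layer with weight and bias arrays, plus the step counter,
#' seed and configuration.
#'
#' @param state A [NetworkState-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(state, path) {
  cfg <- state@config
  obj <- list(
    step = state@step, seed = state@seed,
    config = list(inputShape = cfg@inputShape, baseChannels = cfg@baseChannels,
                  batchSize = cfg@batchSize, learningRate = cfg@learningRate,
                  weightDecay = cfg@weightDecay, initStd = cfg@initStd),
    params = lapply(state@params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network checkpoint written by [saveCheckpoint()]
#'
#' Rebuilds the architecture from the stored configuration, then overwrites
#' parameters, step and seed. Optimizer moments are reset.
#'
#' @param path Input path.
#' @return A [NetworkState-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- networkConfig(inputShape = obj$config$inputShape,
                       baseChannels = obj$config$baseChannels,
                       batchSize = obj$config$batchSize,
                       learningRate = obj$config$learningRate,
                       weightDecay = obj$config$weightDecay,
                       initStd = {
                         iv <- obj$config$initStd
                         if (is.null(iv) || is.character(iv) || is.na(iv))
                           NA_real_ else as.numeric(iv)
                       })
  state <- buildNetwork(cfg, seed = obj$seed)
  params <- state@params
  for (nm in names(params)) {
    p <- obj$params[[nm]]
    params[[nm]] <- if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
      else as.numeric(p$data)
  }
  state@params <- params
  state@step <- as.integer(obj$step)
  state
}

#' Write cochlear states to a JSON configuration
#'
#' Serializes the factorial design (audiogram kind and thresholds, MOCR gain,
#' fiber distribution, CF-grid size) so a state list can be rebuilt exactly
#' with [readStateConfig()].
#'
#' @param states List of [CochlearState-class] (e.g. [table1States()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeStateConfig <- function(states, path) {
  obj <- lapply(states, function(s) list(
    id = s@id, kind = s@audiogram@kind,
    thresholds_db_hl = s@audiogram@thresholdsDbHl,
    mocr_gain_db = s@mocrGainDb, fiber_counts = s@fiberCounts,
    n_cf = length(s@cfGrid@cfs)))
  jsonlite::write_json(unname(obj), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read cochlear states from a JSON configuration
#'
#' @param path JSON file written by [writeStateConfig()].
#' @param grid Optional [CFGrid-class] overriding the stored grid size.
#' @return Named list of [CochlearState-class] objects.
#' @export
readStateConfig <- function(path, grid = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- list()
  for (e in obj) {
    g <- if (is.null(grid)) cfGrid(e$n_cf) else grid
    prof <- audiometricProfile(e$kind, thresholdsDbHl = unlist(e$thresholds_db_hl))
    st <- cochlearState(prof, e$mocr_gain_db, unlist(e$fiber_counts), g, id = e$id)
    out[[st@id]] <- st
  }
  out
}
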