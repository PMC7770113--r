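# S4 classes for the digit-in-noise pipeline. Constructors live with their
# modules; validity methods encode the documented invariants.

#' Virtual base class for calibrated waveforms
#'
#' Holds dimensionless pressure samples under the package convention that
#' full-scale amplitude 1.0 equals 94 dB SPL (1 Pa RMS).
#'
#' @slot samples Numeric vector of pressure samples.
#' @slot sampleRate Sampling rate in Hz.
#' @keywords internal
#' @export
setClass("Waveform", representation("VIRTUAL",
  samples = "numeric", sampleRate = "numeric"))

setValidity("Waveform", function(object) {
  if (!all(is.finite(object@samples))) return("samples must be finite")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    return("sampleRate must be a positive scalar")
  TRUE
})

#' A synthesized spoken-digit token
#'
#' A calibrated single-digit utterance: pressure samples with the digit label,
#' talker identity, and presentation level.
#'
#' @slot digit Integer digit 0-9.
#' @slot talkerId Integer talker identifier.
#' @slot levelDbSpl Presentation level in dB SPL.
#' @seealso [synthesizeDigit()], [setLevel()]
#' @export
setClass("DigitToken", contains = "Waveform", representation(
  digit = "integer", talkerId = "integer", levelDbSpl = "numeric"))

setValidity("DigitToken", function(object) {
  dur <- length(object@samples) / object@sampleRate
  if (dur < 0.3 - 1e-9 || dur > 0.7 + 1e-9)
    return(sprintf("token duration %.3f s outside [0.3, 0.7] s", dur))
  if (object@digit < 0L || object@digit > 9L) return("digit must be 0-9")
  if (is.finite(object@levelDbSpl) &&
      abs(measureLevel(object@samples) - object@levelDbSpl) > 0.01)
    return("measured level disagrees with levelDbSpl by more than 0.01 dB")
  TRUE
})

#' A digit token mixed with calibrated white noise
#'
#' @slot digit Integer digit 0-9.
#' @slot talkerId Integer talker identifier.
#' @slot speechLevelDbSpl Speech level in dB SPL.
#' @slot noiseLevelDbSpl Noise level in dB SPL (-Inf for the quiet reference).
#' @slot snrDb Signal-to-noise ratio: speech minus noise level.
#' @seealso [mixWithNoise()]
#' @export
setClass("NoisyStimulus", contains = "Waveform", representation(
  digit = "integer", talkerId = "integer", speechLevelDbSpl = "numeric",
  noiseLevelDbSpl = "numeric", snrDb = "numeric"))

setValidity("NoisyStimulus", function(object) {
  want <- object@speechLevelDbSpl - object@noiseLevelDbSpl
  same <- (is.nan(want) && is.nan(object@snrDb)) ||
    isTRUE(want == object@snrDb) ||
    (is.finite(want) && abs(object@snrDb - want) < 1e-12)
  if (!same) return("snrDb must equal speechLevelDbSpl - noiseLevelDbSpl")
  TRUE
})

#' A talker profile for the synthetic-digit generator
#'
#' Identical profile and seed give bit-identical tokens; tokens vary across
#' talkers through fundamental-frequency jitter and formant scaling.
#'
#' @slot f0Hz Fundamental frequency in Hz.
#' @slot formantScale Unitless multiplier applied to all formant targets.
#' @slot seed Integer seed driving the talker's stochastic components.
#' @slot id Integer talker identifier.
#' @export
setClass("TalkerProfile", representation(
  f0Hz = "numeric", formantScale = "numeric", seed = "integer", id = "integer"))

setValidity("TalkerProfile", function(object) {
  if (object@f0Hz <= 0) return("f0Hz must be positive")
  if (object@formantScale <= 0) return("formantScale must be positive")
  TRUE
})

#' A pure-tone audiometric profile
#'
#' Thresholds in dB HL at the seven standard audiometric frequencies.
#'
#' @slot frequenciesHz Audiometric frequencies (Hz).
#' @slot thresholdsDbHl Thresholds in dB HL (>= 0, finite).
#' @slot kind One of "NH", "flat_loss", "sloping_loss".
#' @export
setClass("AudiometricProfile", representation(
  frequenciesHz = "numeric", thresholdsDbHl = "numeric", kind = "character"))

setValidity("AudiometricProfile", function(object) {
  if (length(object@frequenciesHz) != length(object@thresholdsDbHl))
    return("frequencies and thresholds must have equal length")
  if (!all(is.finite(object@thresholdsDbHl)) || any(object@thresholdsDbHl < 0))
    return("thresholds must be finite and >= 0 dB HL")
  if (!object@kind %in% c("NH", "flat_loss", "sloping_loss"))
    return("kind must be NH, flat_loss or sloping_loss")
  if (object@kind == "NH" && any(object@thresholdsDbHl != 0))
    return("NH profile must have all thresholds at 0 dB HL")
  TRUE
})

#' A logarithmic characteristic-frequency grid
#'
#' @slot cfs Strictly increasing centre frequencies in Hz, log-spaced.
#' @export
setClass("CFGrid", representation(cfs = "numeric"))

setValidity("CFGrid", function(object) {
  if (length(object@cfs) < 2L) return("need at least 2 CFs")
  if (any(diff(object@cfs) <= 0)) return("cfs must be strictly increasing")
  TRUE
})

#' A modelled cochlear state
#'
#' One row of the simulation design: an audiometric profile translated into
#' per-CF outer/inner hair cell health, an MOCR gain setting, and an
#' auditory-nerve-fiber distribution over [low, medium, high] spontaneous-rate
#' classes.
#'
#' @slot id Human-readable state identifier.
#' @slot audiogram An [AudiometricProfile-class].
#' @slot mocrGainDb MOCR efferent gain in dB (0 = reflex absent, 20 = healthy).
#' @slot fiberCounts Integer vector [low, medium, high] fibers per CF.
#' @slot cohc Per-CF outer-hair-cell health in [0, 1].
#' @slot cihc Per-CF inner-hair-cell health in [0, 1].
#' @slot mocrMax Per-CF maximum fractional OHC-gain reduction in [0, 1].
#' @slot cfGrid The [CFGrid-class] the health vectors are defined on.
#' @seealso [cochlearState()], [table1States()]
#' @export
setClass("CochlearState", representation(
  id = "character", audiogram = "AudiometricProfile", mocrGainDb = "numeric",
  fiberCounts = "numeric", cohc = "numeric", cihc = "numeric",
  mocrMax = "numeric", cfGrid = "CFGrid"))

setValidity("CochlearState", function(object) {
  n <- length(object@cfGrid@cfs)
  if (length(object@cohc) != n || length(object@cihc) != n || length(object@mocrMax) != n)
    return("cohc, cihc and mocrMax must match the CF grid length")
  if (any(object@cohc < 0 | object@cohc > 1)) return("cohc must lie in [0,1]")
  if (any(object@cihc < 0 | object@cihc > 1)) return("cihc must lie in [0,1]")
  if (any(object@mocrMax < 0 | object@mocrMax > 1)) return("mocrMax must lie in [0,1]")
  if (length(object@fiberCounts) != 3L || any(object@fiberCounts < 0))
    return("fiberCounts must be [low, medium, high] nonnegative counts")
  if (sum(object@fiberCounts) > 100) return("total fibers per CF must be <= 100")
  if (!object@mocrGainDb %in% c(0, 20)) return("mocrGainDb must be 0 or 20")
  if (object@audiogram@kind == "NH" &&
      (any(object@cohc != 1) || any(object@cihc != 1)))
    return("NH audiogram requires cohc = cihc = 1 everywhere")
  TRUE
})

#' A population neurogram
#'
#' CF-by-time-frame matrix of binned auditory-nerve population spike counts;
#' after [finalizeNeurogram()] the matrix is trimmed to 70 frames (700 ms at
#' 100 Hz) and z-scored over all cells.
#'
#' @slot values CF x frame numeric matrix.
#' @slot cfGrid The [CFGrid-class].
#' @slot frameRate Frame rate in Hz (100 in all presets).
#' @slot normalized TRUE once z-scored.
#' @slot degenerate TRUE when the raw matrix was constant (sd 0).
#' @slot metadata List: digit, talkerId, snrDb, stateId, seed, baselineMean.
#' @export
setClass("Neurogram", representation(
  values = "matrix", cfGrid = "CFGrid", frameRate = "numeric",
  normalized = "logical", degenerate = "logical", metadata = "list"))

setValidity("Neurogram", function(object) {
  if (nrow(object@values) != length(object@cfGrid@cfs))
    return("rows of values must match the CF grid")
  if (!object@normalized) {
    v <- object@values
    if (any(v < 0) || any(abs(v - round(v)) > 1e-9))
      return("un-normalized neurogram values must be nonnegative integers")
  } else if (!object@degenerate) {
    if (abs(mean(object@values)) > 1e-6) return("normalized neurogram mean must be ~0")
    if (abs(stats::sd(as.vector(object@values)) - 1) > 1e-6)
      return("normalized neurogram sd must be ~1")
    if (ncol(object@values) != 70L) return("finalized neurogram must have 70 frames")
  }
  TRUE
})

#' A batch of aligned finalized neurograms
#'
#' @slot values Array (nCF, nFrames, n) of finalized neurograms.
#' @slot meta data.frame with one row per neurogram (digit, talker_id, snr_db,
#'   state_id, row seed).
#' @slot cfGrid The [CFGrid-class].
#' @slot frameRate Frame rate in Hz.
#' @export
setClass("NeurogramSet", representation(
  values = "array", meta = "data.frame", cfGrid = "CFGrid", frameRate = "numeric"))

setValidity("NeurogramSet", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array")
  if (d[3] != nrow(object@meta)) return("meta rows must match array depth")
  if (d[1] != length(object@cfGrid@cfs)) return("array rows must match CF grid")
  TRUE
})

#' A fitted psychometric sigmoid
#'
#' f(x) = floor + span / (1 + exp(-a (x - b))) with the floor/span pair fixed
#' by variant: human (0.1, 0.9) or model (0.09, 0.88).
#'
#' @slot a Slope parameter (1/dB), constrained positive.
#' @slot b Inflection point (dB SNR).
#' @slot floor Lower asymptote.
#' @slot span Range above the floor.
#' @slot variant "human" or "model".
#' @slot residual Sum of squared fit residuals.
#' @seealso [fitSigmoid()], [snrAtAccuracy()]
#' @export
setClass("SigmoidFit", representation(
  a = "numeric", b = "numeric", floor = "numeric", span = "numeric",
  variant = "character", residual = "numeric"))

setValidity("SigmoidFit", function(object) {
  if (object@a <= 0) return("slope a must be positive")
  if (!object@variant %in% c("human", "model")) return("variant must be human or model")
  TRUE
})

#' A psychometric accuracy-versus-SNR curve
#'
#' @slot snrDb Strictly increasing SNR grid (dB).
#' @slot accuracy Mean proportion correct in [0, 1] per SNR.
#' @slot sem Standard error of the mean across folds (or subjects).
#' @slot n Number of folds/subjects contributing.
#' @export
setClass("PsychometricCurve", representation(
  snrDb = "numeric", accuracy = "numeric", sem = "numeric", n = "integer"))

setValidity("PsychometricCurve", function(object) {
  if (any(diff(object@snrDb) <= 0)) return("snrDb grid must be strictly increasing")
  if (length(object@accuracy) != length(object@snrDb))
    return("accuracy must match the SNR grid")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    return("accuracy must lie in [0, 1]")
  TRUE
})

#' A talker-disjoint train/validation/test split
#'
#' @slot foldId Integer fold index (0-based as reported).
#' @slot trainTalkers,valTalkers,testTalkers Disjoint talker id sets.
#' @slot fractions Target fractions (train, val, test).
#' @slot seed Seed the permutation derives from.
#' @seealso [makeFolds()]
#' @export
setClass("FoldSplit", representation(
  foldId = "integer", trainTalkers = "integer", valTalkers = "integer",
  testTalkers = "integer", fractions = "numeric", seed = "integer"))

setValidity("FoldSplit", function(object) {
  sets <- list(object@trainTalkers, object@valTalkers, object@testTalkers)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) return("train/val/test talker sets must be disjoint")
  if (length(object@trainTalkers) == 0L || length(object@testTalkers) == 0L)
    return("train and test sets must be non-empty")
  if (abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
  TRUE
})

#' A phase-2 training paradigm
#'
#' @slot name "nh_control", "unconstrained" or "constrained".
#' @slot phase2Source "NH" or "degraded": neurogram source for phase 2.
#' @slot maskType "all" or "f5": which parameter tensors may adapt.
#' @export
setClass("Paradigm", representation(
  name = "character", phase2Source = "character", maskType = "character"))

setValidity("Paradigm", function(object) {
  ok <- switch(object@name,
    nh_control    = object@phase2Source == "NH" && object@maskType == "all",
    unconstrained = object@phase2Source == "degraded" && object@maskType == "all",
    constrained   = object@phase2Source == "degraded" && object@maskType == "f5",
    return("name must be nh_control, unconstrained or constrained"))
  if (!ok) return("phase2Source/maskType inconsistent with paradigm name")
  TRUE
})

#' A per-tensor normalized mean parameter difference report
#'
#' For each of the 20 parameter tensors, mean(|(P_i - mu_B) / sigma_B|) against
#' the baseline network; frozen tensors report exactly 0. Tensors whose
#' baseline standard deviation is zero are flagged undefined rather than
#' silently reported as 0.
#'
#' @slot table data.frame: tensor, layer, kind, value, baselineMean,
#'   baselineSd, undefined.
#' @slot step Training-step stamp of the compared network.
#' @seealso [layerChange()]
#' @export
setClass("LayerChangeReport", representation(table = "data.frame", step = "integer"))

setValidity("LayerChangeReport", function(object) {
  t <- object@table
  need <- c("tensor", "layer", "kind", "value", "baselineMean", "baselineSd", "undefined")
  if (!all(need %in% names(t))) return("report table missing columns")
  if (any(t$value[!t$undefined] < 0)) return("normalized mean differences must be >= 0")
  TRUE
})
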