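# Accessors and show methods.

#' @rdname dinoise-generics
setMethod("samples", "Waveform", function(x) x@samples)
#' @rdname dinoise-generics
setMethod("sampleRate", "Waveform", function(x) x@sampleRate)

#' @rdname dinoise-generics
setMethod("digitLabel", "DigitToken", function(x) x@digit)
#' @rdname dinoise-generics
setMethod("digitLabel", "NoisyStimulus", function(x) x@digit)
#' @rdname dinoise-generics
setMethod("talkerId", "DigitToken", function(x) x@talkerId)
#' @rdname dinoise-generics
setMethod("talkerId", "NoisyStimulus", function(x) x@talkerId)
#' @rdname dinoise-generics
setMethod("snrDb", "NoisyStimulus", function(x) x@snrDb)

#' @rdname dinoise-generics
setMethod("cfs", "CFGrid", function(x) x@cfs)
#' @rdname dinoise-generics
setMethod("cfs", "CochlearState", function(x) x@cfGrid@cfs)
#' @rdname dinoise-generics
setMethod("cfs", "Neurogram", function(x) x@cfGrid@cfs)
#' @rdname dinoise-generics
setMethod("cfs", "NeurogramSet", function(x) x@cfGrid@cfs)

#' @rdname dinoise-generics
setMethod("frameRate", "Neurogram", function(x) x@frameRate)
#' @rdname dinoise-generics
setMethod("frameRate", "NeurogramSet", function(x) x@frameRate)

#' @rdname dinoise-generics
setMethod("values", "Neurogram", function(x) x@values)
#' @rdname dinoise-generics
setMethod("values", "NeurogramSet", function(x) x@values)

#' @rdname dinoise-generics
setMethod("isNormalized", "Neurogram", function(x) x@normalized)
#' @rdname dinoise-generics
setMethod("isDegenerate", "Neurogram", function(x) x@degenerate)
#' @rdname dinoise-generics
setMethod("metadata", "Neurogram", function(x) x@metadata)
#' @rdname dinoise-generics
setMethod("metadata", "NeurogramSet", function(x) x@meta)
#' @rdname dinoise-generics
setMethod("stateId", "CochlearState", function(x) x@id)

setMethod("show", "DigitToken", function(object) {
  cat(sprintf("DigitToken: digit %d, talker %d, %.1f dB SPL, %.0f ms @ %g Hz\n",
    object@digit, object@talkerId, object@levelDbSpl,
    1000 * length(object@samples) / object@sampleRate, object@sampleRate))
})

setMethod("show", "NoisyStimulus", function(object) {
  cat(sprintf(
    "NoisyStimulus: digit %d, talker %d, speech %.1f dB SPL, noise %s dB SPL (SNR %s dB)\n",
    object@digit, object@talkerId, object@speechLevelDbSpl,
    format(object@noiseLevelDbSpl), format(object@snrDb)))
})

setMethod("show", "CFGrid", function(object) {
  cat(sprintf("CFGrid: %d log-spaced CFs, %.0f-%.0f Hz\n",
    length(object@cfs), min(object@cfs), max(object@cfs)))
})

setMethod("show", "CochlearState", function(object) {
  cat(sprintf(
    "CochlearState '%s': audiogram %s, MOCR gain %g dB, fibers [%s]/CF, %d CFs\n",
    object@id, object@audiogram@kind, object@mocrGainDb,
    paste(object@fiberCounts, collapse = ","), length(object@cfGrid@cfs)))
})

setMethod("show", "Neurogram", function(object) {
  cat(sprintf("Neurogram: %d CFs x %d frames @ %g Hz, %s%s\n",
    nrow(object@values), ncol(object@values), object@frameRate,
    if (object@normalized) "z-scored" else "spike counts",
    if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "NeurogramSet", function(object) {
  cat(sprintf("NeurogramSet: %d neurograms, %d CFs x %d frames @ %g Hz\n",
    dim(object@values)[3], dim(object@values)[1], dim(object@values)[2],
    object@frameRate))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit (%s): f(x) = %.2f + %.2f/(1+exp(-%.4g (x - %.4g))), rss %.3g\n",
    object@variant, object@floor, object@span, object@a, object@b, object@residual))
})

setMethod("show", "PsychometricCurve", function(object) {
  cat(sprintf("PsychometricCurve: %d SNRs in [%g, %g] dB, accuracy %.2f-%.2f (n=%d)\n",
    length(object@snrDb), min(object@snrDb), max(object@snrDb),
    min(object@accuracy), max(object@accuracy), object@n))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit %d: %d/%d/%d talkers (train/val/test)\n", object@foldId,
    length(object@trainTalkers), length(object@valTalkers), length(object@testTalkers)))
})

setMethod("show", "Paradigm", function(object) {
  cat(sprintf("Paradigm '%s': phase-2 source %s, trainable %s\n",
    object@name, object@phase2Source,
    if (object@maskType == "all") "all tensors" else "F5 weight+bias only"))
})

setMethod("show", "LayerChangeReport", function(object) {
  cat(sprintf("LayerChangeReport @ step %d\n", object@step))
  print(object@table[, c("tensor", "value", "undefined")], row.names = FALSE)
})
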