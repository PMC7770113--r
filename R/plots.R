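# Base-graphics displays for the two objects people look at most.

#' Plot a psychometric curve
#'
#' Mean accuracy versus SNR with fold-SEM error bars, chance level, and an
#' optional fitted sigmoid overlay.
#'
#' @param x A [PsychometricCurve-class].
#' @param y Optional [SigmoidFit-class] to overlay.
#' @param chance Chance level (0.1 for ten alternatives).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
setMethod("plot", signature(x = "PsychometricCurve", y = "ANY"),
  function(x, y = NULL, chance = 0.1, ...) {
    graphics::plot(x@snrDb, x@accuracy, type = "b", pch = 19, ylim = c(0, 1),
                   xlab = "SNR (dB)", ylab = "proportion correct", ...)
    if (any(x@sem > 0))
      graphics::arrows(x@snrDb, x@accuracy - x@sem, x@snrDb, x@accuracy + x@sem,
                       angle = 90, code = 3, length = 0.03)
    graphics::abline(h = chance, lty = 3)
    if (!is.null(y) && methods::is(y, "SigmoidFit")) {
      xx <- seq(min(x@snrDb), max(x@snrDb), length.out = 200)
      graphics::lines(xx, predictSigmoid(y, xx), col = "steelblue", lwd = 2)
    }
    invisible(x)
  })

#' Display a neurogram as an image
#'
#' Time on the x axis (frames at the neurogram frame rate), CF channels on a
#' logarithmic y axis.
#'
#' @param x A [Neurogram-class].
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
setMethod("plot", signature(x = "Neurogram", y = "ANY"), function(x, ...) {
  tt <- (seq_len(ncol(x@values)) - 0.5) / x@frameRate
  graphics::image(tt, log10(x@cfGrid@cfs), t(x@values),
                  xlab = "time (s)", ylab = "CF (log10 Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
})
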