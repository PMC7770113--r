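# Independent oracles used by the tests; these deliberately avoid the
# package's own signal path.

# Plain STFT magnitude spectrogram via base fft (Hann window).
oracleSpectrogram <- function(x, fs, winS = 0.02, hopS = 0.01) {
  n <- round(winS * fs); hop <- round(hopS * fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  starts <- seq(1, length(x) - n + 1, by = hop)
  out <- vapply(starts, function(s) {
    Mod(stats::fft(x[s:(s + n - 1)] * w))[1:(n %/% 2)]
  }, numeric(n %/% 2))
  out
}

# Pad/crop spectrograms to a common size and correlate as vectors.
oracleSpecCor <- function(a, b) {
  nc <- min(ncol(a), ncol(b))
  stats::cor(as.vector(a[, 1:nc]), as.vector(b[, 1:nc]))
}

# Nearest-template digit classifier on normalized spectrograms.
oracleNearestTemplate <- function(tokens, templates) {
  tmplSpecs <- lapply(templates, function(t)
    oracleSpectrogram(dinoise::samples(t), dinoise::sampleRate(t)))
  vapply(tokens, function(tok) {
    sp <- oracleSpectrogram(dinoise::samples(tok), dinoise::sampleRate(tok))
    sims <- vapply(tmplSpecs, function(ts) oracleSpecCor(ts, sp), numeric(1))
    which.max(sims) - 1L
  }, integer(1))
}
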