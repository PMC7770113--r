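# Reference-based neurogram intelligibility metrics.
#
# NSIM is an SSIM-style local comparison of intensity and structure over 3x3
# Gaussian-weighted windows; STMI compares spectro-temporal modulation energy
# (rate 2-32 Hz, scale 0.25-8 cyc/oct) between a clean template and a
# degraded neurogram. Both operate on un-normalized count neurograms and
# return values on a 0-1 scale. They are annotations, not predictions of
# absolute human intelligibility.

# 2-D "valid" convolution of m with a 3x3 kernel w via shift-and-sum.
conv3x3 <- function(m, w) {
  H <- nrow(m) - 2L; W <- ncol(m) - 2L
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3)
    out <- out + w[i, j] * m[i:(i + H - 1L), j:(j + W - 1L)]
  out
}

gauss3x3 <- function(sigma = 0.5) {
  d <- (-1):1
  w <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  w / sum(w)
}

checkMetricInputs <- function(reference, degraded) {
  stopifnot(methods::is(reference, "Neurogram"), methods::is(degraded, "Neurogram"))
  if (!all(dim(reference@values) == dim(degraded@values)))
    stop("reference and degraded neurograms must have identical shape")
  if (!isTRUE(all.equal(reference@cfGrid@cfs, degraded@cfGrid@cfs)))
    stop("reference and degraded neurograms must share the CF grid")
  if (reference@normalized || degraded@normalized)
    stop("metrics operate on un-normalized count neurograms")
}

#' Neurogram similarity metric (NSIM)
#'
#' Mean over all 3x3 Gaussian-weighted (sigma 0.5) local windows of the
#' product of intensity and structure components,
#' l = (2 mu_r mu_d + C1) / (mu_r^2 + mu_d^2 + C1) and
#' s = (sigma_rd + C3) / (sigma_r sigma_d + C3), with C1 = (0.01 L)^2 and
#' C3 = (0.03 L)^2 / 2 where L is the reference dynamic range (stabilized for
#' constant references so equal constant inputs score 1).
#'
#' @param reference Clean reference [Neurogram-class] (un-normalized counts).
#' @param degraded Degraded [Neurogram-class], same shape and CF grid.
#' @return List: `name` ("NSIM"), `value` in [0, 1], `referenceId`,
#'   `degradedId`.
#' @export
nsim <- function(reference, degraded) {
  checkMetricInputs(reference, degraded)
  r <- reference@values; d <- degraded@values
  L <- diff(range(r))
  C1 <- max((0.01 * L)^2, 1e-8)
  C3 <- max((0.03 * L)^2 / 2, 1e-8)
  w <- gauss3x3(0.5)
  muR <- conv3x3(r, w); muD <- conv3x3(d, w)
  sigR2 <- pmax(conv3x3(r * r, w) - muR^2, 0)
  sigD2 <- pmax(conv3x3(d * d, w) - muD^2, 0)
  sigRD <- conv3x3(r * d, w) - muR * muD
  l <- (2 * muR * muD + C1) / (muR^2 + muD^2 + C1)
  s <- (sigRD + C3) / (sqrt(sigR2 * sigD2) + C3)
  val <- mean(l * s)
  list(name = "NSIM", value = min(1, max(0, val)),
       referenceId = reference@metadata$stateId, degradedId = degraded@metadata$stateId)
}

# Spectro-temporal modulation energy: 2-D Fourier magnitude-squared of the
# Hann-windowed neurogram, restricted to the rate/scale passband.
modulationEnergy <- function(ng, rateBandHz = c(2, 32), scaleBandCpo = c(0.25, 8)) {
  m <- ng@values
  nF <- ncol(m); nC <- nrow(m)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  mw <- m * outer(hann(nC), hann(nF))
  M <- stats::mvfft(t(stats::mvfft(t(mw))))
  rate <- ng@frameRate * (seq_len(nF) - 1) / nF
  rate <- pmin(rate, ng@frameRate - rate)               # two-sided |frequency|
  chanPerOct <- nC / log2(max(ng@cfGrid@cfs) / min(ng@cfGrid@cfs))
  scale <- chanPerOct * (seq_len(nC) - 1) / nC
  scale <- pmin(scale, chanPerOct - scale)
  keep <- outer(scale >= scaleBandCpo[1] & scale <= scaleBandCpo[2],
                rate >= rateBandHz[1] & rate <= rateBandHz[2])
  e <- Mod(M)^2
  e[!keep] <- 0
  e
}

#' Spectro-temporal modulation index (STMI)
#'
#' Projects both neurograms onto a spectro-temporal modulation energy
#' representation (windowed 2-D Fourier magnitude, rate band 2-32 Hz, scale
#' band 0.25-8 cyc/oct) and returns 1 - ||T - N||^2 / ||T||^2 with T the
#' reference energy, clamped to [0, 1]. An all-zero reference is rejected
#' (the normalization is undefined).
#'
#' @inheritParams nsim
#' @return List: `name` ("STMI"), `value` in [0, 1], `referenceId`,
#'   `degradedId`.
#' @export
stmi <- function(reference, degraded) {
  checkMetricInputs(reference, degraded)
  Tm <- modulationEnergy(reference)
  if (sum(Tm) == 0) stop("all-zero reference neurogram: STMI undefined")
  Nm <- modulationEnergy(degraded)
  val <- 1 - sum((Tm - Nm)^2) / sum(Tm^2)
  list(name = "STMI", value = min(1, max(0, val)),
       referenceId = reference@metadata$stateId, degradedId = degraded@metadata$stateId)
}
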