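# Phenomenological auditory periphery.
#
# The stimulus is passed through an ERB-bandwidth Butterworth filterbank on a
# logarithmic CF grid; band envelopes drive (i) the medial olivocochlear
# reflex, which reduces effective outer-hair-cell health in its sensitive
# band with asymmetric onset/offset kinetics, and (ii) per-class
# spontaneous-rate fiber rate functions after OHC/IHC attenuation in the dB
# domain. Spikes are drawn as Poisson counts per 10 ms frame (the count of a
# sum of independent Poisson fiber processes equals a Poisson count at the
# summed rate, so the population draw is exact in distribution).
#
# Health fractions map linearly to attenuation: a component health c in [0,1]
# costs (1 - c) * 105 dB of drive, so an audiogram fitted with the 2/3 OHC /
# 1/3 IHC attribution reproduces its threshold shifts exactly.

COMPONENT_LOSS_DB <- 105   # dB of attenuation at health 0, per component
PERIPHERY_FS <- 24000      # internal processing rate, Hz
ENVELOPE_RATE <- 1000      # envelope/rate sampling rate, Hz

# MOCR kinetics and drive nonlinearity
MOCR_ONSET_TAU <- 0.060    # s
MOCR_OFFSET_TAU <- 0.200   # s
MOCR_DRIVE_HALF <- 0.02    # Pa (~60 dB SPL) half-saturation of sigma(d)
MOCR_BAND_HZ <- c(1000, 4000)

#' Construct a logarithmic CF grid
#'
#' @param n Number of CFs (128 in the paper preset, 32 in the desk preset).
#' @param lowHz,highHz Frequency range endpoints in Hz.
#' @return A [CFGrid-class].
#' @export
cfGrid <- function(n = 128L, lowHz = 100, highHz = 8000) {
  methods::new("CFGrid", cfs = exp(seq(log(lowHz), log(highHz), length.out = n)))
}

#' Construct an audiometric profile
#'
#' The three modelled profiles: "NH" (0 dB HL everywhere), "flat_loss"
#' (constant threshold shift, default 30 dB HL), and "sloping_loss"
#' (high-frequency shift rising to 55 dB HL at 8 kHz).
#'
#' @param kind One of "NH", "flat_loss", "sloping_loss".
#' @param flatDbHl Threshold used by the flat profile.
#' @param thresholdsDbHl Optional explicit 7-point threshold vector at
#'   [0.125, 0.25, 0.5, 1, 2, 4, 8] kHz overriding the named presets.
#' @return An [AudiometricProfile-class].
#' @export
audiometricProfile <- function(kind = c("NH", "flat_loss", "sloping_loss"),
                               flatDbHl = 30, thresholdsDbHl = NULL) {
  kind <- match.arg(kind)
  freqs <- c(125, 250, 500, 1000, 2000, 4000, 8000)
  thr <- if (!is.null(thresholdsDbHl)) thresholdsDbHl
    else switch(kind,
      NH = rep(0, 7),
      flat_loss = rep(flatDbHl, 7),
      sloping_loss = c(0, 0, 0, 10, 25, 40, 55))
  methods::new("AudiometricProfile", frequenciesHz = freqs,
               thresholdsDbHl = thr, kind = kind)
}

#' Greenwood cochlear place-frequency map
#'
#' F = A (10^(a x) - k) with human constants A = 165.4, a = 2.1, k = 0.88;
#' x is the fractional distance from apex (0) to base (1).
#'
#' @param x Fractional cochlear position in [0, 1].
#' @return Frequency in Hz.
#' @export
greenwoodMap <- function(x) {
  if (any(x < 0 | x > 1)) stop("cochlear position x must lie in [0, 1]")
  165.4 * (10^(2.1 * x) - 0.88)
}

#' @rdname greenwoodMap
#' @param frequencyHz Frequency in Hz.
#' @return Fractional cochlear position in [0, 1]; exact inverse of
#'   [greenwoodMap()].
#' @export
greenwoodInverse <- function(frequencyHz) {
  x <- log10(frequencyHz / 165.4 + 0.88) / 2.1
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("frequency outside the Greenwood range")
  pmin(1, pmax(0, x))
}

#' Fit an audiogram to per-CF hair-cell health
#'
#' Interpolates the 7-point thresholds (linear in log frequency) onto the CF
#' grid, attributes 2/3 of each threshold shift to OHC loss and 1/3 to IHC
#' loss, and maps each attributed shift linearly in dB onto health in [1, 0]
#' over [0, 105] dB of maximal component loss. Health is monotonically
#' non-increasing in threshold shift; shifts beyond the expressible maximum
#' clamp to health 0 with a warning.
#'
#' @param profile An [AudiometricProfile-class].
#' @param grid A [CFGrid-class].
#' @return List with numeric vectors `cohc` and `cihc` over the grid.
#' @export
fitAudiogram <- function(profile, grid) {
  thr <- stats::approx(log(profile@frequenciesHz), profile@thresholdsDbHl,
                       xout = log(grid@cfs), rule = 2)$y
  shiftOhc <- (2 / 3) * thr
  shiftIhc <- (1 / 3) * thr
  if (any(shiftOhc > COMPONENT_LOSS_DB) || any(shiftIhc > COMPONENT_LOSS_DB))
    warning("threshold shift exceeds the maximum expressible loss; clamping health to 0")
  list(cohc = pmax(0, 1 - shiftOhc / COMPONENT_LOSS_DB),
       cihc = pmax(0, 1 - shiftIhc / COMPONENT_LOSS_DB))
}

#' Construct a cochlear state
#'
#' Combines an audiometric profile (fitted to per-CF OHC/IHC health), an MOCR
#' gain setting, and a fiber distribution. The per-CF maximum fractional MOCR
#' gain reduction is chosen so the steady-state reduction equals the MOCR
#' gain in dB (capped by the OHC gain available at that CF), and is nonzero
#' only inside the MOCR-sensitive band (1-4 kHz, positioned via the Greenwood
#' map).
#'
#' @param audiogram An [AudiometricProfile-class].
#' @param mocrGainDb 0 (reflex absent) or 20 (healthy reflex) dB.
#' @param fiberCounts [low, medium, high] spontaneous-rate fibers per CF.
#' @param grid A [CFGrid-class].
#' @param id State identifier; autogenerated when NULL.
#' @return A [CochlearState-class].
#' @export
cochlearState <- function(audiogram, mocrGainDb, fiberCounts, grid, id = NULL) {
  fit <- fitAudiogram(audiogram, grid)
  xs <- greenwoodInverse(grid@cfs)
  inBand <- xs >= greenwoodInverse(MOCR_BAND_HZ[1]) &
            xs <= greenwoodInverse(MOCR_BAND_HZ[2])
  mocrMax <- ifelse(inBand & fit$cohc > 0 & mocrGainDb > 0,
                    pmin(1, mocrGainDb / (COMPONENT_LOSS_DB * fit$cohc)), 0)
  if (is.null(id))
    id <- sprintf("%s_mocr%g_anf[%s]", audiogram@kind, mocrGainDb,
                  paste(fiberCounts, collapse = ","))
  methods::new("CochlearState", id = id, audiogram = audiogram,
               mocrGainDb = mocrGainDb, fiberCounts = as.numeric(fiberCounts),
               cohc = fit$cohc, cihc = fit$cihc, mocrMax = mocrMax, cfGrid = grid)
}

#' The 12 modelled cochlear states
#'
#' The full factorial of three audiometric profiles, two MOCR gains (20/0 dB)
#' and two fiber distributions ([20,20,60] healthy, [0,0,52] degraded). With
#' `fiberScale` < 1 the fiber distributions are scaled and rounded for
#' desk-scale work ([2,2,6] and [0,0,5] at 0.1).
#'
#' @param grid A [CFGrid-class].
#' @param fiberScale Multiplier applied to the fiber distributions.
#' @return Named list of 12 [CochlearState-class] objects.
#' @export
table1States <- function(grid, fiberScale = 1) {
  out <- list()
  for (kind in c("NH", "flat_loss", "sloping_loss")) {
    prof <- audiometricProfile(kind)
    for (gain in c(20, 0)) {
      for (fib in list(c(20, 20, 60), c(0, 0, 52))) {
        st <- cochlearState(prof, gain, pmax(round(fib * fiberScale),
                                             ifelse(fib > 0, 1, 0)), grid)
        out[[st@id]] <- st
      }
    }
  }
  out
}

#' Spontaneous-rate class parameters
#'
#' Configuration (not constants) for the three ANF classes, ordered
#' [low, medium, high] spontaneous rate. Low-SR fibers have the highest
#' threshold and widest primary dynamic range; high-SR the lowest threshold
#' and narrowest primary dynamic range. Each rate-level function carries a
#' second, shallow "sloping saturation" limb (most pronounced in high-SR
#' fibers) that extends differential level sensitivity to conversational
#' levels; without it the population response pegs at the saturation rate
#' for any stimulus above a few tens of dB SPL and the neurogram loses all
#' spectral contrast at speech levels.
#'
#' @param spontRates Spontaneous rates, spikes/s.
#' @param thresholdDbSpl Absolute rate thresholds in dB SPL.
#' @param dynamicRangeDb Primary dynamic range of the rate-level function, dB.
#' @param saturationRate Saturated driven rate, spikes/s.
#' @param slopeFraction Fraction of the driven range carried by the sloping
#'   limb, per class.
#' @param slopeOffsetDb Offset of the sloping limb above threshold, dB.
#' @param slopeRangeDb Dynamic range of the sloping limb, dB.
#' @return List of class parameters.
#' @export
srClassParams <- function(spontRates = c(0.1, 5, 60),
                          thresholdDbSpl = 5 + c(30, 18, 0),
                          dynamicRangeDb = c(40, 30, 20),
                          saturationRate = 250,
                          slopeFraction = c(0.20, 0.30, 0.45),
                          slopeOffsetDb = c(25, 22, 20),
                          slopeRangeDb = c(110, 100, 95)) {
  list(spontRates = spontRates, thresholdDbSpl = thresholdDbSpl,
       dynamicRangeDb = dynamicRangeDb, saturationRate = saturationRate,
       slopeFraction = slopeFraction, slopeOffsetDb = slopeOffsetDb,
       slopeRangeDb = slopeRangeDb)
  }

# ERB bandwidth (Glasberg & Moore) in Hz at centre frequency f.
erbHz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Prepare filterbank coefficients for a CF grid
#'
#' Precomputes the band-pass (2nd-order Butterworth, ERB bandwidth) and
#' envelope low-pass coefficients so repeated neurogram generation does not
#' re-design filters.
#'
#' @param grid A [CFGrid-class].
#' @param fsInternal Internal processing rate in Hz.
#' @return An opaque list consumed by [simulateFiberRates()].
#' @export
preparePeriphery <- function(grid, fsInternal = PERIPHERY_FS) {
  if (fsInternal < 2 * max(grid@cfs))
    stop("internal rate below 2x the maximum CF")
  band <- lapply(grid@cfs, function(cf) {
    bw <- erbHz(cf)
    lo <- max(cf - bw / 2, 1)
    hi <- min(cf + bw / 2, 0.98 * fsInternal / 2)
    bf <- signal::butter(2, c(lo, hi) / (fsInternal / 2), type = "pass")
    list(b = bf$b, a = bf$a)
  })
  list(grid = grid, fsInternal = fsInternal, band = band)
}

# Apply an IIR filter given (b, a) with zero initial conditions.
applyArma <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1), x), b, method = "convolution", sides = 1)
  v <- v[nb:length(v)]
  as.numeric(stats::filter(v / a[1], -a[-1] / a[1], method = "recursive"))
}

# Resample x from fs to target using a polyphase FIR (signal::resample).
resampleTo <- function(x, fs, target) {
  if (fs == target) return(x)
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(target, fs)
  as.numeric(signal::resample(x, target / d, fs / d))
}

#' Time-varying effective OHC health under the MOCR
#'
#' Within the MOCR-sensitive band, cohc(t) = cohc_static * (1 - mocrMax *
#' s(t)) where s(t) is the saturating drive sigma(d) = d / (d + d_half)
#' smoothed with asymmetric onset (60 ms) and offset (200 ms) time constants.
#' Outside the band, and whenever the MOCR gain is 0 dB, cohc(t) equals the
#' static value.
#'
#' @param driveEnv nCF x nT matrix of nonnegative band envelope drive (Pa
#'   equivalent) at `envRate`.
#' @param state A [CochlearState-class].
#' @param envRate Envelope sampling rate in Hz.
#' @return nCF x nT matrix of effective cohc values.
#' @export
mocrEffectiveCohc <- function(driveEnv, state, envRate = ENVELOPE_RATE) {
  if (any(driveEnv < 0)) stop("drive envelope must be nonnegative")
  nT <- ncol(driveEnv)
  if (all(state@mocrMax == 0))
    return(matrix(state@cohc, nrow(driveEnv), nT))
  sig <- driveEnv / (driveEnv + MOCR_DRIVE_HALF)
  aOn <- 1 - exp(-1 / (MOCR_ONSET_TAU * envRate))
  aOff <- 1 - exp(-1 / (MOCR_OFFSET_TAU * envRate))
  s <- matrix(0, nrow(driveEnv), nT)
  prev <- rep(0, nrow(driveEnv))
  for (t in seq_len(nT)) {
    st <- sig[, t]
    a <- aOff + (aOn - aOff) * (st > prev)
    prev <- prev + a * (st - prev)
    s[, t] <- prev
  }
  state@cohc * (1 - state@mocrMax * s)
}

#' Simulate per-CF, per-class instantaneous firing rates
#'
#' Band-pass filtering with ERB bandwidths, envelope extraction, MOCR gain
#' control, dB-domain OHC/IHC attenuation, and logistic spontaneous-rate-class
#' rate-level functions. Rates are bounded between the class spontaneous rate
#' and the saturation rate.
#'
#' @param stimulus A [NoisyStimulus-class] (calibrated in dB SPL).
#' @param state A [CochlearState-class].
#' @param prepared Output of [preparePeriphery()] for the state's CF grid
#'   (built on the fly when NULL).
#' @param srParams Class parameters from [srClassParams()].
#' @return List: `rates` array (nCF, nT, 3 classes) in spikes/s at `envRate`
#'   Hz, `cohcEff` the effective OHC health matrix, `envelope` the band
#'   envelope matrix.
#' @export
simulateFiberRates <- function(stimulus, state, prepared = NULL,
                               srParams = srClassParams()) {
  grid <- state@cfGrid
  if (stimulus@sampleRate < 2 * max(grid@cfs))
    stop("stimulus sample rate below 2x the maximum CF")
  if (is.null(prepared)) prepared <- preparePeriphery(grid)
  fsI <- prepared$fsInternal
  x <- resampleTo(stimulus@samples, stimulus@sampleRate, fsI)
  dec <- fsI / ENVELOPE_RATE
  stopifnot(dec == round(dec))
  nCF <- length(grid@cfs)
  nTe <- length(x) %/% dec
  env <- matrix(0, nCF, nTe)
  scl <- pi / (2 * sqrt(2))                   # rectified-mean -> RMS-equivalent
  for (k in seq_len(nCF)) {
    bandSig <- applyArma(prepared$band[[k]]$b, prepared$band[[k]]$a, x)
    # envelope: rectify and average over each 1-ms block (boxcar + decimate)
    env[k, ] <- colMeans(matrix(abs(bandSig[seq_len(nTe * dec)]), dec)) * scl
  }
  cohcEff <- mocrEffectiveCohc(env, state)
  lvl <- FULL_SCALE_DB_SPL + 20 * log10(pmax(env, 1e-12))
  drive <- lvl - (1 - cohcEff) * COMPONENT_LOSS_DB -
    (1 - state@cihc) * COMPONENT_LOSS_DB
  rates <- array(0, c(nCF, ncol(env), 3))
  for (cl in 1:3) {
    k <- srParams$dynamicRangeDb[cl] / 8
    ks <- srParams$slopeRangeDb[cl] / 8
    f <- srParams$slopeFraction[cl]
    th <- srParams$thresholdDbSpl[cl]
    driven <- (1 - f) * stats::plogis((drive - th) / k) +
      f * stats::plogis((drive - th - srParams$slopeOffsetDb[cl]) / ks)
    rates[, , cl] <- srParams$spontRates[cl] +
      (srParams$saturationRate - srParams$spontRates[cl]) * driven
  }
  list(rates = rates, cohcEff = cohcEff, envelope = env, envRate = ENVELOPE_RATE)
}

#' Generate an un-normalized population neurogram
#'
#' Draws population spike counts per CF in non-overlapping 10 ms frames
#' (100 Hz frame rate): within each frame the class rate is integrated and
#' multiplied by the class fiber count, and the population count is drawn as
#' a Poisson variate (exactly the distribution of summed independent fiber
#' processes). Reproducible given `seed`.
#'
#' @param stimulus A [NoisyStimulus-class].
#' @param state A [CochlearState-class].
#' @param seed Integer seed for the Poisson draws.
#' @param prepared Optional [preparePeriphery()] output.
#' @param srParams Class parameters from [srClassParams()].
#' @param frameRate Frame rate in Hz (100).
#' @return An un-normalized [Neurogram-class] of integer counts.
#' @export
generateNeurogram <- function(stimulus, state, seed = 1L, prepared = NULL,
                              srParams = srClassParams(), frameRate = 100) {
  sim <- simulateFiberRates(stimulus, state, prepared, srParams)
  perFrame <- sim$envRate / frameRate
  stopifnot(perFrame == round(perFrame))
  nCF <- dim(sim$rates)[1]
  nFrames <- floor(dim(sim$rates)[2] / perFrame)
  r <- sim$rates[, seq_len(nFrames * perFrame), , drop = FALSE]
  dim(r) <- c(nCF, perFrame, nFrames, 3)
  frameMean <- colMeans(aperm(r, c(2, 1, 3, 4)))       # (nCF, nFrames, 3)
  lambda <- sweep(frameMean, 3, state@fiberCounts / frameRate, `*`)
  counts <- withSeed(seed, {
    draws <- stats::rpois(length(lambda), lambda)
    dim(draws) <- dim(lambda)
    draws[, , 1] + draws[, , 2] + draws[, , 3]
  })
  dim(counts) <- c(nCF, nFrames)
  baseline <- sum(state@fiberCounts * srParams$spontRates) / frameRate * nCF
  methods::new("Neurogram", values = counts, cfGrid = state@cfGrid,
               frameRate = frameRate, normalized = FALSE, degenerate = FALSE,
               metadata = list(digit = stimulus@digit, talkerId = stimulus@talkerId,
                               snrDb = stimulus@snrDb, stateId = state@id,
                               seed = as.integer(seed), baselineMean = baseline))
}

#' Trim and z-score a raw neurogram
#'
#' Detects stimulus onset (first frame where the 3-frame-smoothed population
#' count exceeds the spontaneous baseline by 3 Poisson standard deviations),
#' trims to exactly 70 frames (700 ms) from onset, zero-padding shorter
#' tokens, then z-scores over all cells (global mean 0, sd 1). A constant raw
#' neurogram yields an all-zero output flagged degenerate.
#'
#' @param raw An un-normalized [Neurogram-class].
#' @param targetFrames Number of output frames (70).
#' @return A normalized [Neurogram-class].
#' @export
finalizeNeurogram <- function(raw, targetFrames = 70L) {
  if (raw@normalized) stop("neurogram is already normalized")
  v <- raw@values
  pop <- colSums(v)
  sm <- movingAverage(pop, 3L)
  base <- raw@metadata$baselineMean
  if (is.null(base)) base <- stats::median(sm)
  onset <- which(sm > base + 3 * sqrt(max(base, 1e-9)))
  onset <- if (length(onset)) onset[1] else 1L
  lastCol <- min(ncol(v), onset + targetFrames - 1L)
  out <- matrix(0, nrow(v), targetFrames)
  out[, seq_len(lastCol - onset + 1L)] <- v[, onset:lastCol]
  s <- stats::sd(as.vector(out))
  degen <- !is.finite(s) || s == 0
  if (!degen) out <- (out - mean(out)) / s else out[] <- 0
  methods::new("Neurogram", values = out, cfGrid = raw@cfGrid,
               frameRate = raw@frameRate, normalized = TRUE, degenerate = degen,
               metadata = c(raw@metadata, list(onsetFrame = onset)))
}

#' A silent stimulus for baseline measurements
#'
#' @param durationS Duration in seconds.
#' @param sampleRate Sampling rate in Hz.
#' @return A [NoisyStimulus-class] of zeros (levels -Inf, SNR undefined).
#' @export
silentStimulus <- function(durationS = 0.5, sampleRate = 16000) {
  methods::new("NoisyStimulus", samples = rep(0, round(durationS * sampleRate)),
               sampleRate = sampleRate, digit = NA_integer_,
               talkerId = NA_integer_, speechLevelDbSpl = -Inf,
               noiseLevelDbSpl = -Inf, snrDb = NaN)
}
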