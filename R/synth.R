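# Synthetic spoken-digit tokens and calibrated digit+noise mixtures.
#
# Each digit has a hand-designed template of 2-3 segments: vowel-like segments
# are additive harmonic complexes shaped by two formant trajectories; the
# consonant-like segments are band-limited noise bursts. A talker profile
# perturbs the fundamental (+-20% across the pool) and rescales all formant
# targets (+-8%), which is the variability the talker-disjoint splits must
# respect.

# Per-digit segment templates. Durations in seconds; formants in Hz at
# formantScale = 1. Total durations all fall inside [0.3, 0.7] s.
digitTemplates <- function() {
  v <- function(dur, f1, f2, amp = 1) list(type = "vowel", dur = dur, f1 = f1, f2 = f2, amp = amp)
  b <- function(dur, lo, hi, amp = 0.35) list(type = "burst", dur = dur, lo = lo, hi = hi, amp = amp)
  list(
    `0` = list(b(0.08, 3500, 6500), v(0.28, c(420, 520), c(1850, 1300))),
    `1` = list(v(0.22, c(480, 700), c(1050, 900)), v(0.14, c(320, 300), c(1050, 1000), amp = 0.7)),
    `2` = list(b(0.06, 2800, 5200), v(0.28, c(360, 330), c(950, 800))),
    `3` = list(b(0.09, 3800, 7000), v(0.26, c(310, 290), c(2250, 2400))),
    `4` = list(b(0.08, 1800, 4500), v(0.30, c(620, 460), c(1000, 820))),
    `5` = list(b(0.07, 2400, 5600), v(0.32, c(760, 420), c(1250, 1900))),
    `6` = list(b(0.09, 4200, 7400), v(0.18, c(350, 340), c(1950, 2050)), b(0.10, 3400, 6600, amp = 0.3)),
    `7` = list(b(0.09, 4200, 7400), v(0.16, c(560, 540), c(1800, 1700)),
               v(0.15, c(520, 480), c(1450, 1350), amp = 0.8)),
    `8` = list(v(0.24, c(460, 360), c(2050, 2350)), b(0.06, 2900, 5100, amp = 0.4)),
    `9` = list(v(0.10, c(320, 340), c(1150, 1200), amp = 0.6), v(0.28, c(700, 420), c(1300, 2000)))
  )
}

rampEnvelope <- function(n, fs, rampS = 0.01) {
  nr <- max(2L, min(n %/% 2L, round(rampS * fs)))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  env[seq_len(nr)] <- up
  env[(n - nr + 1L):n] <- rev(up)
  env
}

synthVowel <- function(seg, f0, formantScale, fs) {
  n <- round(seg$dur * fs)
  tt <- seq_len(n) / fs
  # slight F0 declination over the segment
  f0t <- f0 * seq(1.04, 0.96, length.out = n)
  phase <- 2 * pi * cumsum(f0t) / fs
  f1 <- seq(seg$f1[1], seg$f1[2], length.out = n) * formantScale
  f2 <- seq(seg$f2[1], seg$f2[2], length.out = n) * formantScale
  h <- seq_len(max(1L, floor(min(4500, 0.45 * fs) / f0)))
  hf <- outer(rep(1, n), h * f0)
  gain <- exp(-((hf - f1) / 110)^2) + 0.7 * exp(-((hf - f2) / 140)^2)
  gain <- gain * outer(rep(1, n), h^-0.3)
  x <- rowSums(gain * sin(outer(phase, h)))
  seg$amp * x / max(abs(x)) * rampEnvelope(n, fs)
}

synthBurst <- function(seg, formantScale, fs) {
  n <- round(seg$dur * fs)
  lo <- min(seg$lo * formantScale, 0.90 * fs / 2)
  hi <- min(seg$hi * formantScale, 0.95 * fs / 2)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  seg$amp * x / max(abs(x)) * rampEnvelope(n, fs)
}

#' Create a talker profile
#'
#' @param f0Hz Fundamental frequency in Hz.
#' @param formantScale Unitless formant multiplier.
#' @param seed Integer seed for the talker's stochastic components.
#' @param id Integer talker id.
#' @return A [TalkerProfile-class].
#' @export
talkerProfile <- function(f0Hz, formantScale = 1, seed = 1L, id = 1L) {
  methods::new("TalkerProfile", f0Hz = f0Hz, formantScale = formantScale,
               seed = as.integer(seed), id = as.integer(id))
}

#' Generate a pool of talker profiles
#'
#' Alternates male-like (100-140 Hz) and female-like (180-230 Hz) fundamentals
#' and draws a formant scaling in [0.92, 1.08] per talker.
#'
#' @param n Number of talkers.
#' @param seed Master seed.
#' @return List of [TalkerProfile-class] objects with ids 1..n.
#' @export
makeTalkers <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withSeed(deriveSeed(seed, "talkers"), {
    lapply(seq_len(n), function(i) {
      f0 <- if (i %% 2L == 1L) stats::runif(1, 100, 140) else stats::runif(1, 180, 230)
      talkerProfile(f0Hz = f0, formantScale = stats::runif(1, 0.92, 1.08),
                    seed = deriveSeed(seed, paste0("talker", i)), id = i)
    })
  })
}

#' Synthesize a spoken-digit token
#'
#' Builds the digit's segment template (formant-trajectory vowels and band
#' noise bursts), perturbed by the talker profile, and calibrates it to
#' `levelDbSpl`. Deterministic given (digit, talker, sampleRate).
#'
#' @param digit Integer 0-9.
#' @param talker A [TalkerProfile-class].
#' @param sampleRate Sampling rate in Hz (>= 16000).
#' @param levelDbSpl Calibration level, default 70 dB SPL.
#' @param utterance Utterance index; repeat utterances of the same digit by
#'   the same talker differ through a small seeded fundamental jitter.
#' @return A [DigitToken-class].
#' @export
synthesizeDigit <- function(digit, talker, sampleRate = 16000, levelDbSpl = 70,
                            utterance = 1L) {
  if (length(digit) != 1L || is.na(digit) || digit != round(digit) ||
      digit < 0 || digit > 9)
    stop("digit must be a single integer in 0..9")
  if (sampleRate < 16000) stop("sampleRate must be >= 16000 Hz")
  tmpl <- digitTemplates()[[as.character(digit)]]
  x <- withSeed(deriveSeed(talker@seed, paste0("digit", digit, "u", utterance)), {
    f0 <- talker@f0Hz * stats::runif(1, 0.97, 1.03)
    unlist(lapply(tmpl, function(seg) {
      s <- if (seg$type == "vowel") synthVowel(seg, f0, talker@formantScale, sampleRate)
           else synthBurst(seg, talker@formantScale, sampleRate)
      c(s, rep(0, round(0.005 * sampleRate)))  # 5 ms inter-segment gap
    }))
  })
  x <- setLevel(x, levelDbSpl)
  methods::new("DigitToken", samples = x, sampleRate = sampleRate,
               digit = as.integer(digit), talkerId = talker@id,
               levelDbSpl = levelDbSpl)
}

#' Calibrate samples to a target dB SPL
#'
#' Rescales the vector so its RMS corresponds to `targetDbSpl` under the
#' package convention (full scale 1.0 = 94 dB SPL). Shape is preserved;
#' all-zero input is rejected (undefined gain).
#'
#' @param x Numeric sample vector, or a [DigitToken-class].
#' @param targetDbSpl Target level in dB SPL.
#' @return Rescaled samples (or a re-calibrated token).
#' @export
setLevel <- function(x, targetDbSpl) {
  if (methods::is(x, "DigitToken")) {
    y <- setLevel(x@samples, targetDbSpl)
    return(methods::new("DigitToken", samples = y, sampleRate = x@sampleRate,
                        digit = x@digit, talkerId = x@talkerId,
                        levelDbSpl = targetDbSpl))
  }
  stopifnot(is.numeric(x))
  r <- sqrt(mean(x^2))
  if (r == 0) stop("cannot calibrate an all-zero signal")
  x * 10^((targetDbSpl - FULL_SCALE_DB_SPL) / 20) / r
}

#' Mix a calibrated token with white background noise
#'
#' Embeds the token at the start of a fixed analysis window (default 700 ms,
#' the neurogram length) and adds flat-spectrum Gaussian noise at
#' `noiseLevelDbSpl` over the whole window, the way a continuous background
#' behaves. The SNR is recorded as speech level minus noise level; speech
#' level refers to the level during the token, the standard convention.
#' Keeping the noise on for the full window matters: if noise stopped at
#' token offset, the active length of the neurogram would reveal the digit
#' even at strongly negative SNRs.
#'
#' @param token A [DigitToken-class] already at its presentation level.
#' @param noiseLevelDbSpl Noise level in dB SPL, within [0, 100].
#' @param seed Integer seed for the noise draw.
#' @param windowS Analysis-window duration in seconds.
#' @return A [NoisyStimulus-class].
#' @seealso [quietStimulus()] for the no-noise reference condition.
#' @export
mixWithNoise <- function(token, noiseLevelDbSpl, seed = 1L, windowS = 0.7) {
  stopifnot(methods::is(token, "DigitToken"))
  if (noiseLevelDbSpl < 0 || noiseLevelDbSpl > 100)
    stop("noiseLevelDbSpl must lie in [0, 100]")
  n <- max(length(token@samples), round(windowS * token@sampleRate))
  speech <- c(token@samples, rep(0, n - length(token@samples)))
  noise <- withSeed(seed, stats::rnorm(n))
  noise <- setLevel(noise, noiseLevelDbSpl)
  methods::new("NoisyStimulus", samples = speech + noise,
               sampleRate = token@sampleRate, digit = token@digit,
               talkerId = token@talkerId, speechLevelDbSpl = token@levelDbSpl,
               noiseLevelDbSpl = noiseLevelDbSpl,
               snrDb = token@levelDbSpl - noiseLevelDbSpl)
}

#' Wrap a token as a noise-free stimulus
#'
#' The quiet reference condition used for reference neurograms: no noise
#' added, noise level -Inf, SNR +Inf. The token is embedded in the same
#' fixed analysis window as [mixWithNoise()].
#'
#' @param token A [DigitToken-class].
#' @param windowS Analysis-window duration in seconds.
#' @return A [NoisyStimulus-class] with zero added noise.
#' @export
quietStimulus <- function(token, windowS = 0.7) {
  n <- max(length(token@samples), round(windowS * token@sampleRate))
  methods::new("NoisyStimulus",
               samples = c(token@samples, rep(0, n - length(token@samples))),
               sampleRate = token@sampleRate, digit = token@digit,
               talkerId = token@talkerId, speechLevelDbSpl = token@levelDbSpl,
               noiseLevelDbSpl = -Inf, snrDb = Inf)
}

#' Build a stimulus-grid manifest
#'
#' Enumerates talker x utterance x digit x noise-level combinations. With 225
#' talkers, 2 utterances per digit and 21 noise levels the manifest has 94,500
#' rows.
#'
#' @param nTalkers Number of talkers.
#' @param utterancesPerDigit Utterances of each digit per talker.
#' @param noiseLevels Vector of noise levels in dB SPL.
#' @param speechDbSpl Speech presentation level (default 70 dB SPL).
#' @param seed Master seed; per-row noise seeds derive from it.
#' @return data.frame with columns talker_id, utterance, digit, speech_db,
#'   noise_db, snr_db, seed.
#' @export
buildStimulusGrid <- function(nTalkers, utterancesPerDigit, noiseLevels,
                              speechDbSpl = 70, seed = 1L) {
  stopifnot(nTalkers >= 1, utterancesPerDigit >= 1, length(noiseLevels) >= 1)
  g <- expand.grid(noise_db = noiseLevels, digit = 0:9,
                   utterance = seq_len(utterancesPerDigit),
                   talker_id = seq_len(nTalkers), KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("talker_id", "utterance", "digit", "noise_db")]
  g$speech_db <- speechDbSpl
  g$snr_db <- g$speech_db - g$noise_db
  g$seed <- vapply(seq_len(nrow(g)), function(i)
    deriveSeed(seed, paste0("stim", i)), integer(1))
  rownames(g) <- NULL
  g[, c("talker_id", "utterance", "digit", "speech_db", "noise_db", "snr_db", "seed")]
}

#' Write a stimulus manifest to CSV
#'
#' @param manifest A manifest from [buildStimulusGrid()] (optionally with a
#'   `path` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
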