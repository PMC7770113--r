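test_that("token synthesis is deterministic and duration-bounded", {
  tk <- makeTalkers(3, seed = 11)
  a <- synthesizeDigit(4, tk[[1]])
  b <- synthesizeDigit(4, tk[[1]])
  expect_identical(samples(a), samples(b))
  # byte-identical WAV for identical inputs
  f1 <- tempfile(fileext = ".wav"); f2 <- tempfile(fileext = ".wav")
  writeWav(samples(a), sampleRate(a), f1)
  writeWav(samples(b), sampleRate(b), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  for (d in 0:9) {
    tok <- synthesizeDigit(d, tk[[2]])
    dur <- length(samples(tok)) / sampleRate(tok)
    expect_gte(dur, 0.3); expect_lte(dur, 0.7)
    expect_true(all(is.finite(samples(tok))))
  }
  # different talkers give different tokens of the same digit
  expect_false(identical(samples(synthesizeDigit(4, tk[[2]])), samples(a)))
  expect_error(synthesizeDigit(10, tk[[1]]), "0..9")
  expect_error(synthesizeDigit(3, tk[[1]], sampleRate = 8000), "16000")
})

test_that("distinct digits are spectrally distinct (independent spectrogram)", {
  tk <- makeTalkers(1, seed = 5)[[1]]
  t3 <- synthesizeDigit(3, tk)
  t7 <- synthesizeDigit(7, tk)
  s3 <- oracleSpectrogram(samples(t3), sampleRate(t3))
  s7 <- oracleSpectrogram(samples(t7), sampleRate(t7))
  expect_lt(oracleSpecCor(s3, s7), 0.8)
})

test_that("level calibration is exact, additive and idempotent", {
  tk <- makeTalkers(1, seed = 2)[[1]]
  tok <- synthesizeDigit(6, tk)
  x <- setLevel(samples(tok), 70)
  expect_lt(abs(measureLevel(x) - 70), 0.01)
  expect_equal(measureLevel(2 * x) - measureLevel(x), 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(setLevel(x, 70), x, tolerance = 1e-12)
  expect_error(setLevel(rep(0, 100), 70), "all-zero")
  # property: 1000 random gains recalibrate to < 0.01 dB error
  set.seed(31)
  targets <- runif(1000, 20, 95)
  errs <- vapply(targets, function(tg)
    abs(measureLevel(setLevel(x * runif(1, 0.1, 10), tg)) - tg), numeric(1))
  expect_lt(max(errs), 0.01)
})

test_that("noise mixing records SNR and adds power", {
  tk <- makeTalkers(1, seed = 3)[[1]]
  tok <- synthesizeDigit(1, tk)     # 70 dB SPL
  expect_equal(snrDb(mixWithNoise(tok, 70, 1)), 0)
  expect_equal(snrDb(mixWithNoise(tok, 90, 1)), -20)
  expect_error(mixWithNoise(tok, 101, 1), "\\[0, 100\\]")
  # mixture power ~ sum of component powers at -20 dB SNR, over >= 100 seeds
  nWin <- length(samples(mixWithNoise(tok, 90, 1)))
  pSpeech <- sum(samples(tok)^2) / nWin        # token power over the window
  pNoise <- 10^((90 - 94) / 10)     # 90 dB SPL under the 94 dB convention
  pMix <- vapply(1:120, function(s) mean(samples(mixWithNoise(tok, 90, s))^2),
                 numeric(1))
  expect_equal(mean(pMix), pSpeech + pNoise, tolerance = 0.01)
  # noise fills the whole analysis window (700 ms), not just the token
  expect_equal(nWin / sampleRate(tok), 0.7, tolerance = 1e-6)
  # quiet reference carries no noise
  q <- quietStimulus(tok)
  expect_identical(samples(q)[seq_along(samples(tok))], samples(tok))
  expect_identical(snrDb(q), Inf)
})

test_that("stimulus grid cardinality follows the design product", {
  expect_equal(nrow(buildStimulusGrid(225, 2, seq(0, 100, 5))), 94500)
  expect_equal(nrow(buildStimulusGrid(1, 1, 50)), 10)
  m <- buildStimulusGrid(5, 2, c(40, 70, 100))
  expect_equal(nrow(m), 300)
  expect_equal(nrow(unique(m[c("talker_id", "utterance", "digit", "noise_db")])),
               300)
  # exhaustive product check at small sizes
  for (nt in 1:3) for (u in 1:2) for (nl in 1:3)
    expect_equal(nrow(buildStimulusGrid(nt, u, seq_len(nl) * 10)),
                 nt * u * 10 * nl)
  expect_true(all(m$snr_db == m$speech_db - m$noise_db))
})

test_that("tokens are separable by a nearest-template spectrogram classifier", {
  tk <- makeTalkers(10, seed = 77)
  templates <- lapply(0:9, function(d) synthesizeDigit(d, tk[[1]]))
  set.seed(19)
  cases <- data.frame(digit = rep(0:9, each = 10),
                      talker = rep(1:10, times = 10))
  tokens <- lapply(seq_len(nrow(cases)), function(i) {
    tok <- synthesizeDigit(cases$digit[i], tk[[cases$talker[i]]])
    # +70 dB SNR: speech 70 dB SPL over 0 dB SPL noise
    mixWithNoise(tok, 0, seed = i)
  })
  pred <- oracleNearestTemplate(tokens, templates)
  expect_gt(mean(pred == cases$digit), 0.9)
})

test_that("WAV I/O round-trips both encodings", {
  x <- sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)) * 0.5
  f <- tempfile(fileext = ".wav")
  writeWav(x, 16000, f, bits = 16L)
  r <- readWav(f)
  expect_equal(r$sampleRate, 16000)
  expect_equal(r$samples, x, tolerance = 1e-4)   # 16-bit quantization
  writeWav(x, 16000, f, bits = 32L)
  r <- readWav(f)
  expect_equal(r$samples, x, tolerance = 1e-7)
})
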