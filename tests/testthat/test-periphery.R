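test_that("audiogram fitting honours the 2/3-1/3 split and monotonicity", {
  grid <- cfGrid(16)
  nh <- fitAudiogram(audiometricProfile("NH"), grid)
  expect_true(all(nh$cohc == 1) && all(nh$cihc == 1))
  flat <- fitAudiogram(audiometricProfile("flat_loss", flatDbHl = 30), grid)
  # 2/3 of 30 dB to OHC, 1/3 to IHC, mapped linearly over [0, 105] dB
  expect_equal(flat$cohc, rep(1 - 20 / 105, 16), tolerance = 1e-12)
  expect_equal(flat$cihc, rep(1 - 10 / 105, 16), tolerance = 1e-12)
  # health non-increasing in threshold shift, swept 0..120 dB
  shifts <- seq(0, 120, by = 5)
  health <- vapply(shifts, function(s) {
    p <- audiometricProfile("flat_loss", flatDbHl = s)
    suppressWarnings(fitAudiogram(p, grid)$cohc[1])
  }, numeric(1))
  expect_true(all(diff(health) <= 0))
  expect_true(all(health >= 0 & health <= 1))
  expect_warning(fitAudiogram(audiometricProfile("flat_loss", flatDbHl = 170),
                              grid), "clamp")
})

test_that("Greenwood map matches the human constants and inverts exactly", {
  expect_equal(greenwoodMap(0), 165.4 * (10^0 - 0.88), tolerance = 1e-12)
  expect_equal(greenwoodMap(1), 165.4 * (10^2.1 - 0.88), tolerance = 1e-12)
  # direct evaluations: ~19.85 Hz at the apex, ~20.7 kHz at the base
  expect_equal(greenwoodMap(0), 19.848, tolerance = 1e-3)
  expect_equal(greenwoodMap(1), 20676.6, tolerance = 0.1)
  set.seed(8)
  xs <- runif(100)
  expect_equal(greenwoodInverse(greenwoodMap(xs)), xs, tolerance = 1e-9)
  expect_error(greenwoodMap(1.2), "\\[0, 1\\]")
})

test_that("MOCR gain control: identity, saturation band and kinetics", {
  grid <- cfGrid(16)
  stOn <- table1States(grid, 0.1)[["NH_mocr20_anf[2,2,6]"]]
  stOff <- table1States(grid, 0.1)[["NH_mocr0_anf[2,2,6]"]]
  inBand <- cfs(grid) >= 1000 & cfs(grid) <= 4000
  # reflex disabled -> identity for any drive
  drive <- matrix(runif(16 * 300, 0, 0.5), 16, 300)
  expect_equal(mocrEffectiveCohc(drive, stOff), matrix(1, 16, 300))
  # sustained loud noise (>= 60 dB SPL drive): in-band cohc strictly below
  # static, out-of-band untouched
  loud <- matrix(0.2, 16, 800)       # 0.2 Pa = 80 dB SPL
  eff <- mocrEffectiveCohc(loud, stOn)
  expect_true(all(eff[inBand, 800] < 1))
  expect_true(all(eff[!inBand, ] == 1))
  # steady state approaches the full configured reduction (20 dB of OHC gain)
  expect_equal(eff[inBand, 800], stOn@cohc[inBand] *
    (1 - stOn@mocrMax[inBand] * (0.2 / (0.2 + 0.02))), tolerance = 1e-3)
  # step onset decays exponentially with the configured onset tau (60 ms)
  k <- which(inBand)[1]
  s <- 1 - eff[k, ] / (stOn@cohc[k])            # reduction trace
  sInf <- s[800]
  lm1 <- lm(log(pmax(sInf - s[5:300], 1e-12)) ~ I(5:300))
  tau <- -1 / coef(lm1)[2] / 1000               # envelope rate is 1 kHz
  expect_equal(unname(tau), 0.060, tolerance = 0.01)
})

test_that("fiber rate functions: spontaneous floor, tuning and monotonicity", {
  grid <- cfGrid(16)
  st <- table1States(grid, 0.1)[[1]]
  prep <- preparePeriphery(grid)
  pars <- srClassParams()
  sil <- simulateFiberRates(silentStimulus(0.3), st, prep)
  for (cl in 1:3)
    expect_equal(mean(sil$rates[, , cl]), pars$spontRates[cl],
                 tolerance = 0.01 * max(pars$spontRates[cl], 0.01))
  # tone at cfs[k] drives row k hardest (settled portion, brute-force argmax)
  for (k in c(3, 6, 9, 12, 15)) {
    f <- cfs(grid)[k]
    tone <- sin(2 * pi * f * seq(0, 0.3, by = 1 / 16000))
    stim <- methods::new("NoisyStimulus", samples = setLevel(tone, 60),
                         sampleRate = 16000, digit = 0L, talkerId = 1L,
                         speechLevelDbSpl = 60, noiseLevelDbSpl = -Inf,
                         snrDb = Inf)
    r <- simulateFiberRates(stim, st, prep)
    prof <- rowMeans(r$rates[, 100:300, 3])
    expect_equal(which.max(prof), k)
  }
  # rate-level function non-decreasing over 0..100 dB SPL in 5 dB steps
  f <- cfs(grid)[8]
  tone <- sin(2 * pi * f * seq(0, 0.12, by = 1 / 16000))
  lvls <- seq(0, 100, 5)
  rates <- vapply(lvls, function(L) {
    stim <- methods::new("NoisyStimulus", samples = setLevel(tone, L),
                         sampleRate = 16000, digit = 0L, talkerId = 1L,
                         speechLevelDbSpl = L, noiseLevelDbSpl = -Inf, snrDb = Inf)
    mean(simulateFiberRates(stim, st, prep)$rates[8, 60:110, 2])
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-9))
  expect_error(simulateFiberRates(
    methods::new("NoisyStimulus", samples = rnorm(1000), sampleRate = 12000,
                 digit = 0L, talkerId = 1L, speechLevelDbSpl = 70,
                 noiseLevelDbSpl = 70, snrDb = 0), st), "2x")
})

test_that("neurogram generation: zero fibers, Poisson oracle, ANF ordering, determinism", {
  grid <- cfGrid(16)
  states <- table1States(grid, 0.1)
  st <- states[[1]]
  stDeg <- states[["NH_mocr20_anf[0,0,5]"]]
  prep <- preparePeriphery(grid)
  none <- cochlearState(audiometricProfile("NH"), 20, c(0, 0, 0), grid)
  sil <- silentStimulus(0.3)
  expect_true(all(values(generateNeurogram(sil, none, 1, prep)) == 0))
  # silent-frame expected count: sum_class count*spont/frameRate per CF;
  # empirical mean over 200 seeds within 3 SE of the analytic Poisson mean
  pars <- srClassParams()
  lam <- sum(st@fiberCounts * pars$spontRates) / 100
  tots <- vapply(1:200, function(s)
    mean(values(generateNeurogram(sil, st, s, prep))), numeric(1))
  nCells <- 16 * 30 * 200
  se <- sqrt(lam / nCells)
  expect_lt(abs(mean(tots) - lam), 3 * se)
  # dispersion index of silent frames near 1 (Poisson oracle)
  cnt <- unlist(lapply(1:50, function(s)
    as.vector(values(generateNeurogram(sil, st, s, prep)))))
  expect_gt(var(cnt) / mean(cnt), 0.8)
  expect_lt(var(cnt) / mean(cnt), 1.2)
  # ANF-degraded state yields strictly lower total count on identical input/seed
  tk <- makeTalkers(1, seed = 4)[[1]]
  stim <- mixWithNoise(synthesizeDigit(7, tk), 65, seed = 2)
  nhNg <- generateNeurogram(stim, st, seed = 3, prepared = prep)
  degNg <- generateNeurogram(stim, stDeg, seed = 3, prepared = prep)
  expect_lt(sum(values(degNg)), sum(values(nhNg)))
  # determinism
  expect_identical(values(generateNeurogram(stim, st, seed = 3, prepared = prep)),
                   values(nhNg))
})

test_that("finalization trims to 70 frames from onset and z-scores exactly", {
  fx <- testFixtures()
  ng <- fx$sets[[1]]
  expect_equal(dim(values(ng))[2], 70L)
  # every fixture neurogram satisfies the z-score invariant
  for (i in seq_len(dim(values(ng))[3])) {
    v <- values(ng)[, , i]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sd(as.vector(v)) - 1), 1e-6)
  }
  # 90-frame raw input: output equals the first 70 post-onset frames, z-scored
  raw <- matrix(rpois(16 * 90, 5), 16, 90)
  raw[, 1:4] <- rpois(16 * 4, 0.2)             # pre-onset quiet
  rawNg <- methods::new("Neurogram", values = raw, cfGrid = cfGrid(16),
                        frameRate = 100, normalized = FALSE, degenerate = FALSE,
                        metadata = list(baselineMean = 16 * 0.2))
  fin <- finalizeNeurogram(rawNg)
  onset <- metadata(fin)$onsetFrame
  ref <- raw[, onset:(onset + 69)]
  expect_equal(values(fin), (ref - mean(ref)) / sd(as.vector(ref)),
               tolerance = 1e-12)
  # constant raw neurogram -> all zeros, degenerate flag
  zero <- methods::new("Neurogram", values = matrix(0L, 16, 80),
                       cfGrid = cfGrid(16), frameRate = 100,
                       normalized = FALSE, degenerate = FALSE,
                       metadata = list(baselineMean = 0))
  fz <- finalizeNeurogram(zero)
  expect_true(isDegenerate(fz))
  expect_true(all(values(fz) == 0))
})
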