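humanSig <- function(x, a, b) 0.1 + 0.9 / (1 + exp(-a * (x - b)))

test_that("sigmoid fitting recovers known parameters and rejects flat data", {
  snr <- seq(-50, 50, 5)          # 21 SNRs
  # noiseless generated data: near-exact interpolation
  y <- humanSig(snr, a = 0.5, b = -20)
  fit <- fitSigmoid(psychometricCurve(snr, y), "human")
  expect_lt(fit@residual, 1e-10)
  expect_equal(fit@a, 0.5, tolerance = 1e-5)
  expect_equal(fit@b, -20, tolerance = 1e-4)
  # parameter recovery under Gaussian noise sigma = 0.02, 100 reps:
  # a within 10%, b within 1 dB on average
  set.seed(55)
  rec <- vapply(1:100, function(i) {
    yn <- pmin(1, pmax(0, y + rnorm(length(y), 0, 0.02)))
    f <- fitSigmoid(psychometricCurve(snr, yn), "human")
    c(f@a, f@b)
  }, numeric(2))
  expect_lt(abs(mean(rec[1, ]) - 0.5) / 0.5, 0.10)
  expect_lt(abs(mean(rec[2, ]) + 20), 1)
  expect_lt(stats::median(abs(rec[1, ] - 0.5) / 0.5), 0.10)
  expect_lt(stats::median(abs(rec[2, ] + 20)), 1)
  # mirror symmetry: reflecting the data through the curve midpoint
  # (x -> -x, y -> 2*floor + span - y) leaves a unchanged and negates b
  ym <- (2 * 0.1 + 0.9) - y
  fitM <- fitSigmoid(psychometricCurve(sort(-snr), rev(ym)), "human")
  expect_equal(fitM@a, fit@a, tolerance = 1e-4)
  expect_equal(fitM@b, -fit@b, tolerance = 1e-3)
  # flat-at-chance data: non-identifiable, rejected with a diagnostic
  expect_error(fitSigmoid(psychometricCurve(snr, rep(0.1, 21)), "human"),
               "flat")
  expect_error(fitSigmoid(psychometricCurve(snr[1:3], y[1:3]), "human"),
               "at least 4")
})

test_that("50%-SNR inversion is closed-form exact", {
  fit <- methods::new("SigmoidFit", a = 0.37, b = -18.2, floor = 0.1,
                      span = 0.9, variant = "human", residual = 0)
  # human variant, target 0.5: x = b - ln(1.25)/a (algebraic inversion),
  # cross-checked numerically by root finding
  expect_equal(snrAtAccuracy(fit, 0.5), -18.2 - log(1.25) / 0.37,
               tolerance = 1e-12)
  root <- uniroot(function(x) predictSigmoid(fit, x) - 0.5, c(-60, 30),
                  tol = 1e-12)$root
  expect_equal(snrAtAccuracy(fit, 0.5), root, tolerance = 1e-8)
  # inflection point: target floor + span/2 gives exactly b
  expect_equal(snrAtAccuracy(fit, 0.1 + 0.45), -18.2, tolerance = 1e-12)
  # round-trip for 100 random targets
  set.seed(12)
  for (t in runif(100, 0.101, 0.999)) {
    expect_equal(predictSigmoid(fit, snrAtAccuracy(fit, t)), t,
                 tolerance = 1e-9)
  }
  expect_error(snrAtAccuracy(fit, 0.05), "outside")
  expect_error(snrAtAccuracy(fit, 1.0), "outside")
})

test_that("human-space scaling is exact on the fit and order-preserving", {
  snr <- seq(-40, 30, 5)
  mFit <- methods::new("SigmoidFit", a = 0.4, b = -21, floor = 0.09,
                       span = 0.88, variant = "model", residual = 0)
  hFit <- methods::new("SigmoidFit", a = 0.5, b = -22, floor = 0.10,
                       span = 0.90, variant = "human", residual = 0)
  modelAcc <- predictSigmoid(mFit, snr)
  scaled <- scaleToHuman(psychometricCurve(snr, modelAcc), mFit, hFit)
  expect_equal(scaled@accuracy, predictSigmoid(hFit, snr), tolerance = 1e-12)
  # identical fits: unit factor
  same <- scaleToHuman(psychometricCurve(snr, modelAcc), mFit, mFit)
  expect_equal(same@accuracy, modelAcc, tolerance = 1e-12)
  # the quantile strategy is also exact on the fit and reduces to identity
  expect_equal(scaleToHuman(psychometricCurve(snr, modelAcc), mFit, hFit,
                            method = "quantile")@accuracy,
               predictSigmoid(hFit, snr), tolerance = 1e-9)
  expect_equal(scaleToHuman(psychometricCurve(snr, modelAcc), mFit, mFit,
                            method = "quantile")@accuracy,
               modelAcc, tolerance = 1e-9)
  # quantile scaling preserves monotonicity for 100 random monotone curves
  # (the ratio form does not in general; see the methods vignette)
  set.seed(77)
  for (i in 1:100) {
    acc <- cumsum(runif(length(snr), 0, 0.08))
    acc <- 0.05 + 0.9 * acc / max(acc)
    sc <- scaleToHuman(psychometricCurve(snr, acc), mFit, hFit,
                       method = "quantile")
    expect_true(all(diff(sc@accuracy) >= -1e-12))
  }
})

test_that("confusion statistics: identity, hand-computed case, symmetry", {
  set.seed(3)
  truth <- sample(0:9, 400, TRUE)
  pred <- ifelse(runif(400) < 0.7, truth, sample(0:9, 400, TRUE))
  cm <- confusionMatrix(truth, pred, snrDb = -10)
  expect_true(all(abs(rowSums(cm$proportions) - 1) < 1e-9))
  expect_equal(sum(cm$counts), 400)
  expect_equal(confusionStats(cm, cm)$rmse, 0)
  # +10 points in one cell, -10 in another: RMSE = sqrt(200/100)
  A <- diag(10) * 100
  B <- A; B[1, 1] <- 90; B[1, 2] <- 10
  expect_equal(confusionStats(A / 100 * 1, B)$rmse, sqrt(200 / 100),
               tolerance = 1e-12)
  expect_equal(confusionStats(A, B)$rmse, confusionStats(B, A)$rmse)
  bad <- matrix(runif(100), 10, 10)
  expect_error(confusionStats(bad, bad), "normalized")
})

test_that("repeated-measures ANOVA: power, null calibration, permutation", {
  makeDesign <- function(effect, seedI, sigma = 0.5, nFolds = 10) {
    d <- expand.grid(fold = seq_len(nFolds), audiometric = c("NH", "loss"),
                     anf = c("healthy", "degraded"), mocr = c("on", "off"))
    withr::with_seed(seedI, {
      d$threshold <- rnorm(nrow(d), -15, sigma) +
        ifelse(d$anf == "degraded", effect, 0) +
        rnorm(nFolds, 0, 0.3)[d$fold]      # fold random effect
    })
    d
  }
  # injected +5 dB ANF main effect detected at alpha = 0.001 (50 reps)
  hits <- vapply(1:50, function(i) {
    tab <- thresholdAnova(makeDesign(5, i))
    tab$p[tab$effect == "anf"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.98)
  # pure-noise thresholds: null calibration over 200 simulations.
  # The F(1, dfE) null median sits just below 0.5 (qf(0.5, 1, 27) ~ 0.47),
  # so calibration is checked on both scales: the empirical F median must
  # match the theoretical null median, and p-values must be uniform enough
  # that their median is near 0.5.
  null200 <- vapply(1:200, function(i) {
    tab <- thresholdAnova(makeDesign(0, 1000 + i))
    k <- tab$effect == "anf"
    c(tab$F[k], tab$p[k], tab$dfError[k])
  }, numeric(3))
  fMedTheory <- stats::qf(0.5, 1, null200[3, 1])
  expect_lt(abs(stats::median(null200[1, ]) - fMedTheory), 0.35)
  expect_gt(stats::median(null200[2, ]), 0.35)
  expect_lt(stats::median(null200[2, ]), 0.65)
  # permuting responses against the design destroys an injected effect
  d <- makeDesign(5, 7)
  dPerm <- d
  dPerm$threshold <- withr::with_seed(8, sample(d$threshold))
  tabI <- thresholdAnova(d)
  tabP <- thresholdAnova(dPerm)
  expect_lt(tabP$F[tabP$effect == "anf"],
            tabI$F[tabI$effect == "anf"] / 5)
  # unbalanced designs are rejected
  expect_error(thresholdAnova(makeDesign(0, 1)[-1, ]), "unbalanced")
})
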