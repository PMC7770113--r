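test_that("folds are talker-disjoint, fraction-true, SNR-complete and reproducible", {
  m <- buildStimulusGrid(10, 1, c(40, 70, 100))
  folds <- makeFolds(m, nFolds = 4, seed = 3)
  expect_length(folds, 4L)
  for (f in folds) {
    expect_length(intersect(f@trainTalkers, f@testTalkers), 0L)
    expect_length(intersect(f@trainTalkers, f@valTalkers), 0L)
    # 70/10/20 of 10 talkers: 7/1/2 exactly
    expect_equal(lengths(list(f@trainTalkers, f@valTalkers, f@testTalkers)),
                 c(7L, 1L, 2L))
    expect_equal(sum(f@fractions), 1)
    for (sub in c("train", "val", "test"))
      expect_setequal(unique(m$snr_db[foldRows(f, m, sub)]), unique(m$snr_db))
  }
  folds2 <- makeFolds(m, nFolds = 4, seed = 3)
  for (i in 1:4) expect_identical(folds[[i]]@trainTalkers,
                                  folds2[[i]]@trainTalkers)
  expect_false(identical(folds[[1]]@trainTalkers, folds[[2]]@trainTalkers))
  expect_error(makeFolds(buildStimulusGrid(2, 1, 70), 2), "too few talkers")
})

test_that("paradigm definitions encode the Fig-5 contracts", {
  expect_identical(paradigm("nh_control")@phase2Source, "NH")
  expect_identical(paradigm("nh_control")@maskType, "all")
  expect_identical(paradigm("unconstrained")@phase2Source, "degraded")
  expect_identical(paradigm("unconstrained")@maskType, "all")
  expect_identical(paradigm("constrained")@phase2Source, "degraded")
  expect_identical(paradigm("constrained")@maskType, "f5")
})

test_that("phase-2 paradigms honour masks and reuse splits", {
  fx <- testFixtures()
  nhSet <- fx$sets[[1]]; degSet <- fx$sets[[2]]
  fold <- makeFolds(fx$manifest, 1, fractions = c(0.5, 0.25, 0.25), seed = 5)[[1]]
  cfg <- fixtureNetConfig()
  baseline <- trainBaseline(cfg, nhSet, fold, budget = 256, seed = 2)
  # constrained: conv and F1-F4 tensors bit-identical to baseline
  resC <- runParadigm(baseline, paradigm("constrained"), fold, nhSet, degSet,
                      phase2Budget = 256, seed = 3)
  for (nm in setdiff(tensorNames(baseline), c("F5.weight", "F5.bias")))
    expect_identical(resC$state@params[[nm]], baseline@params[[nm]])
  expect_false(identical(resC$state@params$F5.weight, baseline@params$F5.weight))
  # accuracy table covers every SNR of the test split
  expect_setequal(resC$accuracy$snr_db, unique(fx$manifest$snr_db))
  expect_true(all(resC$accuracy$accuracy >= 0 & resC$accuracy$accuracy <= 1))
  # nh_control evaluated on NH test neurograms tracks the baseline
  resN <- runParadigm(baseline, paradigm("nh_control"), fold, nhSet, degSet,
                      phase2Budget = 256, seed = 3, testOn = "nh")
  basAcc <- evaluateBySnr(baseline, nhSet, foldRows(fold, fx$manifest, "test"))
  expect_lt(mean(abs(resN$accuracy$accuracy - basAcc$accuracy)), 0.25)
  # the test rows consumed are identical across paradigms for a given fold
  expect_identical(foldRows(fold, nhSet@meta, "test"),
                   foldRows(fold, degSet@meta, "test"))
})

test_that("layer change matches a brute-force oracle and flags degenerate sd", {
  cfg <- fixtureNetConfig()
  baseline <- buildNetwork(cfg, seed = 1)
  current <- baseline
  set.seed(9)
  for (nm in tensorNames(current))
    current@params[[nm]] <- current@params[[nm]] +
      rnorm(length(current@params[[nm]]), 0, 0.05)
  rep <- layerChange(current, baseline)
  expect_identical(nrow(rep@table), 20L)
  # element-wise brute-force recomputation to 1e-12
  for (nm in c("C1.weight", "F3.weight", "F5.bias", "C4.bias")) {
    B <- as.vector(baseline@params[[nm]])
    P <- as.vector(current@params[[nm]])
    muB <- sum(B) / length(B)
    sdB <- sqrt(sum((B - muB)^2) / (length(B) - 1))
    manual <- 0
    for (i in seq_along(P)) manual <- manual + abs(P[i] - B[i]) / sdB
    manual <- manual / length(P)
    expect_equal(rep@table$value[rep@table$tensor == nm], manual,
                 tolerance = 1e-12)
    # a one-parameter move of one baseline sd scores exactly 1
    one <- baseline
    one@params[[nm]][1] <- one@params[[nm]][1] + sdB * length(B)
    rep1 <- layerChange(one, baseline)
    expect_equal(rep1@table$value[rep1@table$tensor == nm], 1,
                 tolerance = 1e-9)
  }
  # identity comparison: all zeros
  repId <- layerChange(baseline, baseline)
  expect_true(all(repId@table$value == 0))
  # sigma_B = 0 is flagged undefined, not silently 0
  degen <- baseline
  degen@params$F5.bias[] <- 0.3
  repDg <- layerChange(current, degen)
  expect_true(repDg@table$undefined[repDg@table$tensor == "F5.bias"])
  expect_true(is.na(repDg@table$value[repDg@table$tensor == "F5.bias"]))
  # frozen tensors report exactly zero after constrained training
  fx <- testFixtures()
  fold <- makeFolds(fx$manifest, 1, fractions = c(0.5, 0.25, 0.25), seed = 5)[[1]]
  trained <- runParadigm(buildNetwork(cfg, seed = 1), paradigm("constrained"),
                         fold, fx$sets[[1]], fx$sets[[2]], 128, seed = 2)$state
  repC <- layerChange(trained, buildNetwork(cfg, seed = 1))
  f5 <- repC@table$tensor %in% c("F5.weight", "F5.bias")
  expect_true(all(repC@table$value[!f5] == 0))
  expect_true(all(repC@table$value[f5] > 0))
  expect_error(layerChange(buildNetwork(fixtureNetConfig(), seed = 1),
                           buildNetwork(networkConfig(c(16, 70), baseChannels = 8),
                                        seed = 1)),
               "architectures differ")
})
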