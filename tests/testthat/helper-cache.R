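# Session-level caches so expensive shared objects are built once per test
# run. All content is fully deterministic given the fixed seeds.

.dinoiseTestCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  got <- .dinoiseTestCache[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .dinoiseTestCache[[key]] <- got
  }
  got
}

# Tiny bundled fixture bundle (16 CFs, 40 tokens x 3 SNRs, 2 states).
testFixtures <- function() cached("fixtures", makeFixtures(seed = 42L))

# A small network configuration matched to the fixture neurograms.
fixtureNetConfig <- function() networkConfig(c(16L, 70L), baseChannels = 4L,
                                             batchSize = 32L)

# Desk-scale end-to-end study shared by the acceptance tests: NH baseline and
# constrained adaptation on the NH-audiogram ANF-degraded state, for three
# training seeds over a fixed stimulus/neurogram pool.
deskStudy <- function() cached("deskStudy", {
  cfg <- experimentConfig("desk", seed = 7L)
  grid <- cfGrid(cfg@nCF)
  states <- table1States(grid, cfg@fiberScale)
  nhState <- states[[1]]
  degState <- states[["NH_mocr20_anf[0,0,5]"]]
  talkers <- makeTalkers(cfg@nTalkers, seed = deriveSeedT(cfg@seed, "talkers"))
  manifest <- buildStimulusGrid(cfg@nTalkers, cfg@utterancesPerDigit,
                                cfg@noiseLevels, cfg@speechDbSpl,
                                seed = deriveSeedT(cfg@seed, "grid"))
  prepared <- preparePeriphery(grid)
  nhSet <- generateNeurogramSet(manifest, talkers, nhState, prepared)
  degSet <- generateNeurogramSet(manifest, talkers, degState, prepared)
  fold <- makeFolds(manifest, 1L, seed = deriveSeedT(cfg@seed, "folds"))[[1]]
  netCfg <- networkConfig(c(cfg@nCF, 70L), baseChannels = cfg@baseChannels,
                          batchSize = cfg@batchSize)
  runs <- lapply(1:3, function(sd) {
    baseline <- trainBaseline(netCfg, nhSet, fold, cfg@phase1Budget, seed = sd)
    nhAcc <- evaluateBySnr(baseline, nhSet, foldRows(fold, manifest, "test"))
    constr <- runParadigm(baseline, paradigm("constrained"), fold, nhSet,
                          degSet, cfg@phase2Budget, seed = sd)
    list(baseline = baseline, nhAcc = nhAcc, constrained = constr)
  })
  list(config = cfg, manifest = manifest, fold = fold, nhSet = nhSet,
       degSet = degSet, runs = runs)
})

# deriveSeed is internal; re-derive through the namespace for helpers.
deriveSeedT <- function(seed, tag) dinoise:::deriveSeed(seed, tag)
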