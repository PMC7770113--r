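# Two-phase, three-paradigm train/test orchestration with talker-disjoint
# folds, and the normalized-mean-difference layer-change metric.

#' The three phase-2 training paradigms
#'
#' nh_control: phase 2 continues on NH neurograms with all tensors trainable
#' (no adaptation to the degradation). unconstrained: phase 2 on degraded
#' neurograms, all tensors trainable. constrained: phase 2 on degraded
#' neurograms with only the final fully connected layer (F5 weight and bias)
#' trainable.
#'
#' @param name "nh_control", "unconstrained" or "constrained".
#' @return A [Paradigm-class].
#' @export
paradigm <- function(name = c("nh_control", "unconstrained", "constrained")) {
  name <- match.arg(name)
  methods::new("Paradigm", name = name,
               phase2Source = if (name == "nh_control") "NH" else "degraded",
               maskType = if (name == "constrained") "f5" else "all")
}

#' Talker-disjoint train/validation/test folds
#'
#' Permutes talkers (not utterances) and apportions them 70/10/20 by largest
#' remainder, so no talker appears in more than one subset; utterances follow
#' their talker, which also guarantees every SNR is represented in every
#' subset. Identical seeds give identical folds, and the same splits are
#' reused across training phases.
#'
#' @param manifest Manifest data.frame with `talker_id` and `snr_db` columns.
#' @param nFolds Number of folds.
#' @param fractions Train/val/test fractions (default 0.70/0.10/0.20).
#' @param seed Master seed.
#' @return List of [FoldSplit-class] objects.
#' @export
makeFolds <- function(manifest, nFolds = 10L, fractions = c(0.70, 0.10, 0.20),
                      seed = 1L) {
  talkers <- sort(unique(manifest$talker_id))
  counts <- apportion(length(talkers), fractions)
  if (any(counts == 0L))
    stop("too few talkers (", length(talkers),
         ") for disjoint train/val/test splits at these fractions")
  lapply(seq_len(nFolds) - 1L, function(f) {
    perm <- withSeed(deriveSeed(seed, paste0("fold", f)), sample(talkers))
    tr <- perm[seq_len(counts[1])]
    va <- perm[counts[1] + seq_len(counts[2])]
    te <- perm[counts[1] + counts[2] + seq_len(counts[3])]
    for (set in list(tr, te)) {
      snrs <- unique(manifest$snr_db[manifest$talker_id %in% set])
      if (!setequal(snrs, unique(manifest$snr_db)))
        stop("a subset does not cover all SNRs; use more talkers per subset")
    }
    methods::new("FoldSplit", foldId = as.integer(f),
                 trainTalkers = as.integer(tr), valTalkers = as.integer(va),
                 testTalkers = as.integer(te), fractions = fractions,
                 seed = deriveSeed(seed, paste0("fold", f)))
  })
}

#' Manifest row indices of a fold subset
#'
#' @param fold A [FoldSplit-class].
#' @param manifest Manifest data.frame with `talker_id`.
#' @param subset "train", "val" or "test".
#' @return Integer row indices.
#' @export
foldRows <- function(fold, manifest, subset = c("train", "val", "test")) {
  subset <- match.arg(subset)
  ids <- switch(subset, train = fold@trainTalkers, val = fold@valTalkers,
                test = fold@testTalkers)
  which(manifest$talker_id %in% ids)
}

# Train `state` for `budget` samples on rows of `set`, shuffling epoch-wise.
# The final partial batch is allowed.
trainOnRows <- function(state, set, rows, budget, batchSize, mask = "all",
                        seed = 1L, logEvery = Inf) {
  consumed <- 0L; epoch <- 0L
  losses <- numeric()
  while (consumed < budget) {
    epoch <- epoch + 1L
    order <- withSeed(deriveSeed(seed, paste0("epoch", epoch)), sample(rows))
    for (start in seq(1L, length(order), by = batchSize)) {
      if (consumed >= budget) break
      take <- min(batchSize, length(order) - start + 1L, budget - consumed)
      idx <- order[start:(start + take - 1L)]
      res <- trainStep(state, set@values[, , idx, drop = FALSE],
                       set@meta$digit[idx], mask)
      state <- res$state
      consumed <- consumed + take
      losses <- c(losses, res$loss)
    }
  }
  list(state = state, losses = losses, samplesConsumed = consumed)
}

#' Train the phase-1 NH-baseline network
#'
#' @param config A [NetworkConfig-class] (or a prebuilt [NetworkState-class]).
#' @param nhSet NH [NeurogramSet-class].
#' @param fold A [FoldSplit-class].
#' @param budget Number of training samples to consume.
#' @param seed Seed for initialization and batch order.
#' @return A trained [NetworkState-class].
#' @export
trainBaseline <- function(config, nhSet, fold, budget, seed = 1L) {
  state <- if (methods::is(config, "NetworkState")) config
    else buildNetwork(config, seed = deriveSeed(seed, "init"))
  rows <- foldRows(fold, nhSet@meta, "train")
  trainOnRows(state, nhSet, rows, budget, state@config@batchSize, "all",
              seed = deriveSeed(seed, "phase1"))$state
}

#' Accuracy-versus-SNR table on a fold subset
#'
#' @param state A [NetworkState-class].
#' @param set A [NeurogramSet-class].
#' @param rows Manifest row indices to evaluate.
#' @return data.frame: snr_db, accuracy, n_test.
#' @export
evaluateBySnr <- function(state, set, rows) {
  pred <- networkPredict(state, set@values[, , rows, drop = FALSE])
  truth <- set@meta$digit[rows]
  snr <- set@meta$snr_db[rows]
  agg <- stats::aggregate(correct ~ snr_db,
    data = data.frame(snr_db = snr, correct = as.numeric(pred == truth)),
    FUN = mean)
  n <- as.vector(table(factor(snr, levels = sort(unique(snr)))))
  data.frame(snr_db = agg$snr_db, accuracy = agg$correct, n_test = n)
}

#' Run one phase-2 paradigm on one fold
#'
#' Continues the NH-baseline network on the paradigm's phase-2 source (NH or
#' degraded neurograms) for `phase2Budget` samples under the paradigm's
#' trainable mask, then evaluates on the held-out test rows of the cochlear
#' state under study. The fold's split is reused unchanged from phase 1.
#'
#' @param baseline Phase-1 [NetworkState-class] (trained on NH neurograms).
#' @param par A [Paradigm-class].
#' @param fold A [FoldSplit-class].
#' @param nhSet,stateSet NH and degraded [NeurogramSet-class] aligned to the
#'   same manifest.
#' @param phase2Budget Samples to consume in phase 2.
#' @param seed Batch-order seed.
#' @param testOn "state" (default: the cochlear state under study) or "nh".
#' @return List: `state` (trained network), `accuracy` (data.frame snr_db,
#'   accuracy, n_test), `paradigm`, `foldId`.
#' @export
runParadigm <- function(baseline, par, fold, nhSet, stateSet, phase2Budget,
                        seed = 1L, testOn = c("state", "nh")) {
  testOn <- match.arg(testOn)
  stopifnot(methods::is(par, "Paradigm"))
  srcSet <- if (par@phase2Source == "NH") nhSet else stateSet
  rows <- foldRows(fold, srcSet@meta, "train")
  tr <- trainOnRows(baseline, srcSet, rows, phase2Budget,
                    baseline@config@batchSize, par@maskType,
                    seed = deriveSeed(seed, paste0("phase2", par@name)))
  evalSet <- if (testOn == "state") stateSet else nhSet
  acc <- evaluateBySnr(tr$state, evalSet, foldRows(fold, evalSet@meta, "test"))
  list(state = tr$state, accuracy = acc, paradigm = par@name,
       foldId = fold@foldId)
}

#' Normalized mean parameter difference per tensor
#'
#' For each of the 20 parameter tensors, the mean absolute per-parameter
#' change scaled by the baseline tensor's standard deviation,
#' (1/n) sum_i |P_i - B_i| / sigma_B. An unchanged (frozen) tensor reports
#' exactly 0 and a one-parameter tensor moved by one baseline standard
#' deviation reports 1. The baseline mean mu_B and sigma_B are carried in
#' the report; tensors with sigma_B = 0 are flagged undefined rather than
#' reported as 0.
#'
#' @param current,baseline [NetworkState-class] objects with identical
#'   architecture.
#' @return A [LayerChangeReport-class].
#' @export
layerChange <- function(current, baseline) {
  if (!identical(lapply(current@params, dim), lapply(baseline@params, dim)))
    stop("architectures differ: cannot compare parameter tensors")
  nm <- tensorNames(baseline)
  rows <- lapply(nm, function(n) {
    B <- as.vector(baseline@params[[n]]); P <- as.vector(current@params[[n]])
    muB <- mean(B); sdB <- stats::sd(B)
    undef <- !is.finite(sdB) || sdB == 0
    data.frame(tensor = n,
               layer = sub("\\..*$", "", n),
               kind = sub("^.*\\.", "", n),
               value = if (undef) NA_real_ else mean(abs(P - B) / sdB),
               baselineMean = muB, baselineSd = sdB, undefined = undef,
               stringsAsFactors = FALSE)
  })
  methods::new("LayerChangeReport", table = do.call(rbind, rows),
               step = current@step)
}
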