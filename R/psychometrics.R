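# Psychometric-curve analysis: sigmoid fits with variant-fixed asymptotes,
# 50%-SNR thresholds, human-space scaling, confusion statistics and
# repeated-measures factorial ANOVA.

sigmoidVariants <- list(human = c(floor = 0.10, span = 0.90),
                        model = c(floor = 0.09, span = 0.88))

#' Evaluate a fitted sigmoid
#'
#' f(x) = floor + span / (1 + exp(-a (x - b))).
#'
#' @param fit A [SigmoidFit-class].
#' @param x SNR values in dB.
#' @return Predicted accuracy.
#' @export
predictSigmoid <- function(fit, x) {
  fit@floor + fit@span / (1 + exp(-fit@a * (x - fit@b)))
}

#' Build a psychometric curve
#'
#' @param snrDb SNR grid (dB), strictly increasing.
#' @param accuracy Mean accuracy per SNR in [0, 1].
#' @param sem Standard error across folds (0 when unknown).
#' @param n Number of folds/subjects.
#' @return A [PsychometricCurve-class].
#' @export
psychometricCurve <- function(snrDb, accuracy, sem = rep(0, length(snrDb)),
                              n = 1L) {
  o <- order(snrDb)
  methods::new("PsychometricCurve", snrDb = snrDb[o], accuracy = accuracy[o],
               sem = sem[o], n = as.integer(n))
}

#' Pool fold-wise accuracy tables into a psychometric curve
#'
#' Mean and standard error of the mean across folds (SEM with n = number of
#' folds).
#'
#' @param tables List of data.frames (snr_db, accuracy) from
#'   [evaluateBySnr()] or [runParadigm()].
#' @return A [PsychometricCurve-class].
#' @export
poolFoldCurves <- function(tables) {
  snr <- sort(unique(unlist(lapply(tables, `[[`, "snr_db"))))
  accs <- vapply(tables, function(t) t$accuracy[match(snr, t$snr_db)],
                 numeric(length(snr)))
  accs <- matrix(accs, nrow = length(snr))
  nf <- length(tables)
  sem <- if (nf > 1) apply(accs, 1, stats::sd) / sqrt(nf) else rep(0, length(snr))
  psychometricCurve(snr, rowMeans(accs), sem, nf)
}

#' Fit a psychometric sigmoid by nonlinear least squares
#'
#' Solves for slope a (> 0) and inflection b with the floor/span pair fixed
#' by the variant: human (0.1, 0.9) or model (0.09, 0.88). Data flat at
#' chance are rejected (b is not identifiable) with a diagnostic.
#'
#' @param curve A [PsychometricCurve-class] or data.frame (snr_db, accuracy).
#' @param variant "human" or "model".
#' @return A [SigmoidFit-class].
#' @export
fitSigmoid <- function(curve, variant = c("model", "human")) {
  variant <- match.arg(variant)
  if (is.data.frame(curve)) curve <- psychometricCurve(curve$snr_db, curve$accuracy)
  x <- curve@snrDb; y <- curve@accuracy
  if (length(x) < 4L) stop("need at least 4 SNR points to fit a sigmoid")
  vf <- sigmoidVariants[[variant]]
  fl <- vf["floor"]; sp <- vf["span"]
  if (diff(range(y)) < 0.15 * sp)
    stop("accuracy is flat across SNR (range ", signif(diff(range(y)), 2),
         "): inflection b is not identifiable")
  # start values: b near the half-rise crossing, a from the gross slope
  bi <- x[which.min(abs(y - (fl + sp / 2)))]
  ai <- max(4 / max(diff(range(x)), 1), 0.05)
  fit <- minpack.lm::nlsLM(
    y ~ fl + sp / (1 + exp(-a * (x - b))),
    start = list(a = ai, b = bi),
    lower = c(a = 1e-4, b = min(x) - 60),
    upper = c(a = 10, b = max(x) + 60),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  methods::new("SigmoidFit", a = unname(cf["a"]), b = unname(cf["b"]),
               floor = unname(fl), span = unname(sp), variant = variant,
               residual = sum(stats::residuals(fit)^2))
}

#' SNR at a target accuracy (closed form)
#'
#' Inverts the fitted sigmoid: x = b - ln(span / (target - floor) - 1) / a.
#' Targets outside the open asymptote range are rejected.
#'
#' @param fit A [SigmoidFit-class].
#' @param target Target accuracy, default 0.5 (the 50%-correct threshold).
#' @return SNR in dB.
#' @export
snrAtAccuracy <- function(fit, target = 0.5) {
  if (target <= fit@floor || target >= fit@floor + fit@span)
    stop("target ", target, " outside the open range (", fit@floor, ", ",
         fit@floor + fit@span, "): asymptotes are unreachable")
  fit@b - log(fit@span / (target - fit@floor) - 1) / fit@a
}

#' Remap a model curve into human performance space
#'
#' Two interchangeable strategies behind one operation. "ratio" (default):
#' SNR-dependent multiplicative scaling, scaled(x) = clip(acc(x) *
#' f_human(x) / f_model(x), 0, 1). "quantile": the monotone composition
#' scaled(x) = f_human(f_model^{-1}(acc(x))), which maps accuracies through
#' the two fits and preserves monotonicity of any monotone curve. Both are
#' exact on the NH-model mean curve (where acc = f_model, the result is
#' f_human) and both reduce to the identity when the two fits coincide.
#'
#' @param curve Model [PsychometricCurve-class].
#' @param modelFit [SigmoidFit-class] of the NH-model mean curve (variant
#'   "model").
#' @param humanFit [SigmoidFit-class] of the NH human mean curve (variant
#'   "human").
#' @param method "ratio" or "quantile".
#' @return A [PsychometricCurve-class] in human units.
#' @export
scaleToHuman <- function(curve, modelFit, humanFit,
                         method = c("ratio", "quantile")) {
  method <- match.arg(method)
  if (method == "ratio") {
    fac <- predictSigmoid(humanFit, curve@snrDb) /
      predictSigmoid(modelFit, curve@snrDb)
    acc <- pmin(1, pmax(0, curve@accuracy * fac))
    return(psychometricCurve(curve@snrDb, acc, curve@sem * fac, curve@n))
  }
  eps <- 1e-9
  a <- pmin(pmax(curve@accuracy, modelFit@floor + eps),
            modelFit@floor + modelFit@span - eps)
  xEquiv <- modelFit@b - log(modelFit@span / (a - modelFit@floor) - 1) / modelFit@a
  acc <- predictSigmoid(humanFit, xEquiv)
  psychometricCurve(curve@snrDb, acc, curve@sem, curve@n)
}

#' Build a confusion matrix from predictions
#'
#' @param truth,predicted Integer digits 0-9.
#' @param snrDb SNR annotation.
#' @return List: `counts` (10x10, rows = true digit), `proportions`
#'   (row-normalized), `snrDb`.
#' @export
confusionMatrix <- function(truth, predicted, snrDb = NA_real_) {
  counts <- table(factor(truth, levels = 0:9), factor(predicted, levels = 0:9))
  counts <- matrix(as.integer(counts), 10, 10,
                   dimnames = list(true = 0:9, predicted = 0:9))
  rs <- rowSums(counts)
  prop <- counts / ifelse(rs > 0, rs, 1)
  list(counts = counts, proportions = prop, snrDb = snrDb)
}

#' Compare two row-normalized confusion matrices
#'
#' RMSE over the 100 cells in percentage points, plus each matrix's diagonal
#' as per-digit accuracy. Symmetric in its arguments.
#'
#' @param A,B 10x10 matrices of row proportions (each row summing to 1 or
#'   expressed in percent summing to 100), or outputs of [confusionMatrix()].
#' @return List: `rmse` (percentage points), `perDigitA`, `perDigitB`
#'   (percent correct per digit).
#' @export
confusionStats <- function(A, B) {
  getP <- function(x) if (is.list(x)) x$proportions else x
  pa <- getP(A); pb <- getP(B)
  stopifnot(all(dim(pa) == c(10, 10)), all(dim(pb) == c(10, 10)))
  toPct <- function(p) {
    rs <- rowSums(p)
    if (all(abs(rs - 1) < 1e-6 | rs == 0)) return(p * 100)
    if (all(abs(rs - 100) < 1e-4 | rs == 0)) return(p)
    stop("confusion rows must be normalized (to 1 or to 100)")
  }
  pa <- toPct(pa); pb <- toPct(pb)
  list(rmse = sqrt(mean((pa - pb)^2)),
       perDigitA = diag(pa), perDigitB = diag(pb))
}

#' Repeated-measures factorial ANOVA on 50%-SNR thresholds
#'
#' Four-way (audiometric x ANF x MOCR x paradigm) ANOVA with cross-validation
#' folds as the random/repeated unit, delegated to a standard
#' `aov` fit with an Error(fold) stratum. Requires a balanced complete
#' design.
#'
#' @param thresholds data.frame with columns `fold`, `threshold`, and factor
#'   columns (any subset of audiometric, anf, mocr, paradigm present is
#'   crossed).
#' @param factors Factor column names to cross.
#' @return data.frame: effect, df, dfError, F, p.
#' @export
thresholdAnova <- function(thresholds,
                           factors = intersect(c("audiometric", "anf", "mocr",
                                                 "paradigm"),
                                               names(thresholds))) {
  stopifnot(all(c("fold", "threshold") %in% names(thresholds)),
            length(factors) >= 1L)
  d <- thresholds
  d$fold <- factor(d$fold)
  for (f in factors) d[[f]] <- factor(d[[f]])
  cells <- table(d[factors])
  if (length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: every factor cell needs the same number of folds")
  form <- stats::as.formula(paste("threshold ~", paste(factors, collapse = " * "),
                                  "+ Error(fold)"))
  fit <- stats::aov(form, data = d)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  effects <- trimws(rownames(within))
  resid <- effects == "Residuals"
  data.frame(effect = effects[!resid],
             df = within$Df[!resid],
             dfError = within$Df[resid],
             F = within$`F value`[!resid],
             p = within$`Pr(>F)`[!resid],
             row.names = NULL)
}
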