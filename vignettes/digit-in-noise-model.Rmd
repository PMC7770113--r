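---
title: "Modelling digit-in-noise perception through a degradable auditory periphery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling digit-in-noise perception through a degradable auditory periphery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dinoise)
```

## The model

`dinoise` simulates a listener performing a digits-in-noise task as a
two-stage system: a cochlear periphery that converts calibrated acoustic
waveforms into auditory-nerve population neurograms under configurable
degradations, and a convolutional network that identifies the spoken digit
from the neurogram. Sweeping background-noise level and reducing the
resulting accuracy-versus-SNR tables to psychometric sigmoid fits yields the
quantities audiologists use — 50%-correct SNR thresholds and their shifts
under cochlear degradation — while the network's two-phase training
schedule provides a controllable model of central adaptation to sudden
hearing loss.

The pipeline is: `synthesizeDigit()` → `mixWithNoise()` →
`generateNeurogram()`/`finalizeNeurogram()` under a `CochlearState` →
`trainBaseline()`/`runParadigm()` → `fitSigmoid()`/`snrAtAccuracy()` →
`thresholdAnova()`. `runExperiment()` wires the stages together
deterministically from one master seed.

## Synthetic digit tokens

Licensed speech corpora cannot ship with a package, so the stimulus module
generates digit-like tokens from ten hand-designed templates: 2–3 segments
per digit, with vowel-like segments synthesized additively (harmonics of a
declining F0 shaped by two linear formant trajectories) and consonant-like
segments as band-limited noise bursts. A talker is a `TalkerProfile`:
male-like (100–140 Hz) or female-like (180–230 Hz) fundamental and a global
formant rescaling in [0.92, 1.08]. Repeat utterances jitter F0 by ±3%.
Durations lie in [0.3, 0.7] s. Everything is deterministic given (digit,
talker, utterance).

Calibration uses a fixed digital-to-pascal convention: full-scale amplitude
1.0 ≡ 94 dB SPL (1 Pa RMS re 20 µPa). `setLevel()` rescales RMS exactly;
the measured-level error is < 0.01 dB by construction.

`mixWithNoise()` embeds the token at the start of a fixed 700 ms analysis
window and adds white Gaussian noise over the *whole* window. This models a
continuous background and is load-bearing: when noise is added only over
the token, the number of active neurogram frames encodes the token's
duration — and therefore the digit — at any SNR, and the psychometric
curve never falls to chance. The speech level refers to the level during
the token, the usual convention for speech audiometry.

What the generator does *not* emulate: coarticulation, prosodic variation,
within-talker variability beyond F0 jitter, or any natural-speech
spectro-temporal richness. Passing tests therefore show that the pipeline's
machinery behaves correctly and reproduces the *relative* phenomena
(sigmoidal psychometric curves, degradation-ordered thresholds), not that
absolute accuracies transfer to real speech.

## The periphery

The periphery is deliberately phenomenological. Each characteristic
frequency (CF) on a log grid (100 Hz – 8 kHz; 128 CFs at paper scale, 32 at
desk scale) has a 2nd-order Butterworth band-pass of one ERB bandwidth.
Band envelopes (rectified, 1-ms boxcar, 1 kHz envelope rate) drive
everything downstream in the dB domain:

* **Hair-cell health.** An audiogram is interpolated onto the CF grid;
  2/3 of each threshold shift is attributed to outer-hair-cell (OHC) loss
  and 1/3 to inner-hair-cell (IHC) loss. Health maps linearly from dB to
  [1, 0] over [0, 105] dB per component, and a component health `c` costs
  `(1 − c) · 105` dB of drive — so fitted audiograms reproduce their
  threshold shifts exactly, and health is monotone in loss.
* **MOCR.** Within the 1–4 kHz sensitive band (positioned via the
  Greenwood map, `F = 165.4(10^{2.1x} − 0.88)`), the efferent reflex
  reduces effective OHC health: `cohc(t) = cohc·(1 − mocrMax·s(t))` where
  `s` is the saturating drive `d/(d + 0.02 Pa)` smoothed with 60 ms onset
  and 200 ms offset time constants (plausible published MOC kinetics). The
  20 dB MOCR-gain setting fixes `mocrMax` so the steady-state reduction
  equals 20 dB of the OHC gain available at that CF; 0 dB disables the
  reflex exactly.
* **Fiber classes.** Rates for low/medium/high spontaneous-rate classes
  (spont 0.1/5/60 sp/s; thresholds 35/23/5 dB SPL; primary dynamic ranges
  40/30/20 dB; saturation 250 sp/s) follow logistic rate-level functions
  plus a shallow *sloping-saturation* limb (fraction 0.20/0.30/0.45 of the
  driven range, ~100 dB half-range). The sloping limb matters: without it
  every class pegs at saturation for any band above a few tens of dB SPL,
  and the high-SR-only synaptopathy state ([0, 0, 52]) loses all spectral
  contrast at the 70 dB SPL speech level — the opposite of the phenomenon
  being modelled, in which audiometrically normal ANF-degraded ears retain
  near-normal performance in quiet and lose it in noise. All class
  parameters are configuration (`srClassParams()`), not constants.
* **Spiking.** Population spike counts per CF are drawn per 10 ms frame as
  Poisson variates at the class rate × fiber count. Summing independent
  Poisson processes is itself Poisson, so drawing the population count
  directly is exact in distribution and orders of magnitude faster than
  per-fiber simulation. The frame rate is exactly 100 Hz (70 frames per
  700 ms); a stated 8 ms summation window cannot coexist with a 100 Hz
  frame rate, and the 10 ms frame is the resolution that makes the 700 ms
  trim exact.

`finalizeNeurogram()` detects onset (first frame whose 3-frame-smoothed
population count exceeds the spontaneous baseline by 3 Poisson SDs), trims
to exactly 70 frames, zero-pads shorter tokens, and z-scores all cells
(global mean 0, SD 1). Constant neurograms return all zeros with a
`degenerate` flag rather than NaNs.

Not modelled: middle-ear filtering, compression and suppression,
refractoriness, power-law/fGn synaptic adaptation, binaural processing.
The absence of rate adaptation shows up in one documented place: sustained
noise inflates the normal-hearing response relative to a quiet reference,
so reference-based similarity metrics can rank a fiber-depleted neurogram
*above* the normal one at low SNR (see below).

## Neurogram metrics

`nsim()` is an SSIM-style comparison over 3×3 Gaussian-weighted windows
(σ = 0.5): intensity `l = (2μ_rμ_d + C1)/(μ_r² + μ_d² + C1)` and structure
`s = (σ_rd + C3)/(σ_rσ_d + C3)`, with `C1 = (0.01 L)²`, `C3 = (0.03 L)²/2`
and `L` the reference dynamic range (floored for constant references so
equal constants score 1). `stmi()` projects both neurograms onto a
windowed 2-D Fourier modulation-energy representation, keeps rates
2–32 Hz and scales 0.25–8 cyc/oct, and returns
`1 − ‖T − N‖²/‖T‖²` clamped to [0, 1]. Both are invariant to joint
positive rescaling.

Against a quiet normal-hearing reference, STMI ranks the ANF+MOCR-degraded
state below normal at +5 dB SNR; NSIM does so only at milder noise
(≥ +30 dB SNR in the bundled tests) because its intensity term rewards the
fiber-depleted state's lower noise drive. This inversion is a known
pathology of reference-based metrics — it is the package's motivation for
evaluating intelligibility with a task-performing classifier instead —
and the bundled tests pin each metric in the regime where its ordering is
stable.

## The classifier

Five convolutional layers (5×5 then 3×3 kernels) with channel depths
[C, 2C, 4C, 2C, C]; local response normalization (size 5, α = 1e-4,
β = 0.75, k = 2) and 2×2 max-pooling after the first two conv layers and
after the fifth; then five fully connected layers shrinking geometrically
to the 10 digit classes; ReLU after every hidden layer; log-softmax +
negative log likelihood; Adam with learning rate and weight decay both
1e-3; batch 256 (64 at desk scale). The 20 parameter tensors (weight +
bias × 10 layers) are drawn from normal distributions; by default each
weight tensor's SD is `sqrt(2/fan_in)` (biases 0.01) because a fixed tiny
SD starves a ten-layer stack of forward signal and the network provably
fails to learn within any reasonable budget; a fixed-SD override remains
available (`initStd`).

The engine is vectorized base R: convolutions via cached linear-index
gathers (im2col), the input gradient via the flipped-kernel convolution of
the output gradient, LRN via a banded channel matrix, and hand-derived
backward passes for every layer (verified against central finite
differences to ~1e-5 relative error). Backpropagation stops at the deepest
layer whose tensors are trainable, so constrained (final-layer-only)
adaptation costs roughly a forward pass.

## Adaptation paradigms and folds

`makeFolds()` permutes *talkers* and apportions them 70/10/20 by largest
remainder; utterances follow their talker, so train/test talkers are
disjoint (novel-talker testing) and every SNR appears in every subset.
The same folds are reused across both training phases. Phase 1 trains the
NH baseline on normal-hearing neurograms; phase 2 follows one of three
paradigms: `nh_control` (more NH data, all tensors trainable),
`unconstrained` (degraded data, all tensors), `constrained` (degraded
data, only F5's weight and bias). Evaluation is on held-out test rows of
the cochlear state under study.

`layerChange()` reports, per tensor, the mean absolute per-parameter
change scaled by the baseline tensor's SD: `(1/n) Σ |P_i − B_i| / σ_B`.
This is the only normalization under which an untouched tensor reports
exactly 0 (the frozen-layer signature of constrained adaptation) and a
single parameter moved by one baseline SD reports 1. Tensors with
`σ_B = 0` are flagged undefined, never silently zero.

## Psychometrics

Accuracy tables pool across folds into mean ± SEM curves. `fitSigmoid()`
solves `f(x) = floor + span/(1 + exp(−a(x − b)))` for `(a, b)` by
nonlinear least squares (`minpack.lm`), with the asymptote pair fixed by
variant: human (0.1, 0.9) or model (0.09, 0.88). Slope `a` is constrained
positive; flat-at-chance data are rejected as non-identifiable.
`snrAtAccuracy()` inverts the fit in closed form. Thresholds are read from
fitted sigmoids, not linear interpolation.

`scaleToHuman()` maps model accuracies into human units with two
swappable strategies: the default SNR-dependent ratio
`acc(x)·f_h(x)/f_m(x)` (clipped to [0, 1]) and a quantile map
`f_h(f_m^{-1}(acc(x)))`. Both are exact on the NH-model mean curve and
reduce to the identity for identical fits; only the quantile form
preserves monotonicity of arbitrary monotone curves (the ratio
`f_h/f_m` is unimodal, so the ratio form can locally invert slowly-rising
curves — which is why both are provided behind one operation).

`thresholdAnova()` runs the repeated-measures factorial (audiometric ×
ANF × MOCR × paradigm) with folds as the repeated unit via a standard
`aov` fit with an `Error(fold)` stratum, requiring a balanced design. Note
that the null median of an F(1, ~27) statistic is ≈ 0.47, not 1; the null
calibration tests check both the F-scale and p-value-scale behaviour.

## Presets, problem sizes and determinism

The `paper` preset reproduces the printed design: 225 talkers × 2
utterances × 10 digits × 21 noise levels (94,500 stimuli), 128 CFs, 100
fibers/CF in the 12-state factorial (3 audiograms × 2 MOCR gains × 2 fiber
distributions), 250,000-sample training phases, batch 256, 10 folds. It is
provided for completeness; generating its neurograms is a cluster-scale
computation.

The `desk` preset is the package's working scale, chosen so a complete
study (neurogram generation for two cochlear states, phase-1 training,
phase-2 adaptation, psychometric reduction) runs end-to-end on one CPU in
roughly a quarter of an hour: 10 talkers × 10 digits × 7 noise levels
spanning SNR +30…−30 dB (700 stimuli per state), 32 CFs, fiber
distributions scaled to [2, 2, 6] / [0, 0, 5], 20,000-sample phases, batch
64, base channels 8. At this scale the NH psychometric curve is sigmoidal
(chance floor near −30 dB SNR, ceiling at +30), but absolute thresholds
sit far above the paper-scale system — with 10 fibers per CF the Poisson
count noise is ~3× larger than with 100 — so only relative comparisons
(threshold shifts, paradigm orderings) are meaningful, and those are what
the acceptance checks assert.

Every stochastic step derives its seed from one master seed and a purpose
tag, so identical configurations are bit-reproducible; `--seed` in
`scripts/acceptance.R` reseeds the entire pipeline.

## Known limitations

Absolute accuracies and thresholds are not comparable to human data (the
synthetic tokens are much easier than natural speech at matched SNR, and
the desk-scale fiber counts are noisier). The MOCR knob's main-effect size
at desk scale is small relative to fold noise. NSIM's low-SNR inversion is
documented above. The CLI (`inst/cli/dinoise.R`) is a thin wrapper over
the documented functions; neurograms and checkpoints persist as JSON/CSV.
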