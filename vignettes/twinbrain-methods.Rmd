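---
title: "Connectome-conditioned digital twins: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-conditioned digital twins: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`twinbrain` builds an individualized generative model of task behavior and
regional BOLD dynamics from a resting-state functional connectome. Two
networks cooperate:

* **Hypernetwork.** A multilayer perceptron with two hidden layers of
  `n_hidden_hyper` Mish units maps the Fisher-z vectorized upper triangle
  of a participant's region-by-region correlation matrix (`n_in` edges;
  99,235 edges for the 446-region atlas of the full-scale configuration)
  to a single flat vector containing *every* weight and bias of that
  participant's main network. Dropout (default rate 0.1) is applied to the
  connectome input during training only. The Mish activation is
  `u * tanh(log(1 + exp(u)))`, evaluated in a form that is stable for
  large `|u|`.
* **Main network.** A vanilla recurrent network with `n_hidden_main` tanh
  units receives, every 80 ms, an 8-dimensional symbolic rendering of the
  visual stimulus plus a constant task-condition flag (0 for the
  emotional-face matching task, 1 for color-word Stroop), and emits
  next-step predictions: 3 button-press probabilities (logistic sigmoid on
  the first readout dimensions) and `n_bold` regional BOLD values (linear
  readout). At the reference dimensions (9 inputs, 400 hidden, 3 + 20
  outputs) the packed parameter vector has 173,623 entries.

Training minimizes `L = lambda_action * BCE + lambda_bold * MSE` (both
weights default 1), where BCE/MSE are elementwise means over all
(segment, step, channel) entries, with gradients flowing through the
unrolled recurrence (backpropagation through time) and the parameter
packing into the hypernetwork, optimized with Adam. The readout at step
`t` is the prediction *for* step `t + 1`; training pairs inputs `1..T-1`
with targets `2..T`. One deliberate numerical choice: the loss
normalizes by the full element count rather than by `batch * T` alone
(which would sum over the 3 action and 20 BOLD channels). The two differ
only by constant factors absorbed into the learning rate and the loss
weights.

Sigmoid-on-actions is itself a documented choice: the readout is linear,
but binary cross-entropy needs probabilities, so the action dimensions
pass through a logistic sigmoid and the BCE is computed in logit form
for numerical stability; BOLD dimensions stay linear for the squared
error. The initial hidden state is zero and is reset at every segment
boundary. Dropout is disabled for evaluation, attribution
(SmoothGrad), and intervention simulation.

## Downstream analysis stack

* **GLM.** Each region's signal is modeled with, per condition, a trial
  boxcar convolved with the Glover double-gamma HRF (peak 6 s,
  undershoot 12 s, dispersions 0.9 s, ratio 0.35 — the conventional
  published parameter set, exposed in `glover_hrf()`), its first
  temporal derivative, `K = floor(2 * duration * f_c)` discrete-cosine
  drift regressors (8 at ~400 s and 0.01 Hz), and a constant. Ordinary
  least squares; contrast t = estimate / standard error. Contrasts use
  HRF columns only (the derivative columns absorb latency jitter but do
  not enter the contrast). Group inference is a one-sample t-test of
  per-participant t-statistics against zero.
* **Functional indicators.** Affective: the face>shape t-statistic of
  the predicted right-amygdala BOLD. Cognitive: mean reaction time in
  ms, where the RT of a trial is the interval from stimulus appearance
  to the first 80 ms step at which any predicted press probability
  reaches the detection threshold (default 0.5); task pooling is the
  unweighted mean of per-task means.
* **PLS intervention vectors.** With participants' packed parameters
  stacked as rows of `W` and an indicator `s`, both standardized, the
  single-component direction is `v = W' s / ||W' s||` and the latent
  score is `z1 = W v`. No deflation or further components. Zero-variance
  parameter columns are dropped with a warning and re-inserted as zeros.
  The column means/SDs and a packing-layout hash travel with the result.
* **SmoothGrad.** The attribution of connectome edge `k` for a latent
  direction is the gradient of `z1` (computed on the standardized
  hypernetwork output using the *training cohort's* stored
  standardization statistics) with respect to the input edge, averaged
  over 100 noise-perturbed copies of the input; the noise SD is
  `noise_level x SD(x)` with `SD(x)` taken over all edges of that
  participant's connectome (the global rather than per-edge reading of
  the ambiguous "SD of the rsFCM"). Cohort maps average per-participant
  maps. Edge reports keep edges beyond 2.5 SD of the map's mean.
* **Intervention.** The perturbed parameters are
  `packed + alpha * v_raw` with `alpha = 2 * SD(z1)` by default. The PLS
  direction lives in standardized-parameter space; before perturbing
  actual weights it is mapped back to raw units by elementwise
  multiplication with the stored column SDs and renormalized. This
  de-standardization is a deliberate, prominent choice: standardized
  coefficients are not commensurate with raw weights, and skipping the
  mapping would over-perturb low-variance parameters. Effect sizes are
  `(pre - post) / SD(pre)` across participants, benchmarked against
  Cohen's d = 0.8.

## The synthetic cohort: what it emulates, and what a green test shows

Real data for this framework are two task-fMRI sessions plus a
resting-state connectome per participant. The generator plants a known
ground truth so that every downstream stage is testable without any
external data:

* Traits: `affective`, `cognitive` and 3 nuisance traits, i.i.d.
  standard normal per participant.
* Behavior: latency = 0.72 s + 0.16 s x cognitive + eps, with eps
  Gaussian (SD 40 ms) truncated at one 80 ms step, clipped into the
  stimulus window; error probability `plogis(qlogis(0.05) +
  0.5 x cognitive)`; errors pick uniformly among the other buttons. The
  40 ms jitter is tighter than human RT variability; it is chosen so the
  planted trait dominates trial noise at cohort sizes of tens, which is
  what the desk-scale recovery tests measure.
* BOLD: per region and condition, amplitude x (boxcar convolved with
  the Glover HRF) plus AR(1) noise (phi 0.3, stationary SD 0.2).
  Amplitudes are drawn once per cohort (N(0.5, 0.3)); the right
  amygdala's face amplitude is `0.8 - 0.35 x affective` (negative slope
  by configuration — higher affective trait, weaker response; the sign
  is recorded in `generator_params`).
* Connectome: `M = tanh(B0 + affective B_a + cognitive B_c +
  sum_k nuisance_k B_k + E)` with symmetric Gaussian loading matrices
  (SD 0.15) and edge noise (SD 0.05). Because the Fisher transform is
  `atanh`, the resulting edge vector is *exactly linear* in the traits
  plus noise. This is the simplest signal a two-hidden-layer MLP can
  exploit and is a synthetic assumption, not a claim about real
  connectomes.
* Timing: cue 2 s (Emotional Faces only), stimulus window 4 s,
  inter-trial interval 6 s, conditions blocked in runs of 4. The source
  tasks' trial timings are not public; these are configurable defaults,
  and whether the original runs were blocked or interleaved remains
  open. Run durations are 394.6 s and 407.2 s, of which the first
  196.8 s train the model and the next 196.8 s are held out.

A green trait-recovery test therefore establishes that the pipeline can
learn a *planted, linear* connectome-to-behavior mapping at toy scale —
not that real connectomes predict real reaction times. Conversely the
generator does not emulate scanner artifacts, motion, voxel-level
structure, session effects, or nonlinear trait embeddings.

## Numerical and design choices that required judgment

* **Press duration (deviation from the single-step rendering).** Button
  presses were initially rendered as a single active 80 ms step. At desk
  scale that leaves ~1 positive element per ~4,700 in the action channel,
  and pilot runs plateaued at the base-rate solution (flat ~1% press
  probability) for hundreds of epochs: the timing gradient is starved.
  Presses now span `press_steps = 3` steps (240 ms) by default —
  physically plausible, configurable, and sufficient for the timing
  gradient to engage. Reaction-time extraction is unaffected (first
  threshold crossing).
* **Baseline initialization of the generated network.** The
  hypernetwork's output bias is the shared baseline main network around
  which individual deviations are learned. Initializing it at zero
  (weights "start small") leaves the generated RNN with no temporal
  memory, and pilot runs stalled at the base-rate press solution.
  `init_hypernet()` therefore starts the baseline as a conventional RNN
  initialization — orthogonal recurrent matrix at spectral radius 0.9,
  Gaussian input weights, action-readout bias near the press base-rate
  logit — while the input-dependent (individualizing) part of the output
  layer still starts small. `baseline = "zero"` restores the plain
  scheme.
* **Learning rate at toy scale.** The full-scale reference is Adam at
  1e-6. On 32/32-unit toy models that rate is orders of magnitude too
  small; the package default for scaled-down configurations is 1e-3
  (pilot-verified descent without divergence).
* **Batching.** Batches are sets of participants; each participant
  contributes all training segments of both tasks to each gradient.
  With cohorts smaller than the batch size this degenerates to
  full-batch training with one update per epoch, so toy configurations
  use smaller batches to get several updates per epoch.
* **Validation and early stopping.** The last 10% of each participant's
  training-half segments (both tasks) form the validation set; early
  stopping monitors it with dropout off and keeps the best epoch.
  Validation never touches the held-out test half.
* **Edge ordering.** Row-major upper triangle with `i < j` everywhere
  (vectorization, hypernetwork input, SmoothGrad reports), with 0-based
  indices in exported TSVs. Degenerate correlations are clipped to
  `|r| <= 1 - 1e-7` before `atanh`.
* **Interpolation.** Ten-fold cubic-spline upsampling preserves the
  original samples exactly and does not extrapolate: `(n-1)*10 + 1`
  points; events beyond the grid are truncated. Linear interpolation is
  available as the robustness alternative.
* **Events on the grid.** Onsets are aligned by flooring `t / step_s`;
  ties between simultaneous button events cannot occur by construction
  (one response per trial, trials non-overlapping).

## Known limitations

* Training at the full published scale (99,235-edge input, 400 hidden
  units, 228 participants) is supported by the configuration surface but
  is far outside desk-scale compute; the paper-scale headline accuracies
  are documented targets, not reproduced results.
* The recurrent core learns press timing slowly; at 32/32 toy scale the
  press-probability peaks sharpen over hundreds of epochs. The
  acceptance suite trains once per run and reuses the fit.
* The cognitive indicator is undefined for a participant whose predicted
  press probabilities never reach the threshold; such participants are
  excluded and counted, and the pipeline skips (with a warning) a PLS
  vector whose indicator is degenerate.
* Clinical-correlation tooling (`correlate_with_measures()`) is a
  generic Pearson + Benjamini-Hochberg table; the published clinical
  battery is not redistributable, so no clinical result is reproduced.
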