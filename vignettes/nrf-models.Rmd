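---
title: "Network receptive field models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network receptive field models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Sensory neurons in auditory cortex respond to natural sounds in ways that a
single linear spectrotemporal receptive field (STRF) with a static output
nonlinearity — the classical linear–nonlinear (LN) model — captures only
partially. `nrfkit` implements the *network receptive field* (NRF)
alternative: a small feedforward network in which each hidden unit (HU) acts
like its own LN model on the stimulus, and a single output unit (OU) combines
the hidden units through a second nonlinearity. The package covers the whole
workflow: stimulus preprocessing, response preprocessing, model fitting,
noise-corrected evaluation, and the structural/functional analyses that make
a fitted network interpretable.

## Models

**Stimulus representation.** Audio clips are converted to cochleagrams:
Hamming-windowed power spectrograms (10 ms frames, 5 ms hop) aggregated into
log-spaced frequency channels (default 34 channels from 500 Hz at 1/6-octave
spacing, topping out at 22,627 Hz) with triangular weights, log-transformed
and clipped at a floor. The model input at time `t` is the `F x H` matrix
`x[f, tau](t)` of the last `H` cochleagram frames (default `H = 20`,
i.e. 100 ms). Cochleagrams are z-scored with pooled dataset statistics before
network fitting.

**Responses.** Spike counts in 5 ms bins, averaged over trials and smoothed
with a unit-sum Hanning window (21 ms, i.e. 5 bins), give the PSTH `y(t)`;
the first 250 ms of each clip is discarded as an onset transient. For network
training, counts are mapped onto the activation range of the network
nonlinearity: count 0 to `-1.7159` and count 1 to `+1.7159`. All reported
metrics are computed back on the spike-count scale. Weakly driven neurons are
screened by a noise ratio: with `R` trials, `noise_power` is the mean
across-trial variance, `signal_power = var(trial mean) - noise_power / R`,
and `NR = noise_power / (R * signal_power)`; neurons with `NR > 40` are
flagged. (The decomposition is a standard signal/noise power split; its scale
is pinned by simulation tests, e.g. signal variance 1, per-trial noise
variance 10, `R = 20` gives `NR ~ 0.5`.)

**LN model.** Stage 1 regresses `y(t)` on the lagged stimulus with an L1
penalty (LASSO; objective `0.5 * sum(err^2) + lambda * sum(|w|)`, bias
unpenalized), producing the STRF and the linear activation `a(t)`. The
coordinate-descent solver from glmnet stands behind `fit_linear_lasso`, with
the penalty rescaled to the unnormalized objective above. Stage 2 fits a
4-parameter logistic `y_hat = rho1 / (1 + exp(-(a - rho3)/rho2)) + rho4` by
quasi-Newton least squares from multiple starts (`rho1 = range(y)`,
`rho4 = min(y)`, `rho3 = median(a)`, `rho2` in `{±sd(a), ±sd(a)/4}`),
keeping the best; `rho1` is constrained positive, so decreasing
relationships appear as `rho2 < 0`. The squared-error surface is multimodal,
which is why the multi-start matters.

**NRF model.** `J` hidden units (default 20) feed one output unit:
`a_j = sum w_jfτ x_fτ + b_j`, `z_j = g(a_j)`,
`a_o = sum_j w_j z_j + b_o`, `y_hat = g(a_o)`, with
`g(z) = rho1 * tanh(z / rho2)`, `rho1 = 1/tanh(2/3) ~ 1.7159`,
`rho2 = 3/2`, chosen so that `g(±1) = ±1`. Training minimizes
`E = 0.5 * sum (y_hat - y)^2 + lambda * (sum|w_jfτ| + sum|w_j|)` —
biases are not penalized (a literal reading of the objective, which lists
only the connection weights).

## The optimizer

The original work used a sum-of-functions optimizer; reproducing it is out of
scope, and at desk scale a simpler method suffices. `train_nrf` runs
full-batch proximal gradient descent: backtracking line search on the smooth
loss with a Barzilai–Borwein initial step, followed by exact soft
thresholding of the weights. This yields true zeros (so "pruned" hidden
units are literally pruned) and a provably non-increasing objective across
checkpoints. Two numerical details matter:

* **Warm-up.** Weights and biases are initialized uniformly in `±1/M`
  (`M` = fan-in + 1 per unit). At that scale the all-zero weight vector is a
  *fixed point* of the proximal step: near-zero output weights annihilate the
  hidden-weight gradients, and the soft threshold then removes whatever is
  left. Training therefore starts with 30 unpenalized gradient steps, used as
  the effective initialization; the penalized phase is monotone from there,
  and the returned parameters are never worse (in objective) than the random
  initialization.
* **Iteration budget.** The default is 40 outer checkpoints of 15 proximal
  steps, with early stopping when the relative objective change over a
  checkpoint drops below `1e-6`. Fits typically settle well before the cap.

Each penalty value in cross-validation is fit *fresh* from the seeded
initialization. Warm-starting down the penalty path — a common LASSO trick —
traps the network in the preceding penalty's sparse basin and flattens the
validation surface; we measured validation `CC_norm` differences of up to
0.15 between warm-started and fresh fits at small penalties.

## Training, validation, and testing

The last 20% of every clip is the test set and is never touched before the
final evaluation. The remaining cross-validation set is split into `k` folds
(default 10) whose validation sets are the cross-validation portions of whole
clips (2 clips per fold at the 20-clip study scale), jointly partitioning the
clip set. For each penalty on a log-spaced grid (largest = the smallest
penalty that zeroes all weights of the linear problem; smallest = `1e-4` of
that; 20 points by default) the model is fit per fold and scored on the
fold's validation set by `CC_norm`; the penalty with the best unweighted
fold-mean wins, ties going to the larger penalty. The final model is refit on
the whole cross-validation set. The LN model's sigmoid stage is refit inside
every fold, and the penalty for the LN pipeline is chosen on full-LN
validation performance (not the linear stage alone). Effective-HU statistics
are computed on the cross-validation stimulus set by default (the stimulus
set is a `data` argument, so the full-set variant is one call away).

## Performance measures

* `CC_raw`: Pearson correlation of prediction and PSTH.
* `CC_half`: mean correlation between PSTHs built from two disjoint halves of
  the trials, over 126 random partitions (the half-PSTHs run through the same
  smoothing pipeline).
* `CC_max = sqrt(2 / (1 + 1/CC_half))`: the reliability ceiling — the
  correlation a perfect model would reach against an `R`-trial PSTH. The
  equation in the source text is typographically garbled; this is the
  Spearman–Brown-consistent reconstruction, satisfying `CC_max(1) = 1` and
  `CC_max ~ sqrt(2 CC_half)` as `CC_half -> 0`. Non-positive `CC_half`
  (possible for pure-noise neurons) leaves the ceiling undefined rather than
  imputed.
* `CC_norm = CC_raw / CC_max`: noise-corrected performance, invariant to
  positive affine maps of the prediction.
* `pMSE`: mean squared error restricted to bins where the observed response
  is at or above its per-clip mean + 2 SD. With the at-or-above rule a
  constant clip marks every bin; that case is pathological (every correlation
  metric is already undefined there) and is kept for fidelity to the peak
  rule as stated.

## Interpreting a fitted network

* **Adjusted network.** `g` is odd, so negating `(w_j, b_j, w_jfτ)` of a HU
  changes nothing. HUs whose STRF weights sum negative are flipped, after
  which `sign(w_j)` alone classifies a HU as excitatory or inhibitory, and an
  equivalent non-negative-output description has output bias
  `b_o - rho1 * sum_j w_j`.
* **Effective HUs.** The variance over the stimulus set of a HU's weighted
  output `w_j z_j(t)`, as a fraction of the summed variance across HUs;
  fractions at or above 5% mark effective units.
* **IE score** `= sign(w_j) * sum(w_jfτ) / sum(|w_jfτ|)`, in `[-1, 1]`.
* **EC score** `= (rho6/rho1) * (mean output - rho4) - rho5`, anchored at -1
  (threshold) and +1 (saturation); NRF units use `rho4 = 0, rho5 = 0,
  rho6 = 1`, LN units the fitted `rho1, rho4` with `rho5 = 1, rho6 = 2`.
  (Also reconstructed from a garbled source equation; the anchors pin it.)
* **Display STRFs, contours, tuning widths.** Inhibitory HU STRFs are
  sign-reversed for display. STRFs are cubic-spline interpolated onto an 8x
  grid (7 inserted values per gap; interpolated frequency bin = 1/6 x 1/8 =
  1/48 octave). Contours are drawn at half the maximum (excitatory) or half
  the minimum (inhibitory). The power STRF is the elementwise square of the
  interpolated STRF — for NRFs, the variance-weighted sum over HUs — and
  tuning widths count marginal-profile bins at or above 50%/25% of the peak,
  times the interpolated bin size. Ties count (the at-or-above reading of the
  50%/25% rules).

## Functional analyses

* **Gain control** (`gain_analysis`): for a bi-feature network (one effective
  excitatory + one effective inhibitory HU), the OU rate is computed on a
  201-point sweep of excitatory activation at 7 inhibitory activation levels
  spanning the inhibitory unit's range. Axes are normalized to the 1st/99th
  activation centiles over the cross-validation stimulus set; the sweep
  extends beyond the centiles so the excitatory unit runs from threshold to
  saturation. Gain = steepest central-difference slope, normalized to 1 at
  the lowest inhibitory level. With a linear OU the inhibitory term is purely
  additive and the gain is provably level-independent — the sigmoidal OU is
  what turns inhibition divisive.
* **Conjunction** (`reduced_nrf`, `peak_time_ratio`): "disabling" an
  excitatory HU clamps its output at the threshold value `-rho1` (the most
  negative output, zero in the non-negative description). The summed
  single-excitatory-HU reduced responses are compared against the per-clip
  2-sigma thresholds of the *observed* PSTH (thresholds are not recomputed
  per reduced model — the literal reading of the analysis); the peak time
  ratio is the reduced/full count of threshold crossings.

## The synthetic-data generator

No recordings ship with the package; `synth_experiment` builds complete
experiments with known ground truth instead. Stimuli are either
spectrotemporally low-pass Gaussian fields drawn directly in cochleagram
space (fast; correlation lengths 2 time bins x 1.5 channels) or tone-cloud
audio rendered through the real cochleagram front end. Ground-truth networks
use unit-norm Gabor STRFs at non-overlapping spectrotemporal centers, output
weights `+0.9` (excitatory) / `-0.6` (inhibitory), and an output bias solved
so the resting rate is 0.05 counts/bin — a sparse, near-threshold output
unit. Trials are `max(0, rate + N(0, sd))` by default (`sd = 0.05` counts,
giving split-half reliability above 0.95, i.e. a well-driven neuron;
Poisson trials are available for realism). Presets: `bifeature` (1+1),
`multifeature` (3+1), `linear` (one weakly driven HU operating in the linear
range of both nonlinearities), and `conjunctive` (two disjoint excitatory
features with a strongly expansive OU that responds mainly to their
coincidence).

What the generator does *not* emulate: natural-sound statistics beyond
low-pass correlation, spike-generation realism (refractoriness, adaptation,
count discreteness in the Gaussian mode), non-stationarity across trials,
and any across-neuron population structure. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions, not performance on cortical data.

## Study scales and problem sizes

Full-study-scale defaults (20 clips x 4.75 s effective, `F = 34`, `H = 20`,
`R = 20`, `J = 20`, 10 folds of 2 clips, 126 split-half partitions) are kept
on every function. The simulation studies in the test suite and the
acceptance script run at a desk scale chosen once: 6 clips x 2 s, `F = 18`,
`H = 12`, `R = 20`, `J = 10`, 3 folds of 2 clips (preserving the
whole-2-clip validation structure), a 4-point penalty grid spanning three
decades below the data-driven maximum, and 15-60 split-half partitions.
These sizes keep a 10-seed end-to-end recovery study within minutes while
leaving every protocol element (split structure, selection rule, refit,
evaluation) identical to the full-scale configuration.

## Known limitations

* The proximal optimizer is a deliberate, documented substitute for the
  original sum-of-functions optimizer; objective values are comparable but
  not bitwise-reproducible against other implementations.
* The penalty-recovery trade-off of the L1 objective means the
  cross-validated penalty (optimal for prediction) is often slightly larger
  than the penalty that best recovers ground-truth STRF shapes; matched-STRF
  correlations in recovery studies reflect both estimation noise and this
  shrinkage bias.
* `CC_max` and the EC score implement reconstructions of garbled source
  equations, pinned by their stated anchor properties.
* The WAV reader covers integer PCM and IEEE float RIFF files only (no
  compressed or extensible formats).
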