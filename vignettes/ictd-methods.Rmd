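---
title: "Dual-view eye-movement emotion classification with ictd: model, objectives, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view eye-movement emotion classification with ictd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictd)
```

## The problem

Emotion classification from eye tracking works with two families of signals:
gaze kinematics (fixations, saccades and their statistics) and pupil
dynamics. The two are recorded simultaneously, are driven by the same
underlying affective state, and carry partly complementary noise. `ictd`
treats them as two correlated views of one latent process and classifies
emotion labels from both jointly. The package implements the ICTD model: a
per-view multi-scale CNN + transformer-encoder branch whose feedforward
sublayer is replaced by an *incremental feature feedforward network* (IFFN),
with the two branch representations aligned through a cosine-similarity
deep canonical correlation objective (cos-DCCA) and fused for a softmax
classifier. The joint training loss is

$$L = \omega_1 L_{CE} + \omega_2 L_{DCCA}, \qquad \omega_1 + \omega_2 = 1,$$

with defaults $\omega_1 = 0.1$, $\omega_2 = 0.9$: cross-entropy is
empirically an order of magnitude larger than the alignment term, and the
weighting rebalances the two.

## The alignment objective

Projected views $H_1, H_2 \in \mathbb{R}^{n\times o}$ (samples as rows
throughout this package) are centered per dimension and compared by the
matrix cosine

$$J = \frac{\operatorname{tr}(\bar H_1^{\top} \bar H_2)}
           {\lVert \bar H_1\rVert_F \, \lVert \bar H_2\rVert_F} \in [-1, 1],$$

the cosine of the two matrices flattened to vectors. $J$ is invariant to
positive rescaling of either view, requires no distributional assumptions,
and is bounded, which keeps its gradients tame. The training loss is $-J$:
the sign is chosen so that *minimizing* the joint loss *maximizes*
cross-view similarity, which is the stated goal of the alignment step; the
similarity itself would otherwise be driven down by the optimizer.

Two subtleties are handled explicitly:

* **Mean-pairwise vs Frobenius form.** The per-sample mean cosine
  $\tfrac1n \sum_i \cos(h_1^{(i)}, h_2^{(i)})$ and the Frobenius form above
  are distinct quantities. The Frobenius form is the canonical objective
  here (it is the one whose gradient the training path uses and the one the
  loss definition matches); the per-sample mean is available through
  `matrix_cosine_objective(..., form = "mean_pairwise")`.
* **Gradient forms.** The exact gradient of $J$ is
  $$\frac{\partial J}{\partial \bar H_1}
    = \frac{\bar H_2}{\lVert\bar H_1\rVert_F \lVert\bar H_2\rVert_F}
    - J\,\frac{\bar H_1}{\lVert\bar H_1\rVert_F^{2}},$$
  and symmetrically for $\bar H_2$. A truncated form consisting of only the
  first term is also in circulation; `objective_gradient()` exposes both
  (`"exact"` and `"as_printed"`). They agree exactly when $J = 0$ and
  diverge as $|J|$ grows — at $J = 1$ the exact gradient vanishes by
  stationarity while the truncated form does not. Training uses `"exact"`.

On outlier robustness: the direction-over-magnitude argument for cosine
similarity applies to the *per-sample* cosine, which is exactly invariant
to rescaling a sample pair; the test suite demonstrates that a 100×
magnitude outlier barely moves the mean-pairwise objective while it moves a
Pearson-correlation objective substantially. The Frobenius form does *not*
share this property uniformly — a large row dominates its norms — so no
such claim is made for it.

## The network

Each view passes through:

1. **Conv stack.** Two same-padded 1-D convolutions (kernel 3) with ReLU,
   `d_in -> 64 -> 128` channels, preserving the timestep count.
2. **Multi-scale pooling.** Average-pooling kernels
   {8, 16, 32, 64, 128, 256, 512} (clamped to the sequence length) produce
   temporally smoothed copies, each upsampled back by nearest-neighbor
   repetition. How the copies merge is unspecified in the source
   description; the package averages them with the unpooled map, which
   keeps 128 channels and the timestep count. At `T = 1` the whole step is
   the identity.
3. **Positional encoding.** Standard sinusoidal encoding added (not
   concatenated) to the channels.
4. **Encoder blocks.** Two blocks of 8-head self-attention and the IFFN,
   each with residual connection, layer normalization and dropout 0.3.
5. **Fusion + head.** Timestep-mean pooling, concatenation of the two
   views (256 dims), linear map, stable softmax. The pooled 128-dim branch
   outputs are also the inputs of the cos-DCCA loss.

**IFFN.** `u = GELU(W1 · PConv(x))`; `u` splits into channel halves
`(u1, u2)`; `r = u1 ⊗ DepthwiseConv(u2)` gates the first half by local
spatial weights extracted from the second; the output is
`GELU(W2 · [r; u2])`. Width bookkeeping is a genuine design choice: the
split halves the width to 64, while both projections are stated as
128 × 128. Concatenating the gated product with the gate branch restores
width 128, keeping both projections square. The gate convolution is
depthwise with kernel 3 (unstated in the source; depthwise keeps the gate
per-channel and cheap). GELU is the exact Gaussian form `x * pnorm(x)`.
`PConv` convolves only the leading `ceil(0.25 · C)` channels and passes the
rest through bit-identically; with a validity mask it renormalizes by the
number of valid inputs under the kernel (out-of-range taps count as
ordinary zero padding, so an all-valid mask reproduces plain convolution).

**Sequence axis.** Feature-table trials enter as single-timestep sequences
(`T = 1`, `D` channels per view): the conv stack degenerates to pointwise
linear maps and attention over one key is the value path, so the
architecture stays well-defined. Raw sequences (`T = samples`) use the same
code with real temporal extent. This resolves the tension between an
`N × D` data model and a temporal-convolution architecture by supporting
both explicitly.

**Interpreting the IFFN input.** The algorithmic description references an
autoencoder reconstruction of the input that is defined nowhere else; by
default the IFFN consumes the attention sublayer output directly, and
`model_config(iffn_autoencoder = TRUE)` inserts a linear `d -> d/2 -> d`
bottleneck for users who want that reading. Only an encoder path exists —
a transformer decoder is mentioned once in the source description but never
specified, so none is built.

## Training and evaluation

Adam (betas 0.9/0.999, learning rate 5e-4, batch 128, decoupled weight
decay 0.01), with a single ×0.1 learning-rate step at half the epoch budget
— a decay *rate* of 0.1 is specified without a schedule, and one step at
mid-run is the simplest schedule consistent with it. The DCCA term is
computed per minibatch on that batch's pooled representations (centering
within the batch), standard stochastic DCCA practice. A NaN loss aborts
with a diagnostic rather than training through it.

Cross-validation is **subject-independent**: folds partition subjects, not
trials, so no subject contributes to both sides of any fold; with 5 folds
each model trains on 80% of subjects. This makes the 80/20 5-fold statement
and subject independence hold simultaneously. The 95% CI on accuracy is a
normal approximation over fold accuracies (mean ± 1.96·sd/√k; the CI style
is reported without a named method in the source, and per-fold spread is
what the harness has). Macro-F1 is the unweighted mean of per-class F1;
the averaging convention is unstated in the source tables, and macro is the
conservative choice under class imbalance. ±std values are across folds,
and are labelled as such.

The ablation harness trains four variants under identical fold assignments
and seeds: full model, IFFN replaced by a plain two-layer FFN of matched
width, alignment weight forced to zero (CE-only), and both. With
$\omega_2 = 0$ the alignment term is still computed and logged but its
zero-weighted gradient contributes exact zeros, so parameters evolve
bit-identically to a run without it.

## The synthetic-data generator

`generate_dual_modality()` draws, per trial, a latent point
$\mu_{class} + z$ with $z \sim \mathcal N(0, I)$ in `latent_dim`
dimensions, maps it into each view through a fixed seeded Gaussian loading
matrix, adds a per-subject offset (drawn once per subject) and per-view
Gaussian noise. Class means sit on a regular simplex with pairwise distance
`class_separation`, so separability is controlled exactly; loading matrices
are drawn once per spec so closed-form oracles stay computable. The
per-subject offset is the simplest mechanism that makes subject-independent
splitting non-trivial: a trial-level splitter would leak subject identity
into training.

The generator emulates: two views driven by one latent class structure,
controllable cross-view correlation (for 1-D latents with unit loadings and
noise sd $\sigma$, the analytic cross-view correlation is
$1/(1+\sigma^2)$), subject-level shifts, and class imbalance-free labels.
It does **not** emulate: heavy-tailed or skewed feature distributions,
temporal autocorrelation inside trials, label noise, device artifacts, or
the oculomotor main sequence. Passing tests therefore demonstrate that the
machinery is correct and that the method behaves as designed under its own
assumptions — not that the printed accuracies on any external recordings
are reproduced.

`generate_gaze_stream()` builds raw streams from explicit plans
(alternating fixations and saccades, optional blinks) with half-open
`[onset, offset)` intervals, so a 500 ms fixation at 100 Hz yields exactly
50 samples and the event detector can be scored against exact ground truth.
Saccades are constant-velocity ramps; fixational scatter is isotropic
Gaussian. These streams exercise the detector and the feature formulas,
nothing more.

## Feature extraction choices

The event detector is I-VT (velocity threshold, default 30 units/s; minimum
fixation 60 ms, minimum saccade 10 ms, all exposed): no detector is named
in the source, and I-VT is the simplest defensible choice for clean
threshold semantics. Undersized segments merge into their larger
non-blink neighbor; invalid runs become blinks and break segments.

Moment conventions (all switchable, defaults documented): population
variance (`ddof = 0`), Fisher *excess* kurtosis ($m_4/m_2^2 - 3$), adjusted
Fisher-Pearson skewness ($G_1$). CV is sd/mean and is reported missing when
the mean is zero. "Average saccade latency" is read as the mean gap between
consecutive saccade onsets — the quantity is not defined in the source, and
this is a documented package choice, not a reconstruction of intent.
Dispersion keeps input position units (X and Y ranges; their sum is the
scalar dispersion). The pupil series averages the two eyes where both are
valid. Features whose events are absent are emitted missing, never
fabricated, and `impute_median()` fills them from training-split medians
before modeling. ANOVA screening retains features with one-way ANOVA
`p < 0.05` across label groups (computed via `stats::oneway.test` with
equal variances); zero-within-group-variance features get `p = 0` by the
limit argument, and constant features are dropped with a recorded reason.

## Numerical choices

* Norm guards: `eps = 1e-12` inside cosine norms during training; strict
  mode (errors on zero vectors/views) for library use.
* CCA oracle ridge: `1e-8` on covariance diagonals.
* Softmax and cross-entropy use max-subtraction and a `1e-12` log floor.
* Layer normalization uses `eps = 1e-5`.
* All randomness flows from explicit seeds; identical spec + seed is
  byte-identical, and two CLI runs with the same config and seed produce
  identical metrics.

## Problem sizes used by the test-suite and acceptance runs

Chosen as the package's own desk-scale study conditions: separable-recovery
runs use 4 classes, 20 subjects × 100 trials (n = 2000), class separation 8,
noise sd 0.5, 12 training epochs; the ablation-direction experiment uses 4
classes, 10 subjects × 100 trials (n = 1000), class separation 2.5, noise
sd 2.5, subject shift 1, and the full 50-epoch budget — with cross-entropy
carrying only weight 0.1, the aligned model converges more slowly, and
comparisons at a fraction of the budget measure optimization speed rather
than the value of alignment. Correlation-recovery checks use n = 10,000 at
the 1-D closed form.

## Known limitations

* CPU-only and written for desk-scale experiments; the reverse-mode engine
  favors clarity over throughput, and long raw sequences (large `T`) pay
  an O(T²) attention cost per sample.
* The Frobenius-form objective is not robust to large-magnitude outlier
  rows (see above); the mean-pairwise form is, but is not the training
  default.
* Subject effects in the generator are additive offsets; real
  inter-individual variability also changes feature covariance, which the
  generator does not model.
* The 95% CI is a normal approximation over few folds and should be read
  as a spread summary, not a calibrated interval.
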