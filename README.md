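# ictd

Dual-view eye-movement emotion classification in R: a CNN–transformer with
an incremental feature feedforward network (IFFN) and cosine-similarity
deep canonical correlation alignment (cos-DCCA).

## What this package is for

Affective-computing studies record gaze kinematics (fixations, saccades)
and pupil dynamics while participants watch emotion-eliciting stimuli, and
ask whether the emotion class can be decoded from the oculomotor signals
alone. `ictd` is for researchers running that kind of analysis. It treats
the gaze-derived features and the pupil-derived features as two correlated
views of one latent affective state and trains a dual-branch network that

1. encodes each view with a multi-scale CNN (kernel-3 conv stack,
   `d → 64 → 128` channels, average-pooling pyramids) followed by a
   2-layer, 8-head transformer encoder whose feedforward sublayer is the
   IFFN — a partial-convolution projection, channel split, and elementwise
   cross-channel gating that re-weights salient features;
2. aligns the two 128-dim branch representations by maximizing the matrix
   cosine between the centered views,

   J = tr(H̄₁ᵀ H̄₂) / (‖H̄₁‖_F ‖H̄₂‖_F) ∈ [−1, 1],

   through the loss L = ω₁·L_CE + ω₂·(−J) with ω₁ = 0.1, ω₂ = 0.9;
3. fuses the views by concatenation into a softmax classifier, evaluated
   with subject-independent k-fold cross-validation (no subject appears in
   both train and test of any fold).

The package also ships the surrounding pipeline: raw gaze preprocessing
(gap interpolation, smoothing), I-VT fixation/saccade/blink detection,
both standard eye-movement feature dialects (SEED-style mean/sd + event
statistics; eSEE-d-style moments with CV/kurtosis/skewness), one-way ANOVA
feature screening at p < 0.05, Russell arousal/valence label mapping, a
closed-form linear CCA oracle, an ablation harness, and a synthetic
dual-view generator with known latent class structure so everything is
testable without external recordings. Training runs on CPU via a small
reverse-mode autodiff engine included in the package.

## Worked example

```r
library(ictd)

# 4 emotion classes, 20 subjects x 100 trials, well-separated latent
# classes observed through noisy gaze (16-dim) and pupil (8-dim) views
spec <- synthetic_spec(n_classes = 4, n_subjects = 20,
                       trials_per_subject = 100, class_separation = 8,
                       noise_sd = c(0.5, 0.5), seed = 3)
ds <- generate_dual_modality(spec)

folds <- subject_kfold_split(ds, folds = 5, seed = 1)
fit <- train_ictd(ds, model_config(), train_config(epochs = 12, seed = 1),
                  folds[[1]])
tail(fit$log, 2)
#>    epoch    lr       loss         ce       dcca val_accuracy
#> 11    11 5e-05 -0.7819240 0.02801765 -0.8719176            1
#> 12    12 5e-05 -0.7853758 0.02829529 -0.8757837            1

evaluate(fit$model, ds, folds[[1]]$test_idx)
#> accuracy 1.0000, macro-F1 1.0000 (n = 400)
```

The log shows the joint loss and its two components: `ce` is the mean
cross-entropy (≈0.03: the classifier is nearly certain and correct) and
`dcca` is −J (≈−0.88: the two views' representations are strongly aligned).
`val_accuracy` is accuracy on the held-out subjects of the fold — here 1.0
because the classes were generated well-separated. On the alignment side
alone, the linear specialization of the projection networks recovers the
closed-form CCA solution:

```r
oracle <- linear_cca_oracle(ds$gaze_view, ds$pupil_view, k = 1)
oracle$correlations
#> [1] 0.9959618
```

A command-line interface covers the same pipeline
(`simulate`, `extract`, `screen`, `train`, `evaluate`, `ablate`):

```sh
Rscript inst/cli/ictd simulate --classes 4 --subjects 10 --seed 7 --out d/
Rscript inst/cli/ictd train    --data d/ --out m/ --epochs 30
Rscript inst/cli/ictd evaluate --model m/ --data d/ --out e/
```

## Method and design notes

The methods vignette (`vignettes/ictd-methods.Rmd`) documents the model
and objective in full, the gradient forms of the cosine objective (exact
vs truncated), the IFFN width bookkeeping, the sequence-axis convention
for feature-table vs raw-sequence input, moment and detector conventions,
the generator's assumptions, and known limitations.
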