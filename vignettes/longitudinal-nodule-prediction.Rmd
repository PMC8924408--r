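---
title: "Predicting pulmonary nodule malignancy from irregular longitudinal CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pulmonary nodule malignancy from irregular longitudinal CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmoseq)
```

## The problem

A pulmonary nodule seen on a screening CT may be benign or an early lung
cancer, and the single most informative sign is how it evolves across
follow-up scans. Clinical follow-up, however, is irregular: one patient
returns after six weeks, another after a year. A growth of 2 mm means
something very different in those two situations, so a sequence model for
this task should see not only *what* each scan shows but *when* it was
acquired.

`pulmoseq` implements a two-stage architecture for this setting:

1. **Multiscale 3D CNN feature extraction.** Each visit's scan is reduced
   to two nodule-centered 3D patches, 30x30x10 and 40x40x10 voxels; the
   smaller receptive field frames small nodules with context, the larger
   one bounds nearly all nodules. Each patch passes through its own
   three-convolution branch ending in a 256-D feature layer, and the two
   feature vectors are concatenated (late fusion) into a 512-D visit
   descriptor. Each branch also carries a 2-class softmax head used to
   train it.
2. **Time-modulated LSTM (T-LSTM).** The per-visit descriptors enter a
   recurrent model whose forget, input and output gates and candidate
   update each receive the elapsed time `delta_t` between consecutive
   visits through a learned weight vector:
   `f_t = sigma(W_fl l_{t-1} + W_fx x_t + W_fj delta_t + b_f)`, and
   analogously for the other gates. The cell state starts at zero,
   updates as `c_t = f_t * c_{t-1} + i_t * c~_t`, and emits
   `y_t = o_t * tanh(c_t)`. A sigmoid head on the final visit's output
   yields the malignancy probability. Setting every `W_.j` to zero
   recovers a standard, time-blind LSTM — which doubles as the baseline
   and as an exact equivalence oracle for testing.

Class imbalance (malignant nodules are the minority in screening) is
handled by a focal-style loss: cross-entropy modulated by `(1-p)^gamma`
and a class weight `alpha`, which down-weights easy examples. Defaults
are `alpha = 0.25`, `gamma = 2`; both are ordinary tuning knobs.

## Reading of the cell equations

The published form of the cell update conflates the cell and hidden
state symbols and writes the candidate term ambiguously. We adopt the
only reading consistent with a standard gated recurrent cell: the
recurrent quantity is the cell state `c_t` (initialized to zero), the
candidate in the update is the `tanh` candidate of the fourth gate
equation, and the emitted output `y_t = o_t * tanh(c_t)` is *not* fed
back into the gates — the gates see the fused image features, the
previous-visit label and the time lapse only. The reduction to a
textbook LSTM when the time weights vanish is enforced by a test that
compares against an independently written LSTM.

## Preprocessing choices

* **Slab window.** The 10-slice slab around the annotated center slice
  is `[k-5, k+4]`: the center slice is kept and the fifth trailing slice
  dropped, because the network input depth is fixed at 10, which rules
  out a symmetric 11-slice window.
* **Out-of-bounds handling.** Edge replication, not zero fill: a nodule
  near the lung apex should not acquire an artificial black border that
  shifts its intensity statistics.
* **z resampling.** Linear interpolation between bracketing slices; with
  `n` slices at spacing `s` resampled to `t` the output has
  `floor((n-1)s/t) + 1` slices and the first slice is preserved exactly.
  Resampling to the source spacing is the identity, and a
  half-spacing round trip restores the original voxels to float
  tolerance — both are tested invariants.
* **Intensity window.** Hounsfield data default to the standard lung
  window `(-1000, 400)`, mapped affinely onto `[0, 1]`. Synthetic
  volumes are already on `[0, 1]` and use the window `(0, 1)`.
* **Coordinates.** 0-based indices, half-open bounding boxes
  `[top_left, bottom_right)`; the box center is the integer mean of the
  corners.
* **Time lapses.** `delta_t` is measured in days from the visit dates
  and divided by 30 before entering the gates (i.e. expressed in
  months), keeping gate pre-activations in a reasonable range for
  multi-year follow-up; a `log1p` variant is available via
  `tlstm_init(delta_log = TRUE)`.

## Network details

Both branches use "same" zero padding and stride 1 for all convolutions
and 2x2x2 max pooling with floor division after the first and second
convolution, so the depth axis survives two poolings (10 -> 5 -> 2).
ReLU follows every convolution; batch normalization (per channel) sits
between each convolution and its ReLU. The FC feature layer is
regularized by dropout (applied before it during training) and an
optional max-norm constraint on its weight rows, rather than by batch
normalization — with small minibatches, feature-wise batch statistics on
a 256-D layer are noisy, while dropout + max-norm is the conventional
pairing for such layers. Kernel sizes follow the published table
verbatim, including the asymmetric 5/2/3 progression of the small-scale
branch against 5/5/2 for the large-scale one. Probabilities are clipped
to `[1e-7, 1 - 1e-7]` inside the loss to avoid `log(0)`.

All forward and backward passes are implemented in the package: the 3D
convolution is im2col + BLAS matrix multiplication (C++), and gradients
for every layer and for the T-LSTM (backpropagation through time) are
analytic. Correctness is guarded by finite-difference checks — a
fourth-order central stencil, with the relative-error denominator
floored at a fraction of the overall gradient scale so that numerical
noise on exactly-zero gradients is not mistaken for a defect.

## Label feedback, not teacher forcing

The gates receive the previous visit's radiological label `l_{t-1}`. In
a research cohort the only available label is the per-patient
benign/malignant diagnosis, which is constant across a patient's visits
and identical to the prediction target. Teacher-forcing that label
during training therefore hands the network the answer: in our
experiments the training loss collapsed to ~1e-5 while autoregressive
inference collapsed to a constant. `train_tlstm()` consequently defaults
to *detached autoregressive feedback*: the label input of visit `t` is
the model's own probability at visit `t-1` (starting from the
uninformative prior 0.5), treated as a constant in the backward pass, so
training matches the inference-time regime. Classic teacher forcing
remains available (`label_input = "teacher"`) for settings with genuine
per-visit labels.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions used throughout the
tests: per patient, 3-5 visits at irregular intervals drawn uniformly
from 30-180 days; one nodule per patient, rendered as an isotropic
Gaussian-profile blob (peak 1.0, FWHM = diameter) at a fixed random
position on zero-mean Gaussian noise (sd 0.1); baseline diameter 6 ± 2
voxels across patients; benign nodules static, malignant nodules growing
linearly at 0.3 voxels per 30 days; half of the patients malignant. The
baseline-diameter jitter matters: it prevents absolute size at any
single visit from separating the classes, so the discriminative signal
is the *growth rate*, which can only be read off together with the
elapsed time — precisely the signal the T-LSTM's time gates can exploit
and a time-blind LSTM cannot. A `regular_intervals` mode fixes every gap
at the interval midpoint, removing all information from the visit
timing, and a zero-growth setting makes the classes indistinguishable
(the null control, where any classifier's AUROC should be at chance).

The simulator does **not** attempt CT realism: no lung texture,
vasculature, pleural attachment or spiculation, no scanner physics, and
intensities on an abstract `[0, 1]` scale rather than Hounsfield units.
Passing the synthetic benchmark demonstrates that the architecture and
optimization behave as designed — that time gating extracts interval
information when it is informative and is harmless when it is not — but
says nothing about accuracy on clinical data, which requires the
original access-restricted cohorts.

## Problem sizes and defaults

The benchmark configuration (`run_config()`) trains width-scaled
branches (channels 2/4/8, 8-D features per branch, 16-D fused) for 2
epochs with Adam (lr 1e-3, batch 16), then a single-layer T-LSTM with
16 hidden units for 40 epochs (lr 1e-2), on cohorts of 200 patients
split 60/10/30 by patient. These sizes were chosen so a full benchmark
(two models x five seeds x two interval regimes, plus the null control)
completes in minutes on one CPU core while leaving the contrast between
the two recurrent models clearly measurable; the full-size architecture
(`width_scale = 1`, `hidden_size = 64`, `n_layers = 4`) is what the
contracts in the test suite exercise for shape and determinism. The
train/validation/test split uses a larger test share than the 80/10/10
screening-trial convention (which remains the `split_dataset()` default)
because with 200 patients a 10% test set would make the AUROC
comparison too coarse.

Metrics follow the screening literature: sensitivity, specificity,
accuracy, F1 at threshold 0.5; AUROC by the Mann-Whitney rank statistic
(equal to the trapezoidal area under the empirical ROC, a tested
identity); specificity at a sensitivity floor of 0.87 over empirical
thresholds only; and 95% percentile bootstrap confidence intervals from
2000 patient-level resamples. Ties at probability exactly 0.5 predict
malignant — the recall-favouring choice in a screening context.

## Known limitations

* The CNN and the T-LSTM are trained in two stages (features are frozen
  before the recurrent stage); joint fine-tuning is not implemented.
* Per-visit probabilities are emitted, but only the final visit is
  scored and trained on.
* Single-threaded CPU implementation; full-width training on real
  cohort sizes is out of scope (the full-width networks are exercised
  in forward mode by the architecture contracts).
* The preprocessed dataset lives in memory (serialize with `saveRDS()`
  if needed); volumes are read from NIfTI, and manifests are plain CSV.
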