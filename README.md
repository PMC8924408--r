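# pulmoseq

Longitudinal pulmonary nodule malignancy prediction from irregular CT
follow-up, for researchers in medical image analysis who need a fully
testable implementation of time-aware sequence modelling on 3D imaging —
with no access-restricted data required.

## What it implements

A screening patient is followed with CT at irregular intervals; whether a
nodule is growing — and how fast relative to the time elapsed — is the key
malignancy signal. `pulmoseq` provides the complete two-stage pipeline:

* **Preprocessing** — z-axis linear resampling of slice stacks,
  nodule-centered multiscale 3D slabs (30×30×10 and 40×40×10 voxels, the
  10 slices `[k−5, k+4]` around the annotated center, edge-replicated at
  boundaries), Hounsfield windowing onto [0, 1], and visit sequences with
  day-resolution time lapses from a CSV manifest + NIfTI volumes.
* **Two-branch multiscale 3D CNN** — per branch, three convolutions
  (kernels 5/2/3 at the small scale, 5/5/2 at the large; channels
  64/128/256 at full width) with batch-norm, ReLU and two 2×2×2 max-pools,
  ending in a 256-D feature layer and a 2-class softmax head; the two
  feature vectors are concatenated into a 512-D visit descriptor (late
  fusion). Training minimizes the focal loss

  ```
  J(θ) = −(1/m) Σᵢ [ α·yᵢ·(1−pᵢ)^γ·log pᵢ + (1−α)·(1−yᵢ)·pᵢ^γ·log(1−pᵢ) ]
  ```

  with defaults α = 0.25, γ = 2.
* **Time-modulated LSTM (T-LSTM)** — gates that each receive the elapsed
  time δₜ between visits:

  ```
  fₜ = σ(W_fl·lₜ₋₁ + W_fx·x̂ₜ + W_fj·δₜ + b_f)        (forget; i, o analogous)
  c̃ₜ = tanh(W_cl·lₜ₋₁ + W_cx·x̂ₜ + W_cj·δₜ + b_c)     (candidate)
  cₜ = fₜ ∘ cₜ₋₁ + iₜ ∘ c̃ₜ,   yₜ = oₜ ∘ tanh(cₜ),   c₀ = 0
  ```

  with a sigmoid head on the final visit. Zeroing every `W_·j`
  (`as_standard_lstm()`) yields the time-blind standard-LSTM baseline.
* **Synthetic cohort simulator** — Gaussian-blob nodules on noisy
  background; benign = static diameter, malignant = linear growth in
  calendar time, with jittered baselines so only the *growth rate* (growth
  per elapsed time) separates the classes. This makes visit timing
  genuinely informative and the T-LSTM-vs-LSTM contrast falsifiable.
* **Evaluation** — patient-level splits, sensitivity/specificity/
  accuracy/F1, rank-statistic AUROC, specificity at a sensitivity floor
  (0.87), and 2000-replicate patient-level bootstrap 95% CIs.

All neural-network forward *and* backward passes (im2col 3D convolution,
batch-norm, pooling, dense layers, backpropagation through time for the
T-LSTM) are implemented in the package in R/C++ and verified against
independent oracles and finite differences in the test suite.

## Worked example

Simulate a cohort of 80 patients, train the two CNN branches and the
T-LSTM, and evaluate on the held-out test patients:

```r
library(pulmoseq)

params  <- sim_params(n_patients = 80)          # 3-5 visits, 30-180 day gaps
cohort  <- simulate_cohort(params, seed = 1)
dataset <- cohort_to_sequences(cohort, window = c(0, 1))

fit <- train_model(dataset, run_config(seed = 1))
ev  <- evaluate_model(fit, "test")
print(ev$metrics)
#> <metrics_report> n = 24
#>   sensitivity 0.583  specificity 0.917  accuracy 0.750  F1 0.700
#>   AUROC 0.924 [0.797, 1.000]
#>   spec @ sens>=0.87: 0.833 [0.470, 1.000]
```

The report reads: of the 24 test patients, the model ranks malignant above
benign cases with probability 0.924 (AUROC, bootstrap CI in brackets); at
the default 0.5 threshold it recovers 58% of malignant and 92% of benign
patients; if one instead operates at ≥ 0.87 sensitivity, 83% specificity
is attainable. Small-cohort CIs are wide by design.

The head-to-head comparison that motivates the architecture:

```r
bench <- benchmark_tlstm(sim_params(), seeds = 0:4, config = run_config())
median(bench$auroc_tlstm) >= median(bench$auroc_lstm)   # time gating helps
```

A thin CLI covering simulate / train / eval / gradcheck is installed at
`inst/cli/pulmoseq`.

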