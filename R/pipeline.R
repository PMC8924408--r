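#' Patient-level train/validation/test split
#'
#' Uniform random split of patient identifiers into disjoint, exhaustive
#' groups. Splitting is always by patient, so no visit of one patient can
#' land in two splits. Group sizes are `floor(f * n)` with the remainder
#' assigned by largest fractional part, so 100 patients at (0.8, 0.1, 0.1)
#' give exactly (80, 10, 10).
#'
#' @param ids vector of patient identifiers (unique).
#' @param fractions positive fractions summing to 1.
#' @param seed integer seed; the split is deterministic under it.
#' @return A list of id vectors, one per fraction (named train/val/test for
#'   three fractions).
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be positive and sum to 1")
  }
  n <- length(ids)
  if (n < length(fractions)) stop("fewer patients than splits")
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_part <- fractions * n - sizes
    bump <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1L
  }
  perm <- with_seed(seed, sample(ids))
  out <- vector("list", length(fractions))
  at <- 0L
  for (i in seq_along(fractions)) {
    out[[i]] <- perm[(at + 1L):(at + sizes[i])]
    at <- at + sizes[i]
  }
  if (length(fractions) == 3L) names(out) <- c("train", "val", "test")
  out
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param probs predicted scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, with tied scores contributing 1/2; `NA` with
#'   a warning when only one class is present.
#' @export
auroc <- function(probs, labels) {
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Empirical ROC curve coordinates
#'
#' Sweeps the empirical thresholds (each observed score, plus one above the
#' maximum) with the decision rule `score >= threshold` and returns the
#' (FPR, TPR) staircase from (0,0) to (1,1).
#'
#' @inheritParams auroc
#' @return Data frame with `threshold`, `fpr`, `tpr`, sorted by increasing
#'   FPR.
#' @export
roc_points <- function(probs, labels) {
  th <- c(sort(unique(probs), decreasing = TRUE), -Inf)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(probs >= t & labels == 1) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(probs >= t & labels == 0) / N, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

# Specificity at the best operating point whose sensitivity >= floor,
# over empirical thresholds only (no interpolation).
spec_at_sens <- function(probs, labels, sens_floor = 0.87) {
  th <- sort(unique(probs))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  best <- 0
  for (t in th) {
    sens <- sum(probs >= t & labels == 1) / P
    if (sens >= sens_floor) {
      spec <- sum(probs < t & labels == 0) / N
      if (spec > best) best <- spec
    }
  }
  best
}

#' Classification metrics with bootstrap confidence intervals
#'
#' Computes sensitivity, specificity, accuracy and F1 at the given
#' probability threshold, the AUROC by the rank statistic, the specificity
#' at a sensitivity floor (default 0.87) over empirical thresholds, and
#' percentile bootstrap confidence intervals (patient-level resampling)
#' for AUROC and specificity-at-sensitivity.
#'
#' @param probs per-patient predicted probabilities.
#' @param labels 0/1 labels, same length.
#' @param threshold decision threshold (predict 1 when `prob >= threshold`).
#' @param sens_floor sensitivity floor of the SPC@SEN operating point.
#' @param n_boot bootstrap replicates (0 disables the CIs).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5,
                            sens_floor = 0.87, n_boot = 2000L,
                            conf = 0.95, seed = 0L) {
  if (length(probs) != length(labels)) stop("probs/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0 && !is.na(sens)) {
    2 * prec * sens / (prec + sens)
  } else {
    0
  }
  auc <- auroc(probs, labels)
  sas <- if (!is.na(auc)) spec_at_sens(probs, labels, sens_floor) else
    NA_real_

  ci_auc <- c(NA_real_, NA_real_)
  ci_sas <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !is.na(auc)) {
    bs_auc <- numeric(0)
    bs_sas <- numeric(0)
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(length(probs), replace = TRUE)
        lb <- labels[idx]
        if (sum(lb == 1) == 0 || sum(lb == 0) == 0) next
        pb <- probs[idx]
        bs_auc <- c(bs_auc, auroc(pb, lb))
        bs_sas <- c(bs_sas, spec_at_sens(pb, lb, sens_floor))
      }
    })
    a <- (1 - conf) / 2
    if (length(bs_auc) > 0) {
      ci_auc <- unname(quantile(bs_auc, c(a, 1 - a)))
      ci_sas <- unname(quantile(bs_sas, c(a, 1 - a)))
    }
  }
  structure(
    list(
      sensitivity = sens, specificity = spec, accuracy = acc, f1 = f1,
      auroc = auc,
      spec_at_sens = c(sens_floor = sens_floor, specificity = sas),
      ci95_auroc = ci_auc, ci95_spec_at_sens = ci_sas,
      threshold = threshold, n = length(labels), seed = seed
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("<metrics_report> n = %d\n",
           "  sensitivity %.3f  specificity %.3f  accuracy %.3f  F1 %.3f\n",
           "  AUROC %.3f [%.3f, %.3f]\n",
           "  spec @ sens>=%.2f: %.3f [%.3f, %.3f]\n"),
    x$n, x$sensitivity, x$specificity, x$accuracy, x$f1,
    x$auroc, x$ci95_auroc[1], x$ci95_auroc[2],
    x$spec_at_sens["sens_floor"], x$spec_at_sens["specificity"],
    x$ci95_spec_at_sens[1], x$ci95_spec_at_sens[2]
  ))
  invisible(x)
}

#' Convert a simulated cohort into preprocessed visit sequences
#'
#' Runs every patient of a [simulate_cohort()] result through the
#' preprocessing module: optional z resampling, nodule-centered multiscale
#' slab extraction and intensity windowing. Simulated intensities live on
#' `[0, 1]` (blob peak 1), so the default window is `(0, 1)`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param window intensity window.
#' @param target_spacing_mm optional z spacing to resample to first.
#' @return A list with `sequences` (list of `visit_sequence`), `labels` and
#'   `patient_ids`.
#' @export
cohort_to_sequences <- function(cohort, window = c(0, 1),
                                target_spacing_mm = NULL) {
  n <- length(cohort$patients)
  seqs <- vector("list", n)
  labels <- integer(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    pat <- cohort$patients[[i]]
    rows <- cohort$manifest[cohort$manifest$patient_id == pat$patient_id, ,
                            drop = FALSE]
    series <- pat$series
    if (!is.null(target_spacing_mm)) {
      series <- lapply(series, resample_z, target_spacing_mm)
    }
    seqs[[i]] <- build_visit_sequence(rows, series, window = window)
    labels[i] <- pat$label
    ids[i] <- pat$patient_id
  }
  list(sequences = seqs, labels = labels, patient_ids = ids)
}

# Eval-mode branch features for a list of patches, batched for speed.
branch_features_batch <- function(net, patches, batch_size = 64L) {
  n <- length(patches)
  out <- matrix(0, net$config$fc_dim, n)
  shp <- net$config$input_shape
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(0, dim = c(shp, 1L, length(idx)))
    for (j in seq_along(idx)) xb[, , , 1L, j] <- patches[[idx[j]]]
    out[, idx] <- branch_forward(net, xb, training = FALSE)$features
  }
  out
}

#' Fused feature sequences from trained CNN branches
#'
#' Forward-passes every visit's small and large patch through the
#' respective branch in eval mode and concatenates the two feature vectors
#' (late fusion), preserving the per-visit time lapses.
#'
#' @param dataset result of [cohort_to_sequences()].
#' @param net30,net40 trained [build_branch()] networks for the 30- and
#'   40-voxel scales.
#' @return List of feature sequences; each visit holds `x` (fused feature)
#'   and `delta_days`.
#' @export
extract_feature_sequences <- function(dataset, net30, net40) {
  visits_per_seq <- vapply(dataset$sequences, length, integer(1))
  small <- list()
  large <- list()
  for (s in dataset$sequences) {
    small <- c(small, lapply(s, `[[`, "small30"))
    large <- c(large, lapply(s, `[[`, "large40"))
  }
  f30 <- branch_features_batch(net30, small)
  f40 <- branch_features_batch(net40, large)
  out <- vector("list", length(dataset$sequences))
  at <- 0L
  for (i in seq_along(out)) {
    nv <- visits_per_seq[i]
    vis <- vector("list", nv)
    for (v in seq_len(nv)) {
      vis[[v]] <- list(
        x = fuse(f30[, at + v], f40[, at + v]),
        delta_days = dataset$sequences[[i]][[v]]$delta_days
      )
    }
    out[[i]] <- vis
    at <- at + nv
  }
  out
}

#' Default run configuration
#'
#' Settings for the two-stage training pipeline: the CNN branches are
#' trained first on per-visit patches with the focal loss, then the T-LSTM
#' is trained on the frozen fused features with teacher forcing. The
#' defaults describe the small-scale configuration used for synthetic
#' cohorts (narrow branches via `width_scale`); set `width_scale = 1`,
#' `hidden_size = 64`, `n_layers = 4` for the full-size architecture.
#'
#' @param width_scale CNN channel-width multiplier (1 = full Table-size).
#' @param epochs_cnn,epochs_lstm training epochs for the two stages.
#' @param lr_cnn,lr_lstm Adam learning rates.
#' @param batch_size minibatch size for both stages.
#' @param alpha,gamma focal-loss parameters.
#' @param hidden_size,n_layers T-LSTM dimensions.
#' @param dropout CNN dropout rate before the FC layer.
#' @param use_batchnorm CNN batch normalization switch.
#' @param maxnorm CNN max-norm constraint (`Inf` disables).
#' @param time_gated `FALSE` trains the standard-LSTM baseline instead.
#' @param split train/val/test fractions (by patient).
#' @param seed global seed for initialization, shuffling and the split.
#' @return A `run_config` list.
#' @export
run_config <- function(width_scale = 1 / 32, epochs_cnn = 2,
                       epochs_lstm = 40, lr_cnn = 1e-3, lr_lstm = 1e-2,
                       batch_size = 16, alpha = 0.25, gamma = 2,
                       hidden_size = 16, n_layers = 1, dropout = 0.2,
                       use_batchnorm = TRUE, maxnorm = 2.0,
                       time_gated = TRUE, split = c(0.6, 0.1, 0.3),
                       seed = 0L) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(
    list(
      width_scale = width_scale, epochs_cnn = epochs_cnn,
      epochs_lstm = epochs_lstm, lr_cnn = lr_cnn, lr_lstm = lr_lstm,
      batch_size = batch_size, alpha = alpha, gamma = gamma,
      hidden_size = hidden_size, n_layers = n_layers, dropout = dropout,
      use_batchnorm = use_batchnorm, maxnorm = maxnorm,
      time_gated = time_gated, split = split, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# Train the two CNN branches on the training split's per-visit patches.
train_branches <- function(dataset, train_ids, config) {
  tr <- dataset$patient_ids %in% train_ids
  patches30 <- list()
  patches40 <- list()
  labels <- integer(0)
  for (i in which(tr)) {
    s <- dataset$sequences[[i]]
    patches30 <- c(patches30, lapply(s, `[[`, "small30"))
    patches40 <- c(patches40, lapply(s, `[[`, "large40"))
    labels <- c(labels, rep(dataset$labels[i], length(s)))
  }
  if (length(labels) == 0L) stop("empty training split")
  cfg30 <- branch_config("archi1", dropout = config$dropout,
                         use_batchnorm = config$use_batchnorm,
                         maxnorm = config$maxnorm,
                         width_scale = config$width_scale)
  cfg40 <- branch_config("archi2", dropout = config$dropout,
                         use_batchnorm = config$use_batchnorm,
                         maxnorm = config$maxnorm,
                         width_scale = config$width_scale)
  net30 <- build_branch(cfg30, seed = config$seed + 1L)
  net40 <- build_branch(cfg40, seed = config$seed + 2L)
  net30 <- train_branch(net30, patches30, labels,
                        epochs = config$epochs_cnn, lr = config$lr_cnn,
                        batch_size = config$batch_size,
                        alpha = config$alpha, gamma = config$gamma,
                        seed = config$seed + 3L)
  net40 <- train_branch(net40, patches40, labels,
                        epochs = config$epochs_cnn, lr = config$lr_cnn,
                        batch_size = config$batch_size,
                        alpha = config$alpha, gamma = config$gamma,
                        seed = config$seed + 4L)
  list(net30 = net30, net40 = net40)
}

#' Train the full two-stage model on a preprocessed dataset
#'
#' Stage 1 trains each CNN branch on the training split's per-visit patches
#' with the focal loss; stage 2 extracts frozen fused features and trains
#' the T-LSTM (or, with `time_gated = FALSE`, the standard-LSTM baseline)
#' on the training split's sequences with teacher forcing.
#'
#' @param dataset result of [cohort_to_sequences()] (or an equivalently
#'   shaped list).
#' @param config a [run_config()].
#' @return A `checkpoint` list with the trained networks, the patient
#'   split, the feature sequences and the config.
#' @export
train_model <- function(dataset, config = run_config()) {
  splits <- split_dataset(dataset$patient_ids, config$split,
                          seed = config$seed + 7L)
  nets <- train_branches(dataset, splits$train, config)
  feats <- extract_feature_sequences(dataset, nets$net30, nets$net40)
  tr <- which(dataset$patient_ids %in% splits$train)
  model <- tlstm_init(
    input_dim = 2L * nets$net30$config$fc_dim,
    hidden_size = config$hidden_size, n_layers = config$n_layers,
    seed = config$seed + 5L
  )
  if (!config$time_gated) model <- as_standard_lstm(model)
  model <- train_tlstm(model, feats[tr], dataset$labels[tr],
                       epochs = config$epochs_lstm, lr = config$lr_lstm,
                       batch_size = config$batch_size,
                       alpha = config$alpha, gamma = config$gamma,
                       seed = config$seed + 6L)
  structure(
    list(net30 = nets$net30, net40 = nets$net40, tlstm = model,
         splits = splits, features = feats, config = config,
         patient_ids = dataset$patient_ids, labels = dataset$labels),
    class = "checkpoint"
  )
}

#' Evaluate a trained checkpoint on one split
#'
#' Predicts the final-visit malignancy probability for every patient of
#' the chosen split and computes the metric report and ROC coordinates.
#'
#' @param checkpoint a [train_model()] result.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param n_boot bootstrap replicates for the CIs.
#' @return List with `metrics` (a `metrics_report`), `roc` (data frame),
#'   `probs` and `labels`.
#' @export
evaluate_model <- function(checkpoint, split = "test", n_boot = 2000L) {
  ids <- checkpoint$splits[[split]]
  idx <- which(checkpoint$patient_ids %in% ids)
  probs <- predict_tlstm(checkpoint$tlstm, checkpoint$features[idx])
  labels <- checkpoint$labels[idx]
  list(
    metrics = compute_metrics(probs, labels, n_boot = n_boot,
                              seed = checkpoint$config$seed),
    roc = roc_points(probs, labels),
    probs = probs, labels = labels
  )
}

#' Synthetic T-LSTM versus standard-LSTM benchmark
#'
#' For each seed: simulate a cohort, preprocess it, train the CNN branches
#' once, then train a T-LSTM and a standard LSTM (time-lapse weights pinned
#' to zero) from the same initialization on the same frozen features, and
#' record both test AUROCs. The two recurrent models differ only in the
#' time gating, so the comparison isolates the value of the visit-interval
#' information.
#'
#' @param params a [sim_params()] object describing the cohort.
#' @param seeds integer vector of simulation/training seeds.
#' @param config a [run_config()] (its `time_gated` field is ignored).
#' @param n_boot bootstrap replicates for the per-seed reports (0 = none).
#' @return Data frame with one row per seed: `auroc_tlstm`, `auroc_lstm`.
#' @export
benchmark_tlstm <- function(params = sim_params(), seeds = 0:4,
                            config = run_config(), n_boot = 0L) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(params, seed = s)
    dataset <- cohort_to_sequences(cohort, window = c(0, 1))
    # free the raw volumes; only the patches are needed from here on
    cohort$patients <- NULL

    splits <- split_dataset(dataset$patient_ids, cfg$split,
                            seed = cfg$seed + 7L)
    nets <- train_branches(dataset, splits$train, cfg)
    feats <- extract_feature_sequences(dataset, nets$net30, nets$net40)
    tr <- which(dataset$patient_ids %in% splits$train)
    te <- which(dataset$patient_ids %in% splits$test)

    base <- tlstm_init(
      input_dim = 2L * nets$net30$config$fc_dim,
      hidden_size = cfg$hidden_size, n_layers = cfg$n_layers,
      seed = cfg$seed + 5L
    )
    fit_t <- train_tlstm(base, feats[tr], dataset$labels[tr],
                         epochs = cfg$epochs_lstm, lr = cfg$lr_lstm,
                         batch_size = cfg$batch_size, alpha = cfg$alpha,
                         gamma = cfg$gamma, seed = cfg$seed + 6L)
    fit_l <- train_tlstm(as_standard_lstm(base), feats[tr],
                         dataset$labels[tr],
                         epochs = cfg$epochs_lstm, lr = cfg$lr_lstm,
                         batch_size = cfg$batch_size, alpha = cfg$alpha,
                         gamma = cfg$gamma, seed = cfg$seed + 6L)
    yt <- dataset$labels[te]
    data.frame(
      seed = s,
      auroc_tlstm = auroc(predict_tlstm(fit_t, feats[te]), yt),
      auroc_lstm = auroc(predict_tlstm(fit_l, feats[te]), yt)
    )
  })
  do.call(rbind, rows)
}

#' Save / load a checkpoint with a JSON sidecar
#'
#' The checkpoint itself is a binary RDS file; a human-readable `.json`
#' sidecar records the run configuration and seed.
#'
#' @param checkpoint a [train_model()] result.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    sidecar <- sub("\\.rds$", ".json", path)
    jsonlite::write_json(unclass(checkpoint$config), sidecar,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
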