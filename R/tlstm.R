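#' Initialize a time-modulated LSTM (T-LSTM) model
#'
#' The T-LSTM is an LSTM variant for irregularly sampled visit sequences:
#' each gate receives, in addition to the fused image feature vector
#' \eqn{\hat X_t} and the previous-visit label \eqn{l_{t-1}}, the elapsed
#' time \eqn{\delta_t} between consecutive visits through a learned weight
#' vector. The gate equations are
#' \deqn{f_t = \sigma(W_{fl} l_{t-1} + W_{fx} \hat X_t + W_{fj}\delta_t + b_f)}
#' and analogously for the input gate \eqn{i_t}, output gate \eqn{o_t} and
#' candidate \eqn{\tilde c_t = \tanh(\cdot)}; the cell state updates as
#' \eqn{c_t = f_t \circ c_{t-1} + i_t \circ \tilde c_t} and the emitted
#' output is \eqn{y_t = o_t \circ \tanh(c_t)}. The initial cell state is
#' zero. Setting every \eqn{W_{\cdot j}} to zero recovers a standard
#' (time-blind) LSTM, which serves as the baseline.
#'
#' Layers can be stacked; layer k > 1 receives the previous layer's output
#' as its feature input, and every layer receives \eqn{l_{t-1}} and
#' \eqn{\delta_t}. A sigmoid head on the top layer's final output gives the
#' malignancy probability.
#'
#' @param input_dim dimension D of the fused feature vector (512 for the
#'   full-width two-branch CNN).
#' @param hidden_size hidden width H of each layer.
#' @param label_dim dimension L of the previous-visit label input
#'   (1 = binary).
#' @param n_layers number of stacked T-LSTM layers.
#' @param delta_scale multiplier applied to the visit gap (in days) before
#'   it enters the gates; the default 1/30 expresses gaps in months.
#' @param delta_log if `TRUE`, use `log1p(days) * delta_scale` instead of
#'   the linear transform.
#' @param init_sd standard deviation of the Gaussian weight initialization.
#' @param seed RNG seed for initialization.
#' @return An object of class `tlstm`.
#' @export
tlstm_init <- function(input_dim, hidden_size = 64L, label_dim = 1L,
                       n_layers = 4L, delta_scale = 1 / 30,
                       delta_log = FALSE, init_sd = 0.1, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_size >= 1, label_dim >= 1, n_layers >= 1)
  H <- as.integer(hidden_size)
  L <- as.integer(label_dim)
  gates <- c("f", "i", "o", "c")
  layers <- vector("list", n_layers)
  with_seed(seed, {
    for (k in seq_len(n_layers)) {
      D <- if (k == 1L) as.integer(input_dim) else H
      lay <- list()
      for (g in gates) {
        lay[[paste0("W_", g, "l")]] <- matrix(rnorm(H * L, sd = init_sd), H, L)
        lay[[paste0("W_", g, "x")]] <- matrix(rnorm(H * D, sd = init_sd), H, D)
        lay[[paste0("W_", g, "j")]] <- matrix(rnorm(H, sd = init_sd), H, 1)
        lay[[paste0("b_", g)]] <- numeric(H)
      }
      layers[[k]] <- lay
    }
    head_w <- rnorm(H, sd = init_sd)
  })
  structure(
    list(
      input_dim = as.integer(input_dim), hidden_size = H, label_dim = L,
      n_layers = as.integer(n_layers),
      layers = layers,
      head = list(w = head_w, b = 0),
      delta_scale = delta_scale, delta_log = isTRUE(delta_log),
      time_gated = TRUE
    ),
    class = "tlstm"
  )
}

transform_delta <- function(model, delta_days) {
  if (model$delta_log) log1p(delta_days) * model$delta_scale
  else delta_days * model$delta_scale
}

#' One T-LSTM cell step
#'
#' Applies the gate equations of one layer to a single time step.
#'
#' @param params one layer's weights (an element of `model$layers`).
#' @param state list with `cell` (length-H cell state) and `output`; the
#'   initial state has `cell = 0`.
#' @param x feature input vector.
#' @param l previous-visit label vector (length L).
#' @param delta transformed nonnegative time lapse (scalar).
#' @return List with the new `state` (`cell`, `output`) and the
#'   `gates` (`f`, `i`, `o`, `c_tilde`).
#' @export
cell_step <- function(params, state, x, l, delta) {
  H <- length(params$b_f)
  if (ncol(params$W_fx) != length(x)) stop("feature input has wrong length")
  if (ncol(params$W_fl) != length(l)) stop("label input has wrong length")
  if (length(state$cell) != H) stop("cell state has wrong length")
  if (!all(is.finite(x)) || !all(is.finite(l)) || !is.finite(delta)) {
    stop("non-finite input to cell_step")
  }
  pre <- function(g) {
    as.numeric(params[[paste0("W_", g, "l")]] %*% l +
               params[[paste0("W_", g, "x")]] %*% x +
               params[[paste0("W_", g, "j")]] * delta +
               params[[paste0("b_", g)]])
  }
  f <- plogis(pre("f"))
  i <- plogis(pre("i"))
  o <- plogis(pre("o"))
  c_tilde <- tanh(pre("c"))
  cell <- f * state$cell + i * c_tilde
  output <- o * tanh(cell)
  list(
    state = list(cell = cell, output = output),
    gates = list(f = f, i = i, o = o, c_tilde = c_tilde)
  )
}

#' Unroll a T-LSTM over one patient's visit sequence
#'
#' Initializes every layer's cell state to zero, applies [cell_step()] in
#' visit order, and maps the top layer's output at each visit through a
#' sigmoid head to a malignancy probability. The final prediction is 1 when
#' the last-visit probability is >= 0.5 (ties predict malignant, the
#' recall-favouring choice in a screening context).
#'
#' @param model a [tlstm_init()] model.
#' @param visits list of visits, each a list with `x` (feature vector of
#'   length `input_dim`) and `delta_days` (0 for the first visit).
#' @param l_inputs optional numeric vector of teacher-forced label inputs
#'   \eqn{l_{t-1}} (length = number of visits, first element the
#'   uninformative prior 0.5). When `NULL` the model runs autoregressively,
#'   feeding its own previous-visit probability.
#' @param keep_cache retain intermediates for backpropagation.
#' @return List with `probs` (per-visit probabilities), `prob` (final), and
#'   `prediction` (0/1).
#' @export
unroll <- function(model, visits, l_inputs = NULL, keep_cache = FALSE) {
  Tn <- length(visits)
  if (Tn < 1L) stop("empty visit sequence")
  if (visits[[1]]$delta_days != 0) stop("first visit must have delta = 0")
  H <- model$hidden_size
  K <- model$n_layers
  states <- replicate(K, list(cell = numeric(H), output = numeric(H)),
                      simplify = FALSE)
  probs <- numeric(Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  l_prev <- if (is.null(l_inputs)) 0.5 else l_inputs[1]

  for (t in seq_len(Tn)) {
    if (!is.null(l_inputs) && t > 1L) l_prev <- l_inputs[t]
    delta <- transform_delta(model, visits[[t]]$delta_days)
    xk <- visits[[t]]$x
    step_cache <- if (keep_cache) vector("list", K) else NULL
    for (k in seq_len(K)) {
      st <- cell_step(model$layers[[k]], states[[k]], xk, l_prev, delta)
      if (keep_cache) {
        step_cache[[k]] <- list(
          x = xk, l = l_prev, delta = delta,
          cell_prev = states[[k]]$cell,
          gates = st$gates, cell = st$state$cell, output = st$state$output
        )
      }
      states[[k]] <- st$state
      xk <- st$state$output
    }
    z <- sum(model$head$w * states[[K]]$output) + model$head$b
    probs[t] <- plogis(z)
    if (keep_cache) {
      cache[[t]] <- list(layers = step_cache, y_top = states[[K]]$output)
    }
    if (is.null(l_inputs)) l_prev <- probs[t]
  }
  out <- list(
    probs = probs,
    prob = probs[Tn],
    prediction = as.integer(probs[Tn] >= 0.5)
  )
  if (keep_cache) out$cache <- cache
  out
}

#' Reduce a T-LSTM to a standard (time-blind) LSTM
#'
#' Returns a copy of the model with every time-lapse gate weight
#' \eqn{W_{\cdot j}} set to zero and time gating disabled for any further
#' training, so the unrolled model is invariant to the visit gaps.
#'
#' @param model a [tlstm_init()] model.
#' @return The reduced model (idempotent).
#' @export
as_standard_lstm <- function(model) {
  for (k in seq_len(model$n_layers)) {
    for (g in c("f", "i", "o", "c")) {
      model$layers[[k]][[paste0("W_", g, "j")]][] <- 0
    }
  }
  model$time_gated <- FALSE
  model
}

# ---- parameter flattening (for Adam and finite differences) --------------

tlstm_flatten <- function(model) {
  out <- list()
  for (k in seq_len(model$n_layers)) {
    for (nm in names(model$layers[[k]])) {
      out[[sprintf("l%d.%s", k, nm)]] <- model$layers[[k]][[nm]]
    }
  }
  out[["head.w"]] <- model$head$w
  out[["head.b"]] <- model$head$b
  out
}

tlstm_unflatten <- function(model, flat) {
  for (k in seq_len(model$n_layers)) {
    for (nm in names(model$layers[[k]])) {
      model$layers[[k]][[nm]][] <- flat[[sprintf("l%d.%s", k, nm)]]
    }
  }
  model$head$w <- as.numeric(flat[["head.w"]])
  model$head$b <- as.numeric(flat[["head.b"]])
  model
}

# Backpropagation through time for one sequence. `dprob` is dJ/d(final
# probability). Returns a flat gradient list matching tlstm_flatten().
tlstm_backward <- function(model, visits, cache, final_prob, dprob) {
  K <- model$n_layers
  H <- model$hidden_size
  Tn <- length(cache)
  grads <- lapply(tlstm_flatten(model), function(p) p * 0)

  dz <- dprob * final_prob * (1 - final_prob)
  grads[["head.w"]] <- dz * cache[[Tn]]$y_top
  grads[["head.b"]] <- dz
  # dy for the top layer at the final step; zero elsewhere (final-visit loss)
  dy_next <- replicate(K, numeric(H), simplify = FALSE)
  dy_next[[K]] <- dz * model$head$w
  dcell <- replicate(K, numeric(H), simplify = FALSE)

  for (t in Tn:1) {
    dy_t <- dy_next
    dy_next <- replicate(K, numeric(H), simplify = FALSE)
    for (k in K:1) {
      cc <- cache[[t]]$layers[[k]]
      g <- cc$gates
      tc <- tanh(cc$cell)
      dy <- dy_t[[k]]
      do_ <- dy * tc
      dc <- dcell[[k]] + dy * g$o * (1 - tc^2)
      df <- dc * cc$cell_prev
      di <- dc * g$c_tilde
      dct <- dc * g$i
      dcell[[k]] <- dc * g$f
      da <- list(
        f = df * g$f * (1 - g$f),
        i = di * g$i * (1 - g$i),
        o = do_ * g$o * (1 - g$o),
        c = dct * (1 - g$c_tilde^2)
      )
      dx <- numeric(length(cc$x))
      for (gn in c("f", "i", "o", "c")) {
        a <- da[[gn]]
        pre <- sprintf("l%d.", k)
        grads[[paste0(pre, "W_", gn, "x")]] <-
          grads[[paste0(pre, "W_", gn, "x")]] + outer(a, cc$x)
        grads[[paste0(pre, "W_", gn, "l")]] <-
          grads[[paste0(pre, "W_", gn, "l")]] + outer(a, cc$l)
        grads[[paste0(pre, "W_", gn, "j")]] <-
          grads[[paste0(pre, "W_", gn, "j")]] + matrix(a * cc$delta, ncol = 1)
        grads[[paste0(pre, "b_", gn)]] <-
          grads[[paste0(pre, "b_", gn)]] + a
        dx <- dx + as.numeric(crossprod(model$layers[[k]][[
          paste0("W_", gn, "x")]], a))
      }
      if (k > 1L) dy_t[[k - 1L]] <- dy_t[[k - 1L]] + dx
    }
  }
  grads
}

#' Finite-difference gradient check of the T-LSTM
#'
#' Compares the analytic backpropagation gradient of the focal loss on the
#' final-visit probability against central finite differences over every
#' weight, and returns the maximum relative error
#' `|ga - gn| / max(1e-8, |ga| + |gn|)`.
#'
#' @param model a [tlstm_init()] model.
#' @param visits visit list as in [unroll()].
#' @param y true label (0/1) for the sequence.
#' @param l_inputs teacher-forced label inputs (see [unroll()]); defaults
#'   to `c(0.5, rep(y, T-1))`.
#' @param alpha,gamma focal-loss parameters.
#' @param h finite-difference step.
#' @return Maximum relative error across all parameters.
#' @export
gradient_check <- function(model, visits, y, l_inputs = NULL,
                           alpha = 0.25, gamma = 2, h = 1e-5) {
  if (is.null(l_inputs)) l_inputs <- c(0.5, rep(y, length(visits) - 1L))
  fw <- unroll(model, visits, l_inputs = l_inputs, keep_cache = TRUE)
  dprob <- focal_loss_grad(fw$prob, y, alpha, gamma)
  ga <- tlstm_backward(model, visits, fw$cache, fw$prob, dprob)

  flat <- tlstm_flatten(model)
  loss_at <- function(fp) {
    lm <- unroll(tlstm_unflatten(model, fp), visits, l_inputs = l_inputs)
    focal_loss(lm$prob, y, alpha, gamma)
  }
  # floor the denominator at a fraction of the overall gradient scale so
  # that finite-difference noise on exactly-zero gradients (e.g. gates that
  # never open) does not masquerade as a mismatch
  gmax <- max(vapply(ga, function(g) max(abs(g)), numeric(1)), 1e-8)
  max_err <- 0
  for (nm in names(flat)) {
    p <- flat[[nm]]
    for (j in seq_along(p)) {
      # fourth-order central stencil: truncation O(h^4) keeps the
      # difference quotient accurate even for ~1e-6 gradients
      fp <- flat
      fp[[nm]][j] <- p[j] + 2 * h; l_p2 <- loss_at(fp)
      fp[[nm]][j] <- p[j] + h;     l_p1 <- loss_at(fp)
      fp[[nm]][j] <- p[j] - h;     l_m1 <- loss_at(fp)
      fp[[nm]][j] <- p[j] - 2 * h; l_m2 <- loss_at(fp)
      gn <- (-l_p2 + 8 * l_p1 - 8 * l_m1 + l_m2) / (12 * h)
      gaj <- ga[[nm]][j]
      err <- abs(gaj - gn) / max(1e-4 * gmax, abs(gaj) + abs(gn))
      if (err > max_err) max_err <- err
    }
  }
  max_err
}

#' Train a T-LSTM on fused feature sequences
#'
#' Minimizes the focal loss on the final-visit probability with Adam. The
#' previous-visit label input \eqn{l_{t-1}} is fed autoregressively by
#' default (the model's own previous-visit probability, treated as a
#' constant in the backward pass), matching how the model runs at
#' inference; `label_input = "teacher"` instead teacher-forces the
#' ground-truth label. With a per-patient benign/malignant label the
#' teacher signal equals the prediction target, so teacher forcing lets
#' the network copy the label input and learn nothing about the images —
#' hence the autoregressive default. For a model reduced with
#' [as_standard_lstm()], the time-lapse weights stay pinned at zero so the
#' baseline remains time-blind.
#'
#' @param model a [tlstm_init()] model.
#' @param sequences list of visit lists (see [unroll()]).
#' @param labels 0/1 patient labels parallel to `sequences`.
#' @param epochs,lr,batch_size optimization settings.
#' @param alpha,gamma focal-loss parameters.
#' @param label_input `"autoregressive"` (default) or `"teacher"`.
#' @param seed RNG seed for shuffling.
#' @return The trained model with a `history` of per-epoch mean losses.
#' @export
train_tlstm <- function(model, sequences, labels, epochs = 30, lr = 1e-2,
                        batch_size = 16, alpha = 0.25, gamma = 2,
                        label_input = c("autoregressive", "teacher"),
                        seed = 1L) {
  label_input <- match.arg(label_input)
  if (length(sequences) != length(labels)) stop("sequences/labels mismatch")
  if (length(sequences) == 0L) stop("empty training set")
  flat <- tlstm_flatten(model)
  opt <- adam_init(flat, lr = lr)
  history <- numeric(0)
  zero_j <- grep("W_.j", names(flat), value = TRUE)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(sequences))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        acc <- lapply(flat, function(p) p * 0)
        bl <- 0
        for (s in idx) {
          visits <- sequences[[s]]
          yv <- labels[s]
          li <- if (label_input == "teacher") {
            c(0.5, rep(yv, length(visits) - 1L))
          } else {
            NULL
          }
          fw <- unroll(model, visits, l_inputs = li, keep_cache = TRUE)
          bl <- bl + focal_loss(fw$prob, yv, alpha, gamma)
          dprob <- focal_loss_grad(fw$prob, yv, alpha, gamma)
          g <- tlstm_backward(model, visits, fw$cache, fw$prob, dprob)
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
        if (!model$time_gated) for (nm in zero_j) acc[[nm]][] <- 0
        st <- adam_step(opt, flat, acc)
        opt <- st$state
        flat <- st$params
        if (!model$time_gated) for (nm in zero_j) flat[[nm]][] <- 0
        model <- tlstm_unflatten(model, flat)
        losses <- c(losses, bl / length(idx))
      }
      history <- c(history, mean(losses))
    }
  })
  model$history <- history
  model
}

#' Predict malignancy probabilities for feature sequences
#'
#' Runs the model autoregressively (the label input of each visit is the
#' model's previous-visit probability, starting from the uninformative
#' prior 0.5) and returns the final-visit probability per patient.
#'
#' @param model a trained [tlstm_init()] model.
#' @param sequences list of visit lists (see [unroll()]).
#' @return Numeric vector of final-visit malignancy probabilities.
#' @export
predict_tlstm <- function(model, sequences) {
  vapply(sequences, function(v) unroll(model, v)$prob, numeric(1))
}
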