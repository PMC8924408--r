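# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: plain R loops and textbook formulas.

# Naive 3-D "same" convolution (stride 1, zero padding, even kernels padded
# on the far edge), matching the layout of the package's weight matrix.
naive_conv3d <- function(x, Wm, b, k) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  Cout <- ncol(Wm)
  pad <- (k - 1) %/% 2
  out <- array(0, c(H, W, D, Cout))
  for (co in 1:Cout) for (h in 1:H) for (w in 1:W) for (dd in 1:D) {
    s <- 0
    for (ci in 1:Cin) for (kz in 0:(k - 1)) for (kx in 0:(k - 1))
      for (ky in 0:(k - 1)) {
        ih <- h + ky - pad; iw <- w + kx - pad; id <- dd + kz - pad
        xv <- if (ih >= 1 && ih <= H && iw >= 1 && iw <= W &&
                  id >= 1 && id <= D) x[ih, iw, id, ci] else 0
        q <- ky + k * (kx + k * (kz + k * (ci - 1))) + 1
        s <- s + xv * Wm[q, co]
      }
    out[h, w, dd, co] <- s + b[co]
  }
  out
}

# Textbook LSTM unroll without any time-lapse input, written directly from
# the gate equations; used as the equivalence oracle for the reduced model.
naive_lstm <- function(layers, head, xs, ls, n_layers) {
  H <- length(layers[[1]]$b_f)
  states <- replicate(n_layers, numeric(H), simplify = FALSE)
  probs <- numeric(length(xs))
  for (t in seq_along(xs)) {
    inp <- xs[[t]]
    for (k in seq_len(n_layers)) {
      lay <- layers[[k]]
      f <- 1 / (1 + exp(-(lay$W_fl %*% ls[t] + lay$W_fx %*% inp + lay$b_f)))
      i <- 1 / (1 + exp(-(lay$W_il %*% ls[t] + lay$W_ix %*% inp + lay$b_i)))
      o <- 1 / (1 + exp(-(lay$W_ol %*% ls[t] + lay$W_ox %*% inp + lay$b_o)))
      ct <- tanh(lay$W_cl %*% ls[t] + lay$W_cx %*% inp + lay$b_c)
      states[[k]] <- as.numeric(f) * states[[k]] + as.numeric(i) *
        as.numeric(ct)
      inp <- as.numeric(o) * tanh(states[[k]])
    }
    probs[t] <- 1 / (1 + exp(-(sum(head$w * inp) + head$b)))
  }
  probs
}

# Central finite differences of f at x (numeric vector/array), step h.
fd_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# A small synthetic series whose slice z holds the constant value z-1
# (0-based), handy for asserting which slices a slab picked up.
slice_index_series <- function(n_slices = 64L, nrow = 60L, ncol = 60L,
                               spacing = 1) {
  vol <- array(rep(seq_len(n_slices) - 1L, each = nrow * ncol),
               dim = c(nrow, ncol, n_slices))
  ct_series(vol, spacing)
}

# Random T-LSTM visit sequences for property tests.
random_visits <- function(Tn, D, delta_max = 300) {
  lapply(seq_len(Tn), function(t) {
    list(x = rnorm(D),
         delta_days = if (t == 1L) 0 else runif(1, 1, delta_max))
  })
}
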