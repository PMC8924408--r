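# Minimal all-zero single-layer parameter set used by several tests.
zero_cell_params <- function(H = 1, D = 1, L = 1) {
  out <- list()
  for (g in c("f", "i", "o", "c")) {
    out[[paste0("W_", g, "l")]] <- matrix(0, H, L)
    out[[paste0("W_", g, "x")]] <- matrix(0, H, D)
    out[[paste0("W_", g, "j")]] <- matrix(0, H, 1)
    out[[paste0("b_", g)]] <- numeric(H)
  }
  out
}

test_that("zero-parameter cell step gives sigma(0)/tanh(0) gate values", {
  p <- zero_cell_params(H = 3, D = 2)
  st <- cell_step(p, list(cell = numeric(3), output = numeric(3)),
                  x = c(1, -2), l = 0, delta = 7)
  expect_equal(st$gates$f, rep(0.5, 3))
  expect_equal(st$gates$i, rep(0.5, 3))
  expect_equal(st$gates$o, rep(0.5, 3))
  expect_equal(st$gates$c_tilde, rep(0, 3))
  expect_equal(st$state$cell, rep(0, 3))
  expect_equal(st$state$output, rep(0, 3))
})

test_that("scalar cell step reproduces the hand-evaluated gate equations", {
  p <- zero_cell_params()
  p$W_fx[] <- 1; p$W_ix[] <- 1; p$W_ox[] <- 1; p$W_cx[] <- 1
  st <- cell_step(p, list(cell = 1, output = 0), x = 1, l = 0, delta = 0)
  # independent hand evaluation: f=i=o=sigma(1), c~=tanh(1),
  # cell' = f*1 + i*c~, output = o*tanh(cell')
  s1 <- plogis(1)
  cellp <- s1 * 1 + s1 * tanh(1)
  expect_equal(st$state$cell, cellp, tolerance = 1e-12)
  expect_equal(st$state$output, s1 * tanh(cellp), tolerance = 1e-12)
  # frozen oracle values
  expect_equal(st$state$cell, 1.2878292, tolerance = 1e-6)
  expect_equal(st$state$output, 0.6276553, tolerance = 1e-6)
})

test_that("a two-step scalar sequence matches sequential hand evaluation", {
  p <- zero_cell_params()
  p$W_fx[] <- 1; p$W_ix[] <- 1; p$W_ox[] <- 1; p$W_cx[] <- 1
  s1 <- plogis(1); c1 <- tanh(1)
  cell1 <- s1 * 0 + s1 * c1            # from zero initial cell
  cell2 <- s1 * cell1 + s1 * c1
  st1 <- cell_step(p, list(cell = 0, output = 0), 1, 0, 0)
  st2 <- cell_step(p, st1$state, 1, 0, 0)
  expect_equal(st1$state$cell, cell1, tolerance = 1e-12)
  expect_equal(st2$state$cell, cell2, tolerance = 1e-12)
  expect_equal(st2$state$output, s1 * tanh(cell2), tolerance = 1e-12)
})

test_that("cell_step validates shapes and finiteness", {
  p <- zero_cell_params(H = 2, D = 3)
  st0 <- list(cell = numeric(2), output = numeric(2))
  expect_error(cell_step(p, st0, x = c(1, 2), l = 0, delta = 0), "length")
  expect_error(cell_step(p, list(cell = 0, output = 0), rnorm(3), 0, 0),
               "wrong length")
  expect_error(cell_step(p, st0, c(1, 2, NaN), 0, 0), "finite")
})

test_that("gate activations stay in their ranges on random inputs", {
  set.seed(31)
  m <- tlstm_init(6, hidden_size = 5, n_layers = 2, seed = 8, init_sd = 0.5)
  for (rep in 1:25) {
    visits <- random_visits(4, 6)
    st <- list(cell = rnorm(5), output = rnorm(5))
    g <- cell_step(m$layers[[1]], st, visits[[2]]$x, runif(1),
                   runif(1, 0, 6))$gates
    expect_true(all(g$f > 0 & g$f < 1))
    expect_true(all(g$i > 0 & g$i < 1))
    expect_true(all(g$o > 0 & g$o < 1))
    expect_true(all(g$c_tilde > -1 & g$c_tilde < 1))
  }
})

test_that("unroll of the zero model gives probability 0.5 and predicts 1", {
  m <- tlstm_init(4, hidden_size = 3, n_layers = 1, seed = 1)
  for (k in seq_along(m$layers)) {
    for (nm in names(m$layers[[k]])) m$layers[[k]][[nm]][] <- 0
  }
  m$head$w[] <- 0; m$head$b <- 0
  visits <- random_visits(3, 4)
  out <- unroll(m, visits)
  expect_equal(out$probs, rep(0.5, 3))
  expect_equal(out$prediction, 1L)   # >= 0.5 tie rule
})

test_that("single-visit unroll equals one cell step plus head", {
  set.seed(32)
  m <- tlstm_init(5, hidden_size = 4, n_layers = 1, seed = 3)
  v <- list(list(x = rnorm(5), delta_days = 0))
  out <- unroll(m, v, l_inputs = 0.5)
  st <- cell_step(m$layers[[1]],
                  list(cell = numeric(4), output = numeric(4)),
                  v[[1]]$x, 0.5, 0)
  expect_equal(out$prob,
               plogis(sum(m$head$w * st$state$output) + m$head$b),
               tolerance = 1e-12)
  expect_error(unroll(m, list()), "empty")
  expect_error(unroll(m, list(list(x = rnorm(5), delta_days = 3))), "delta")
})

test_that("with zero time weights the T-LSTM is an ordinary LSTM", {
  set.seed(33)
  m <- tlstm_init(6, hidden_size = 4, n_layers = 2, seed = 9)
  red <- as_standard_lstm(m)
  expect_false(red$time_gated)
  expect_identical(red, as_standard_lstm(red))  # idempotent

  for (rep in 1:20) {
    visits <- random_visits(4, 6)
    li <- c(0.5, rep(1, 3))
    got <- unroll(red, visits, l_inputs = li)$probs
    ref <- naive_lstm(red$layers, red$head,
                      lapply(visits, `[[`, "x"), li, red$n_layers)
    expect_equal(got, ref, tolerance = 1e-14)
    # delta-invariance of the reduced model
    shifted <- lapply(visits, function(v) {
      v$delta_days <- v$delta_days + runif(1, 0, 500)
      v
    })
    shifted[[1]]$delta_days <- 0
    expect_equal(unroll(red, shifted, l_inputs = li)$probs, got,
                 tolerance = 1e-14)
  }
})

test_that("nonzero time weights make the unroll depend on the gaps", {
  set.seed(34)
  m <- tlstm_init(6, hidden_size = 4, n_layers = 1, seed = 10)
  visits1 <- random_visits(3, 6)
  visits2 <- lapply(visits1, function(v) { v$delta_days <- v$delta_days * 3; v })
  visits2[[1]]$delta_days <- 0
  p1 <- unroll(m, visits1, l_inputs = c(0.5, 1, 1))$probs
  p2 <- unroll(m, visits2, l_inputs = c(0.5, 1, 1))$probs
  expect_gt(max(abs(p1 - p2)), 1e-8)
})

test_that("backpropagation matches central finite differences", {
  set.seed(35)
  for (layers in 1:2) {
    m <- tlstm_init(6, hidden_size = 4, n_layers = layers, seed = 40 + layers)
    visits <- random_visits(3, 6)
    err <- gradient_check(m, visits, y = 1)
    # deeper stacks carry some parameters with ~1e-6 gradients, where the
    # O(h^2) truncation error of central differences dominates the ratio
    expect_lt(err, if (layers == 1) 1e-5 else 1e-4)
  }
  # smooth at the all-zero parameter point too
  m0 <- tlstm_init(4, hidden_size = 3, n_layers = 1, seed = 1, init_sd = 0)
  expect_lt(gradient_check(m0, random_visits(3, 4), y = 0), 1e-5)
})

test_that("the gradient check detects a corrupted cell update", {
  # forward pass with Eq. 6 mis-implemented as cell' = f * cell (candidate
  # term dropped); analytic gradients of the *correct* model must disagree
  # with finite differences of the mutant by a large margin
  set.seed(36)
  m <- tlstm_init(5, hidden_size = 4, n_layers = 1, seed = 50)
  visits <- random_visits(3, 5)
  li <- c(0.5, 1, 1)
  y <- 1

  mutant_loss <- function(model) {
    lay <- model$layers[[1]]
    cell <- numeric(model$hidden_size)
    for (t in seq_along(visits)) {
      d <- visits[[t]]$delta_days / 30
      pre <- function(g) {
        as.numeric(lay[[paste0("W_", g, "l")]] %*% li[t] +
                   lay[[paste0("W_", g, "x")]] %*% visits[[t]]$x +
                   lay[[paste0("W_", g, "j")]] * d +
                   lay[[paste0("b_", g)]])
      }
      f <- plogis(pre("f")); o <- plogis(pre("o"))
      cell <- f * cell                      # dropped i * c_tilde
      out <- o * tanh(cell)
    }
    prob <- plogis(sum(model$head$w * out) + model$head$b)
    focal_loss(prob, y)
  }

  fw <- unroll(m, visits, l_inputs = li, keep_cache = TRUE)
  ga <- pulmoseq:::tlstm_backward(m, visits, fw$cache, fw$prob,
                                  focal_loss_grad(fw$prob, y))
  flat <- pulmoseq:::tlstm_flatten(m)
  h <- 1e-5
  max_err <- 0
  for (nm in c("l1.W_cx", "l1.W_ix", "l1.b_c")) {
    p <- flat[[nm]]
    for (j in seq_along(p)) {
      fp <- flat; fp[[nm]][j] <- p[j] + h
      lp <- mutant_loss(pulmoseq:::tlstm_unflatten(m, fp))
      fp[[nm]][j] <- p[j] - h
      lm <- mutant_loss(pulmoseq:::tlstm_unflatten(m, fp))
      gn <- (lp - lm) / (2 * h)
      err <- abs(ga[[nm]][j] - gn) / max(1e-8, abs(ga[[nm]][j]) + abs(gn))
      max_err <- max(max_err, err)
    }
  }
  expect_gt(max_err, 1e-2)
})

test_that("outputs are bounded by tanh of the cell state", {
  set.seed(37)
  m <- tlstm_init(5, hidden_size = 6, n_layers = 1, seed = 60, init_sd = 0.8)
  visits <- random_visits(5, 5)
  fw <- unroll(m, visits, l_inputs = rep(0.5, 5), keep_cache = TRUE)
  for (t in 1:5) {
    cc <- fw$cache[[t]]$layers[[1]]
    expect_true(all(abs(cc$output) <= abs(tanh(cc$cell)) + 1e-15))
    expect_true(all(abs(cc$output) < 1))
  }
})

test_that("training reduces the loss and respects the time-blind baseline", {
  set.seed(38)
  D <- 4
  mk_seq <- function(label) {
    Tn <- sample(3:4, 1)
    gaps <- c(0, runif(Tn - 1, 30, 300))
    t_days <- cumsum(gaps)
    lapply(seq_len(Tn), function(t) {
      size <- 1 + label * 0.1 * t_days[t] / 30 + rnorm(1, 0, 0.05)
      list(x = c(size, rnorm(D - 1, 0, 0.1)), delta_days = gaps[t])
    })
  }
  labels <- rep(c(0, 1), each = 10)
  seqs <- lapply(labels, mk_seq)
  m <- tlstm_init(D, hidden_size = 6, n_layers = 1, seed = 70)
  fit <- train_tlstm(m, seqs, labels, epochs = 15, lr = 5e-2, seed = 71)
  expect_lt(tail(fit$history, 1), fit$history[1])

  base <- train_tlstm(as_standard_lstm(m), seqs, labels, epochs = 3,
                      lr = 5e-2, seed = 71)
  for (k in seq_len(base$n_layers)) {
    for (g in c("f", "i", "o", "c")) {
      expect_true(all(base$layers[[k]][[paste0("W_", g, "j")]] == 0))
    }
  }
})
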