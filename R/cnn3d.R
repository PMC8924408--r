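#' Configuration of one multiscale 3D CNN branch
#'
#' The two branches share a three-conv + one-FC layout and differ in their
#' receptive field and kernel sizes: `archi1` takes 30x30x10 patches with
#' kernels 5/2/3, `archi2` takes 40x40x10 patches with kernels 5/5/2. Both
#' max-pool (2x2x2, floor division) after the first and second convolution
#' and end in a fully connected feature layer. At full width the channel
#' progression is 64/128/256 with a 256-D feature vector; `width_scale`
#' shrinks every layer proportionally for small-scale experiments while
#' preserving the layout.
#'
#' @param name `"archi1"` or `"archi2"`.
#' @param dropout dropout rate applied before the FC layer during training.
#' @param use_batchnorm apply batch normalization after each convolution.
#' @param maxnorm optional max-norm constraint on FC/head weight rows
#'   (`Inf` disables).
#' @param width_scale multiplier on channel counts and feature width
#'   (1 = full size).
#' @return A `branch_config` list.
#' @export
branch_config <- function(name = c("archi1", "archi2"), dropout = 0.5,
                          use_batchnorm = TRUE, maxnorm = 2.0,
                          width_scale = 1) {
  name <- match.arg(name)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (width_scale <= 0) stop("width_scale must be positive")
  channels <- pmax(1L, as.integer(round(c(64, 128, 256) * width_scale)))
  fc_dim <- max(4L, as.integer(round(256 * width_scale)))
  structure(
    list(
      name = name,
      input_shape = if (name == "archi1") c(30L, 30L, 10L) else
        c(40L, 40L, 10L),
      kernels = if (name == "archi1") c(5L, 2L, 3L) else c(5L, 5L, 2L),
      channels = channels,
      pool_after = c(TRUE, TRUE, FALSE),
      fc_dim = fc_dim,
      dropout = dropout,
      use_batchnorm = isTRUE(use_batchnorm),
      maxnorm = maxnorm
    ),
    class = "branch_config"
  )
}

validate_branch_config <- function(config) {
  if (!inherits(config, "branch_config")) stop("not a branch_config")
  ok_kernels <- if (config$name == "archi1") c(5L, 2L, 3L) else c(5L, 5L, 2L)
  if (!identical(as.integer(config$kernels), ok_kernels)) {
    stop(sprintf("kernels for %s must be (%s)", config$name,
                 paste(ok_kernels, collapse = ",")))
  }
  if (length(config$channels) != 3L || any(config$channels < 1L)) {
    stop("channels must be three positive integers")
  }
  exp_shape <- if (config$name == "archi1") c(30L, 30L, 10L) else
    c(40L, 40L, 10L)
  if (!identical(as.integer(config$input_shape), exp_shape)) {
    stop("input_shape inconsistent with branch name")
  }
  if (!identical(config$pool_after[1:2], c(TRUE, TRUE))) {
    stop("pooling must follow the first and second convolutions")
  }
  invisible(config)
}

# Spatial dims after the conv/pool stack ("same" convs, floor-halving pools).
branch_out_shape <- function(config) {
  shp <- config$input_shape
  for (i in 1:3) if (config$pool_after[i]) shp <- shp %/% 2L
  shp
}

#' Build (initialize) one CNN branch
#'
#' Allocates He-initialized weights for the conv stack, the FC feature layer
#' and the 2-class softmax head described by `config`.
#'
#' @param config a [branch_config()].
#' @param seed integer seed for weight initialization.
#' @param zero_init initialize all weights to zero (diagnostics only).
#' @return A `cnn_branch` object holding `config`, trainable `params` and
#'   batch-norm running statistics.
#' @export
build_branch <- function(config, seed = 1L, zero_init = FALSE) {
  validate_branch_config(config)
  shp <- config$input_shape
  cin <- c(1L, config$channels[1:2])
  params <- list()
  with_seed(seed, {
    for (i in 1:3) {
      k <- config$kernels[i]
      fan_in <- k^3 * cin[i]
      W <- matrix(rnorm(fan_in * config$channels[i], sd = sqrt(2 / fan_in)),
                  fan_in, config$channels[i])
      if (zero_init) W[] <- 0
      params[[paste0("W", i)]] <- W
      params[[paste0("b", i)]] <- numeric(config$channels[i])
      if (config$use_batchnorm) {
        params[[paste0("g", i)]] <- rep(1, config$channels[i])
        params[[paste0("beta", i)]] <- numeric(config$channels[i])
      }
    }
    flat_dim <- prod(branch_out_shape(config)) * config$channels[3]
    Wfc <- matrix(rnorm(flat_dim * config$fc_dim, sd = sqrt(2 / flat_dim)),
                  flat_dim, config$fc_dim)
    Whead <- matrix(rnorm(config$fc_dim * 2, sd = sqrt(2 / config$fc_dim)),
                    config$fc_dim, 2)
    if (zero_init) { Wfc[] <- 0; Whead[] <- 0 }
    params$Wfc <- Wfc
    params$bfc <- numeric(config$fc_dim)
    params$Whead <- Whead
    params$bhead <- numeric(2)
  })
  structure(
    list(
      config = config,
      params = params,
      bn_mean = lapply(config$channels, function(c) numeric(c)),
      bn_var = lapply(config$channels, function(c) rep(1, c)),
      bn_momentum = 0.9
    ),
    class = "cnn_branch"
  )
}

# ---- batch-norm helpers (per-channel over all voxels and samples) --------

bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training, momentum, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  N <- if (length(d) == 5L) d[5] else 1L
  V <- prod(d[1:3])
  dim(x) <- c(V, C, N)
  if (training) {
    mu <- vapply(seq_len(C), function(c) mean(x[, c, ]), numeric(1))
    va <- vapply(seq_len(C), function(c) {
      xc <- x[, c, ]
      mean((xc - mu[c])^2)
    }, numeric(1))
    new_mean <- momentum * running_mean + (1 - momentum) * mu
    new_var <- momentum * running_var + (1 - momentum) * va
  } else {
    mu <- running_mean
    va <- running_var
    new_mean <- running_mean
    new_var <- running_var
  }
  std <- sqrt(va + eps)
  xhat <- x
  for (c in seq_len(C)) xhat[, c, ] <- (x[, c, ] - mu[c]) / std[c]
  y <- xhat
  for (c in seq_len(C)) y[, c, ] <- gamma[c] * xhat[, c, ] + beta[c]
  dim(y) <- d
  list(y = y, xhat = xhat, std = std, dims = d,
       running_mean = new_mean, running_var = new_var)
}

bn_backward <- function(cache, gamma, dy, training) {
  d <- cache$dims
  C <- d[4]
  N <- if (length(d) == 5L) d[5] else 1L
  V <- prod(d[1:3])
  dim(dy) <- c(V, C, N)
  xhat <- cache$xhat
  dx <- dy
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, c, ]
    xc <- xhat[, c, ]
    dgamma[c] <- sum(dyc * xc)
    dbeta[c] <- sum(dyc)
    if (training) {
      dxh <- gamma[c] * dyc
      dx[, c, ] <- (dxh - mean(dxh) - xc * mean(dxh * xc)) / cache$std[c]
    } else {
      dx[, c, ] <- gamma[c] * dyc / cache$std[c]
    }
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward ---------------------------------------------------

as_batch5d <- function(x, input_shape) {
  d <- dim(x)
  if (length(d) == 3L) {
    if (!identical(as.integer(d), as.integer(input_shape))) {
      stop(sprintf("patch shape (%s) does not match branch input (%s)",
                   paste(d, collapse = ","),
                   paste(input_shape, collapse = ",")))
    }
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 5L) {
    if (!identical(as.integer(d[1:3]), as.integer(input_shape)) || d[4] != 1L) {
      stop("batch shape does not match branch input")
    }
  } else {
    stop("input must be a 3-D patch or a 5-D (H,W,D,1,N) batch")
  }
  x
}

#' Forward pass through one CNN branch
#'
#' @param net a [build_branch()] network.
#' @param x a single patch (3-D array matching the branch input shape) or a
#'   5-D `(H,W,D,1,N)` minibatch.
#' @param training use batch statistics / dropout (`TRUE`) or running
#'   statistics with dropout disabled (`FALSE`).
#' @param keep_cache retain intermediates for [branch_backward()].
#' @return A list with `features` (`fc_dim x N`), `probs` (`2 x N` softmax,
#'   row 2 = malignant probability) and, if requested, `cache`.
#' @export
branch_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  x <- as_batch5d(unclass(x), cfg$input_shape)
  storage.mode(x) <- "double"
  N <- dim(x)[5]
  cache <- list(x = x, N = N)

  a <- x
  for (i in 1:3) {
    k <- rep(cfg$kernels[i], 3L)
    cache[[paste0("conv_in", i)]] <- a
    a <- .conv3d_forward(a, p[[paste0("W", i)]], p[[paste0("b", i)]],
                         as.integer(k))
    if (cfg$use_batchnorm) {
      bn <- bn_forward(a, p[[paste0("g", i)]], p[[paste0("beta", i)]],
                       net$bn_mean[[i]], net$bn_var[[i]], training,
                       net$bn_momentum)
      a <- bn$y
      cache[[paste0("bn", i)]] <- bn
    }
    cache[[paste0("relu", i)]] <- a > 0
    a <- a * (a > 0)
    if (cfg$pool_after[i]) {
      cache[[paste0("pool_in_dim", i)]] <- dim(a)
      mp <- .maxpool3d_forward(a)
      cache[[paste0("pool_arg", i)]] <- mp$argmax
      a <- mp$out
    }
  }

  flat <- matrix(a, ncol = N)
  if (training && cfg$dropout > 0) {
    mask <- matrix(runif(length(flat)) >= cfg$dropout, nrow(flat), N) /
      (1 - cfg$dropout)
    flat <- flat * mask
    cache$drop_mask <- mask
  }
  cache$flat <- flat

  fc_pre <- crossprod(p$Wfc, flat) + p$bfc
  feat <- fc_pre * (fc_pre > 0)
  cache$fc_pre <- fc_pre
  cache$feat <- feat

  logits <- crossprod(p$Whead, feat) + p$bhead
  zmax <- apply(logits, 2, max)
  ez <- exp(sweep(logits, 2, zmax))
  probs <- sweep(ez, 2, colSums(ez), "/")
  cache$probs <- probs

  out <- list(features = feat, probs = probs)
  if (keep_cache) out$cache <- cache
  out
}

# Backpropagate d(loss)/d(logits) (2 x N) through the branch; returns
# gradients for every trainable parameter (same names as net$params).
branch_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  p <- net$params
  grads <- list()
  grads$Whead <- cache$feat %*% t(dlogits)
  grads$bhead <- rowSums(dlogits)
  dfeat <- p$Whead %*% dlogits
  dpre <- dfeat * (cache$fc_pre > 0)
  grads$Wfc <- cache$flat %*% t(dpre)
  grads$bfc <- rowSums(dpre)
  dflat <- p$Wfc %*% dpre
  if (!is.null(cache$drop_mask)) dflat <- dflat * cache$drop_mask

  # reshape to the conv stack's output dims
  out_shp <- branch_out_shape(cfg)
  da <- array(dflat, dim = c(out_shp, cfg$channels[3], cache$N))

  for (i in 3:1) {
    if (cfg$pool_after[i]) {
      da <- .maxpool3d_backward(da, cache[[paste0("pool_arg", i)]],
                                as.integer(cache[[paste0("pool_in_dim", i)]]))
    }
    da <- da * cache[[paste0("relu", i)]]
    if (cfg$use_batchnorm) {
      bnb <- bn_backward(cache[[paste0("bn", i)]], p[[paste0("g", i)]], da,
                         training = TRUE)
      da <- bnb$dx
      grads[[paste0("g", i)]] <- bnb$dgamma
      grads[[paste0("beta", i)]] <- bnb$dbeta
    }
    cb <- .conv3d_backward(cache[[paste0("conv_in", i)]],
                           p[[paste0("W", i)]], da,
                           as.integer(rep(cfg$kernels[i], 3L)))
    grads[[paste0("W", i)]] <- cb$dW
    grads[[paste0("b", i)]] <- as.numeric(cb$db)
    da <- cb$dx
  }
  grads
}

#' Extract the per-branch feature vector for one patch
#'
#' Deterministic eval-mode forward pass returning the branch's feature
#' vector (length `fc_dim`, 256 at full width).
#'
#' @param net a [build_branch()] network.
#' @param patch a 3-D patch matching the branch input shape.
#' @return Numeric feature vector.
#' @export
forward_features <- function(net, patch) {
  as.numeric(branch_forward(net, patch, training = FALSE)$features)
}

#' Late fusion of the two branch features
#'
#' Concatenates the small-scale and large-scale feature vectors (branch 1
#' first) into one fused descriptor.
#'
#' @param f1,f2 per-branch feature vectors of equal length (256 at full
#'   width).
#' @param expected_len optional length check for each input.
#' @return Numeric vector of length `2 * length(f1)`.
#' @export
fuse <- function(f1, f2, expected_len = length(f1)) {
  if (length(f1) != expected_len || length(f2) != expected_len) {
    stop("feature vectors must both have length ", expected_len)
  }
  c(as.numeric(f1), as.numeric(f2))
}

#' Focal-style loss for imbalanced binary classification
#'
#' Average over the batch of the focusing-modulated cross-entropy
#' \deqn{J = -\frac{1}{m}\sum_i \alpha y_i (1-p_i)^\gamma \log p_i +
#'   (1-\alpha)(1-y_i) p_i^\gamma \log(1-p_i),}
#' where \eqn{p_i} is the predicted malignancy probability. Probabilities
#' are clipped to `[eps, 1-eps]` before the logs. With `gamma = 0` this is
#' the \eqn{\alpha}-weighted binary cross-entropy.
#'
#' @param p predicted probabilities in (0,1).
#' @param y labels in \{0,1\}.
#' @param alpha class-balance weight in `[0,1]`.
#' @param gamma focusing exponent, >= 0.
#' @param eps probability clipping bound.
#' @return Nonnegative scalar loss.
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2, eps = 1e-7) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  pc <- pmin(pmax(p, eps), 1 - eps)
  terms <- alpha * y * (1 - pc)^gamma * log(pc) +
    (1 - alpha) * (1 - y) * pc^gamma * log(1 - pc)
  -mean(terms)
}

#' Gradient of [focal_loss()] with respect to the probabilities
#'
#' @inheritParams focal_loss
#' @return Numeric vector `dJ/dp` of the same length as `p` (zero where the
#'   probability is clipped).
#' @export
focal_loss_grad <- function(p, y, alpha = 0.25, gamma = 2, eps = 1e-7) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  m <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  pow1 <- if (gamma == 0) 0 else gamma * (1 - pc)^(gamma - 1)
  pow0 <- if (gamma == 0) 0 else gamma * pc^(gamma - 1)
  g1 <- pow1 * log(pc) - (1 - pc)^gamma / pc         # d(-L)/dp, y = 1
  g0 <- -pow0 * log(1 - pc) + pc^gamma / (1 - pc)    # d(-L)/dp, y = 0
  g <- (alpha * y * g1 + (1 - alpha) * (1 - y) * g0) / m
  g[p < eps | p > 1 - eps] <- 0
  g
}

#' Train one CNN branch with the focal loss
#'
#' Minibatch Adam on the branch's softmax head probability of malignancy.
#' Optionally applies a max-norm constraint to the FC and head weights after
#' each step.
#'
#' @param net a [build_branch()] network.
#' @param patches list of 3-D patches matching the branch input shape.
#' @param labels 0/1 vector parallel to `patches`.
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param alpha,gamma focal-loss parameters.
#' @param seed RNG seed for shuffling and dropout.
#' @return The trained network with an attached `history` of per-epoch
#'   mean losses.
#' @export
train_branch <- function(net, patches, labels, epochs = 3, lr = 1e-3,
                         batch_size = 16, alpha = 0.25, gamma = 2,
                         seed = 1L) {
  if (length(patches) != length(labels)) stop("patches/labels mismatch")
  if (length(patches) == 0L) stop("empty training set")
  cfg <- net$config
  opt <- adam_init(net$params, lr = lr)
  history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(patches))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- array(0, dim = c(cfg$input_shape, 1L, length(idx)))
        for (j in seq_along(idx)) xb[, , , 1L, j] <- patches[[idx[j]]]
        yb <- labels[idx]
        fw <- branch_forward(net, xb, training = TRUE, keep_cache = TRUE)
        pmal <- fw$probs[2, ]
        losses <- c(losses, focal_loss(pmal, yb, alpha, gamma))
        dp <- focal_loss_grad(pmal, yb, alpha, gamma)
        dz2 <- dp * pmal * (1 - pmal)
        dlogits <- rbind(-dz2, dz2)
        grads <- branch_backward(net, fw$cache, dlogits)
        # carry over batch-norm running statistics from the forward pass
        if (cfg$use_batchnorm) {
          for (i in 1:3) {
            bn <- fw$cache[[paste0("bn", i)]]
            net$bn_mean[[i]] <- bn$running_mean
            net$bn_var[[i]] <- bn$running_var
          }
        }
        st <- adam_step(opt, net$params, grads)
        opt <- st$state
        net$params <- st$params
        if (is.finite(cfg$maxnorm)) {
          net$params$Wfc <- apply_maxnorm(net$params$Wfc, cfg$maxnorm)
          net$params$Whead <- apply_maxnorm(net$params$Whead, cfg$maxnorm)
        }
      }
      history <- c(history, mean(losses))
    }
  })
  net$history <- history
  net
}
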