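#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic under their `seed`
#' argument without clobbering the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

#' Adam optimiser over a flat named list of numeric tensors
#'
#' Minimal Adam implementation used for both the CNN branches and the
#' T-LSTM. Parameters and gradients are flat named lists whose elements are
#' numeric vectors/matrices/arrays of matching shapes.
#'
#' @param params named list of numeric tensors.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return An optimiser state object; pass to [adam_step()].
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

#' @rdname adam_init
#' @param state optimiser state from [adam_init()].
#' @param grads named list of gradients, same structure as `params`.
#' @keywords internal
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

# Rescale rows of a matrix so no row exceeds `maxnorm` in L2 norm
# (max-norm weight constraint, applied after each optimiser step).
apply_maxnorm <- function(W, maxnorm) {
  if (is.null(maxnorm) || !is.finite(maxnorm)) return(W)
  nr <- sqrt(rowSums(W * W))
  scl <- pmin(1, maxnorm / pmax(nr, 1e-12))
  W * scl
}
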