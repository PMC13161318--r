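# Minimal dense neural-network machinery: linear layers, ReLU, softmax,
# exact backprop and an AdamW optimizer.  Kept deliberately small -- the
# package needs reproducible, single-threaded training loops whose gradients
# can be audited against finite differences, not a general DL framework.

#' MLP architecture specification
#'
#' The default mirrors the package's reference tabular model: input width 10,
#' five hidden layers of 256 rectified-linear units, and a softmax output
#' over k groups.
#'
#' @param input_dim number of input features.
#' @param hidden_layers integer vector of hidden widths.
#' @param k_outputs number of groups (softmax width).
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim = 10, hidden_layers = rep(256, 5), k_outputs = 3) {
  structure(list(kind = "mlp", input_dim = as.integer(input_dim),
                 hidden_layers = as.integer(hidden_layers),
                 k_outputs = as.integer(k_outputs)),
            class = "mlp_spec")
}

# He/Kaiming-uniform initialisation, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for
# weights and biases alike (the convention of mainstream DL linear layers).
init_linear <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

init_mlp <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_layers, spec$k_outputs)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) layers[[l]] <- init_linear(dims[l], dims[l + 1L])
  structure(list(spec = spec, layers = layers), class = "lrc_mlp")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Forward pass; keeps pre-activations for backprop when cache = TRUE.
mlp_forward <- function(model, x, cache = FALSE) {
  a <- x
  acts <- list(a)
  L <- length(model$layers)
  for (l in seq_len(L)) {
    z <- a %*% model$layers[[l]]$W +
      matrix(model$layers[[l]]$b, nrow(a), length(model$layers[[l]]$b), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
    if (cache) acts[[l + 1L]] <- a
  }
  probs <- softmax_rows(a)
  if (cache) list(probs = probs, acts = acts) else probs
}

# dL/dprobs -> parameter gradients.  Softmax Jacobian first, then dense
# layers; ReLU gradient read off the cached post-activation sign.
mlp_backward <- function(model, fwd, dprobs) {
  p <- fwd$probs
  dz <- p * (dprobs - rowSums(dprobs * p))      # through softmax
  L <- length(model$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, dz), b = colSums(dz))
    if (l > 1L) {
      da <- tcrossprod(dz, model$layers[[l]]$W)
      dz <- da * (fwd$acts[[l]] > 0)            # ReLU mask
    }
  }
  grads
}

#' Predict soft group assignments
#'
#' @param object a trained model from [train_cluster_model()].
#' @param newdata feature matrix (MLP) or image array (CNN), already
#'   preprocessed.
#' @param ... unused.
#' @return n-by-k row-stochastic probability matrix.
#' @export
predict.lrc_mlp <- function(object, newdata, ...) {
  mlp_forward(object, as.matrix(newdata))
}

# --- AdamW ------------------------------------------------------------------

adamw_state <- function(params) {
  lapply(params, function(layer)
    lapply(layer, function(p) list(m = p * 0, v = p * 0)))
}

# One decoupled-weight-decay Adam step on a flat list of parameter arrays.
# params/grads/state share the same nested list shape.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 1) {
  walk <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps) - lr * weight_decay * p
    list(p = p, s = s)
  }
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      res <- walk(params[[l]][[nm]], grads[[l]][[nm]], state[[l]][[nm]])
      params[[l]][[nm]] <- res$p
      state[[l]][[nm]] <- res$s
    }
  }
  list(params = params, state = state)
}
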