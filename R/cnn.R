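# Convolutional model for image cohorts.  Blocks of zero-padded ("same")
# convolution + ReLU + max-pooling shrink the spatial map until a 1x1
# 4-channel activation remains, which feeds a single linear layer with
# softmax over the k groups.  Two profiles are provided: the full-resolution
# profile (six blocks, pool factors 4,4,4,2,2,2, requiring 512x512
# inputs) and a reduced four-block desk-scale profile for 64x64 images
# (pool factors 4,4,2,2), which is the default used throughout the package's
# synthetic image experiments.

#' CNN architecture specification
#'
#' @param input_size integer `(H, W)` of the (single-channel) input images.
#' @param k_outputs number of groups.
#' @param profile `"desk"` (four blocks, for 64x64 inputs) or `"full"` (six
#'   blocks, for 512x512 inputs).
#' @return A list of class `cnn_spec` describing channels, kernel and pool
#'   sizes per block.
#' @export
cnn_spec <- function(input_size = c(64, 64), k_outputs = 3,
                     profile = c("desk", "full")) {
  profile <- match.arg(profile)
  input_size <- as.integer(rep(input_size, length.out = 2L))
  blocks <- switch(profile,
    desk = list(
      list(cin = 1, cout = 8, kernel = 5, pool = 4),
      list(cin = 8, cout = 8, kernel = 5, pool = 4),
      list(cin = 8, cout = 8, kernel = 3, pool = 2),
      list(cin = 8, cout = 4, kernel = 3, pool = 2)),
    full = list(
      list(cin = 1, cout = 32, kernel = 16, pool = 4),
      list(cin = 32, cout = 8, kernel = 8, pool = 4),
      list(cin = 8, cout = 8, kernel = 8, pool = 4),
      list(cin = 8, cout = 8, kernel = 8, pool = 2),
      list(cin = 8, cout = 4, kernel = 3, pool = 2),
      list(cin = 4, cout = 4, kernel = 2, pool = 2)))
  total_pool <- prod(vapply(blocks, `[[`, 1, "pool"))
  if (any(input_size != total_pool))
    stop(sprintf(
      "config error: the '%s' profile reduces the map to 1x1 only for %dx%d inputs (got %dx%d)",
      profile, total_pool, total_pool, input_size[1], input_size[2]))
  structure(list(kind = "cnn", input_size = input_size,
                 blocks = blocks, k_outputs = as.integer(k_outputs),
                 profile = profile),
            class = "cnn_spec")
}

init_cnn <- function(spec) {
  layers <- lapply(spec$blocks, function(bl) {
    fan_in <- bl$kernel^2 * bl$cin
    bd <- 1 / sqrt(fan_in)
    list(W = array(stats::runif(bl$kernel^2 * bl$cin * bl$cout, -bd, bd),
                   c(bl$kernel, bl$kernel, bl$cin, bl$cout)),
         b = stats::runif(bl$cout, -bd, bd))
  })
  layers[[length(layers) + 1L]] <-
    init_linear(spec$blocks[[length(spec$blocks)]]$cout, spec$k_outputs)
  structure(list(spec = spec, layers = layers), class = "lrc_cnn")
}

as_slices <- function(a) {            # (H, W, C, B) array -> 3-d cube layout
  d <- dim(a)
  dim(a) <- c(d[1], d[2], d[3] * d[4])
  a
}

cnn_forward <- function(model, images, cache = FALSE) {
  spec <- model$spec
  B <- dim(images)[1]
  x <- aperm(images, c(2, 3, 1))               # (H, W, B), C = 1
  dim(x) <- c(dim(x)[1], dim(x)[2], 1L, B)
  caches <- list()
  for (l in seq_along(spec$blocks)) {
    bl <- spec$blocks[[l]]
    H <- dim(x)[1]; W <- dim(x)[2]
    z <- conv2d_fwd(as_slices(x), as_slices_w(model$layers[[l]]$W),
                    model$layers[[l]]$b, B, bl$cin, bl$cout)
    relu_mask <- z > 0
    z <- z * relu_mask
    pooled <- maxpool_fwd(z, bl$pool, B, bl$cout)
    if (cache)
      caches[[l]] <- list(x = as_slices(x), relu_mask = relu_mask,
                          idx = pooled$idx, H = H, W = W)
    x <- pooled$y
    dim(x) <- c(dim(pooled$y)[1], dim(pooled$y)[2], bl$cout, B)
  }
  # final map is 1 x 1 x C x B -> B x C
  flat <- t(matrix(x, dim(x)[3], B))
  lin <- model$layers[[length(model$layers)]]
  logits <- flat %*% lin$W + matrix(lin$b, B, length(lin$b), byrow = TRUE)
  probs <- softmax_rows(logits)
  if (cache) list(probs = probs, flat = flat, caches = caches) else probs
}

as_slices_w <- function(w) {          # (kh, kw, Cin, Cout) -> cube layout
  d <- dim(w)
  dim(w) <- c(d[1], d[2], d[3] * d[4])
  w
}

cnn_backward <- function(model, fwd, dprobs) {
  spec <- model$spec
  B <- nrow(dprobs)
  p <- fwd$probs
  dz <- p * (dprobs - rowSums(dprobs * p))
  lin <- model$layers[[length(model$layers)]]
  grads <- vector("list", length(model$layers))
  grads[[length(model$layers)]] <- list(W = crossprod(fwd$flat, dz),
                                        b = colSums(dz))
  dflat <- tcrossprod(dz, lin$W)               # B x C_last
  # back to a 1 x 1 x C x B cube
  C_last <- ncol(dflat)
  dmap <- array(t(dflat), c(1, 1, C_last * B))
  for (l in rev(seq_along(spec$blocks))) {
    bl <- spec$blocks[[l]]
    ch <- caches_get(fwd$caches, l)
    dz_conv <- maxpool_bwd(dmap, ch$idx, ch$H, ch$W) * ch$relu_mask
    bw <- conv2d_bwd(ch$x, as_slices_w(model$layers[[l]]$W), dz_conv,
                     B, bl$cin, bl$cout)
    grads[[l]] <- list(W = array(bw$dw, dim(model$layers[[l]]$W)),
                       b = as.vector(bw$db))
    dmap <- bw$dx
  }
  grads
}

caches_get <- function(caches, l) caches[[l]]

#' @rdname predict.lrc_mlp
#' @export
predict.lrc_cnn <- function(object, newdata, ...) {
  cnn_forward(object, newdata)
}
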