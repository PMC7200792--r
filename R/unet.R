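# A convolutional encoder-decoder (U-Net family) with hand-written forward
# and backward passes. The whole network is a map from one single-channel
# image to one single-channel image of the same size; it is optimized per
# measurement, never trained on a dataset, so the implementation favors
# exactness and determinism over generality: 3x3 same-padding convolutions
# via im2col + BLAS, spatial batch normalization (batch of one image,
# statistics over pixels), leaky ReLU, 2x2 max pooling, nearest-neighbor
# x2 upsampling followed by a 3x3 convolution as the up-convolution block,
# and channel-concatenation skip connections.
#
# Feature maps are 3D arrays (rows, cols, channels). Convolution kernels are
# (9*c_in, c_out) matrices whose rows are ordered offset-major: for each of
# the 9 taps (dy, dx) in column-major order over dy = -1..1, dx = -1..1, all
# input channels. Every backward pass is checked against finite differences
# in the test suite.

#' Architecture of the encoder-decoder reconstruction network
#'
#' @param n_scales Number of encoder/decoder levels (each halves the grid);
#'   the input side length must be divisible by `2^n_scales`.
#' @param base_channels Channels at the finest scale.
#' @param channel_growth Multiplier applied to the channel count per level
#'   (2 doubles; 1 keeps the width constant).
#' @param leaky_slope Negative-side slope of the leaky ReLU, in (0, 1).
#' @param skip_connections Concatenate encoder features into the decoder at
#'   matching scales (`TRUE`, default).
#' @param output_activation `"scaled_sigmoid"` (default; output in
#'   `[0, 2*pi]`, nonnegative and bounded with gradients everywhere) or
#'   `"relu"` (hard lower clamp at zero; pixels caught at the clamp stop
#'   receiving gradient, which can stall the single-image optimization).
#'   Both anchor the piston ambiguity by making the phase nonnegative.
#' @return An object of class `"network_spec"`. The convolution kernel is
#'   fixed at 3x3.
#' @export
network_spec <- function(n_scales = 4L, base_channels = 16L, channel_growth = 2,
                         leaky_slope = 0.1, skip_connections = TRUE,
                         output_activation = "scaled_sigmoid") {
  n_scales <- as.integer(n_scales)
  base_channels <- as.integer(base_channels)
  if (is.na(n_scales) || n_scales < 1L) stop("`n_scales` must be >= 1")
  if (is.na(base_channels) || base_channels < 1L) stop("`base_channels` must be >= 1")
  if (!is.numeric(channel_growth) || channel_growth < 1) stop("`channel_growth` must be >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1) stop("`leaky_slope` must be in (0, 1)")
  output_activation <- match.arg(output_activation, c("scaled_sigmoid", "relu"))
  structure(list(n_scales = n_scales, base_channels = base_channels,
                 channel_growth = channel_growth, kernel = 3L,
                 leaky_slope = leaky_slope,
                 skip_connections = isTRUE(skip_connections),
                 output_activation = output_activation),
            class = "network_spec")
}

# Channels at level i (1-based, finest first).
.level_channels <- function(spec, i) {
  as.integer(round(spec$base_channels * spec$channel_growth^(i - 1)))
}

#' Build a randomly initialized reconstruction network
#'
#' Allocates all convolution kernels (He-scaled normal initialization),
#' biases and normalization parameters for the architecture in `spec`,
#' seeded for exact reproducibility. The realized network maps one
#' single-channel image of shape `input_shape` to one single-channel image
#' of the same shape; under the default ReLU output activation the output is
#' nonnegative everywhere.
#'
#' @param spec A [network_spec()].
#' @param input_shape Integer vector `c(rows, cols)`; both must be divisible
#'   by `2^n_scales`.
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `"phase_network"`: the parameter list plus the
#'   architecture and shape metadata.
#' @export
build_network <- function(spec, input_shape, seed = 1L) {
  if (!inherits(spec, "network_spec")) stop("`spec` must be a network_spec")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2L) stop("`input_shape` must be c(rows, cols)")
  div <- 2L^spec$n_scales
  if (any(input_shape %% div != 0L))
    stop(sprintf("input shape (%d x %d) must be divisible by 2^n_scales = %d",
                 input_shape[1], input_shape[2], div))
  S <- spec$n_scales
  layers <- list()
  make_block <- function(c_in, c_out) {
    sd <- sqrt(2 / (9 * c_in))
    list(W = matrix(stats::rnorm(9 * c_in * c_out, 0, sd), 9 * c_in, c_out),
         b = numeric(c_out), gamma = rep(1, c_out), beta = numeric(c_out))
  }
  with_seed(seed, {
    c_prev <- 1L
    for (i in seq_len(S)) {
      c_i <- .level_channels(spec, i)
      layers[[paste0("enc", i)]] <- make_block(c_prev, c_i)
      c_prev <- c_i
    }
    layers[["bottleneck"]] <- make_block(c_prev, c_prev)
    c_up <- c_prev
    for (i in rev(seq_len(S))) {
      c_i <- .level_channels(spec, i)
      c_in <- if (spec$skip_connections) c_up + c_i else c_up
      layers[[paste0("dec", i)]] <- make_block(c_in, c_i)
      c_up <- c_i
    }
    sd_out <- sqrt(2 / (9 * c_up))
    layers[["out"]] <- list(W = matrix(stats::rnorm(9 * c_up, 0, sd_out), 9 * c_up, 1),
                            b = 0)
  })
  structure(list(spec = spec, input_shape = input_shape, layers = layers,
                 seed = as.integer(seed)),
            class = "phase_network")
}

#' Number of trainable parameters of a network
#' @param net A `"phase_network"` from [build_network()].
#' @return Integer parameter count (kernels + biases + normalization scales
#'   and shifts).
#' @export
count_parameters <- function(net) {
  sum(vapply(net$layers, function(l) sum(vapply(l, length, 1L)), 1L))
}

## ---- primitive layers (forward returns cache for backward) ----

conv_fwd <- function(x, W, b) {
  r <- conv3x3_fwd(x, W, b)
  list(y = r$y, col = r$col, dims = dim(x))
}

conv_bwd <- function(gy, cache, W) {
  d <- cache$dims
  r <- conv3x3_bwd(gy, cache$col, W, d[1], d[2], d[3])
  list(gx = r$gx, gW = r$gW, gb = as.numeric(r$gb))
}

# Spatial batch normalization over the pixels of the single image, per
# channel; training statistics are used for every pass (there is no separate
# inference distribution when the batch is one fixed image).
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  xm <- matrix(x, N, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = array(y, d), xhat = xhat, invstd = invstd, dims = d)
}

bn_bwd <- function(gy, cache, gamma) {
  d <- cache$dims; N <- d[1] * d[2]
  gym <- matrix(gy, N, d[3])
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  gxhat <- sweep(gym, 2L, gamma, "*")
  t1 <- sweep(gxhat, 2L, colMeans(gxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(gxhat * cache$xhat), "*")
  gx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

lrelu_fwd <- function(x, slope) {
  neg <- x <= 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}

lrelu_bwd <- function(gy, cache, slope) {
  g <- gy
  g[cache$neg] <- slope * gy[cache$neg]
  g
}

maxpool_fwd <- function(x) {
  d <- dim(x); n1 <- d[1]; n2 <- d[2]
  o1 <- seq(1L, n1, 2L); e1 <- o1 + 1L
  o2 <- seq(1L, n2, 2L); e2 <- o2 + 1L
  s <- list(x[o1, o2, , drop = FALSE], x[e1, o2, , drop = FALSE],
            x[o1, e2, , drop = FALSE], x[e1, e2, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # deterministic tie-break: first window position in the fixed order above
  k <- array(4L, dim(y))
  k[s[[3]] == y] <- 3L
  k[s[[2]] == y] <- 2L
  k[s[[1]] == y] <- 1L
  list(y = y, k = k, dims = d)
}

maxpool_bwd <- function(gy, cache) {
  d <- cache$dims
  gx <- array(0, d)
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  k <- cache$k
  route <- function(rows, cols, kk) {
    sub <- array(0, dim(gy))
    sel <- k == kk
    sub[sel] <- gy[sel]
    gx[rows, cols, ] <<- sub
  }
  route(o1, o2, 1L); route(e1, o2, 2L); route(o1, e2, 3L); route(e1, e2, 4L)
  gx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(gy) {
  d <- dim(gy)
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  gy[o1, o2, , drop = FALSE] + gy[e1, o2, , drop = FALSE] +
    gy[o1, e2, , drop = FALSE] + gy[e1, e2, , drop = FALSE]
}

convblock_fwd <- function(x, p, slope) {
  c1 <- conv_fwd(x, p$W, p$b)
  c2 <- bn_fwd(c1$y, p$gamma, p$beta)
  c3 <- lrelu_fwd(c2$y, slope)
  list(y = c3$y, conv = c1, bn = c2, act = c3)
}

convblock_bwd <- function(gy, cache, p, slope) {
  g <- lrelu_bwd(gy, cache$act, slope)
  gb <- bn_bwd(g, cache$bn, p$gamma)
  gc <- conv_bwd(gb$gx, cache$conv, p$W)
  list(gx = gc$gx,
       grads = list(W = gc$gW, b = gc$gb, gamma = gb$ggamma, gbeta = gb$gbeta))
}

## ---- whole-network forward / backward ----

# Forward pass. `x` is a matrix (single-channel image); returns the output
# phase matrix plus caches for the backward pass.
net_forward <- function(net, x) {
  spec <- net$spec
  S <- spec$n_scales
  h <- array(x, c(nrow(x), ncol(x), 1L))
  caches <- list()
  skips <- list()
  for (i in seq_len(S)) {
    cb <- convblock_fwd(h, net$layers[[paste0("enc", i)]], spec$leaky_slope)
    caches[[paste0("enc", i)]] <- cb
    skips[[i]] <- cb$y
    mp <- maxpool_fwd(cb$y)
    caches[[paste0("pool", i)]] <- mp
    h <- mp$y
  }
  cb <- convblock_fwd(h, net$layers[["bottleneck"]], spec$leaky_slope)
  caches[["bottleneck"]] <- cb
  h <- cb$y
  for (i in rev(seq_len(S))) {
    h <- upsample_fwd(h)
    if (spec$skip_connections) {
      caches[[paste0("split", i)]] <- dim(h)[3]
      h <- .concat3(h, skips[[i]])
    }
    cb <- convblock_fwd(h, net$layers[[paste0("dec", i)]], spec$leaky_slope)
    caches[[paste0("dec", i)]] <- cb
    h <- cb$y
  }
  co <- conv_fwd(h, net$layers[["out"]]$W, net$layers[["out"]]$b)
  caches[["out"]] <- co
  z <- co$y[, , 1L]
  if (spec$output_activation == "relu") {
    phi <- pmax(z, 0)
    caches[["act_pos"]] <- z > 0
  } else {
    sig <- 1 / (1 + exp(-z))
    phi <- 2 * pi * sig
    caches[["act_sig"]] <- sig
  }
  list(phi = phi, caches = caches)
}

.concat3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# Backward pass: dLoss/dPhi (matrix) -> list of per-layer parameter
# gradients shaped exactly like net$layers.
net_backward <- function(net, fw, gphi) {
  spec <- net$spec
  S <- spec$n_scales
  caches <- fw$caches
  grads <- list()
  if (spec$output_activation == "relu") {
    gz <- gphi * caches[["act_pos"]]
  } else {
    sig <- caches[["act_sig"]]
    gz <- gphi * 2 * pi * sig * (1 - sig)
  }
  co <- caches[["out"]]
  gco <- conv_bwd(array(gz, c(dim(gz), 1L)), co, net$layers[["out"]]$W)
  grads[["out"]] <- list(W = gco$gW, b = gco$gb)
  g <- gco$gx
  gskips <- vector("list", S)
  for (i in seq_len(S)) {
    cb <- convblock_bwd(g, caches[[paste0("dec", i)]],
                        net$layers[[paste0("dec", i)]], spec$leaky_slope)
    grads[[paste0("dec", i)]] <- cb$grads
    g <- cb$gx
    if (spec$skip_connections) {
      c_up <- caches[[paste0("split", i)]]
      gskips[[i]] <- g[, , c_up + seq_len(dim(g)[3] - c_up), drop = FALSE]
      g <- g[, , seq_len(c_up), drop = FALSE]
    }
    g <- upsample_bwd(g)
  }
  cb <- convblock_bwd(g, caches[["bottleneck"]], net$layers[["bottleneck"]],
                      spec$leaky_slope)
  grads[["bottleneck"]] <- cb$grads
  g <- cb$gx
  for (i in rev(seq_len(S))) {
    g <- maxpool_bwd(g, caches[[paste0("pool", i)]])
    if (spec$skip_connections && !is.null(gskips[[i]])) g <- g + gskips[[i]]
    cb <- convblock_bwd(g, caches[[paste0("enc", i)]],
                        net$layers[[paste0("enc", i)]], spec$leaky_slope)
    grads[[paste0("enc", i)]] <- cb$grads
    g <- cb$gx
  }
  grads
}

## ---- Adam ----

adam_init <- function(layers) {
  lapply(layers, function(l) lapply(l, function(p) list(m = p * 0, v = p * 0)))
}

# One Adam step; `grads` uses names (W, b, gamma, gbeta) produced by the
# backward pass; the beta shift gradient is stored under `gbeta` and applied
# to parameter `beta`.
adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (ln in names(grads)) {
    gl <- grads[[ln]]
    for (pn in names(gl)) {
      target <- if (pn == "gbeta") "beta" else pn
      g <- gl[[pn]]
      st <- state[[ln]][[target]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[ln]][[target]] <- st
      layers[[ln]][[target]] <- layers[[ln]][[target]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}
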