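#' Fully convolutional backbone configuration
#'
#' Describes a stack of 3x3 (by default) convolution layers with ReLU
#' activations between them and a linear final layer; optional batch
#' normalization can be enabled on the hidden layers.  The cumulative output stride `s` and the theoretical receptive
#' field `r` are computed in closed form from the layer spec:
#' `s = prod(strides)` and
#' `r = 1 + sum((kernel - 1) * cumprod(c(1, strides[-L])))`.
#' The final feature map `phi` has `d = channels[L]` channels on a
#' `u x v = ceil(H/s) x ceil(W/s)` grid (padding `floor(kernel/2)` per
#' layer).
#'
#' The default — four layers, 16/32/64/128 channels, two stride-2
#' downsamplings — gives `s = 4` and `r = 13` pixels, a receptive field on
#' the order of the phantom lesion scale, while remaining CPU-trainable.
#'
#' @param channels output channels per layer.
#' @param kernel odd kernel size shared by all layers.
#' @param strides stride per layer (same length as `channels`).
#' @param input_size `c(H, W)` of the model input.
#' @param in_channels input image channels (1 for grayscale MIPs).
#' @param batchnorm use batch normalization on all but the final layer.
#' @return An object of class `backbone_config` with derived fields
#'   `stride`, `receptive_field`, `embed_dim` and `grid` (`c(u, v)`).
#' @examples
#' cfg <- backbone_config(input_size = c(64, 64))
#' c(cfg$stride, cfg$receptive_field)
#' @export
backbone_config <- function(channels = c(16, 32, 64, 128), kernel = 3,
                            strides = c(1, 2, 1, 2),
                            input_size = c(128, 128), in_channels = 1,
                            batchnorm = FALSE) {
  stopifnot(length(channels) == length(strides), kernel %% 2 == 1,
            all(strides >= 1), all(channels >= 1), length(input_size) == 2)
  s <- prod(strides)
  jumps <- cumprod(c(1, strides[-length(strides)]))
  r <- 1 + sum((kernel - 1) * jumps)
  grid <- as.integer(ceiling(input_size / s))
  if (r < 3) stop("receptive field must be at least 3 pixels")
  if (any(grid < 2)) stop("output grid smaller than 2x2 for this input size")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 strides = as.integer(strides),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 batchnorm = isTRUE(batchnorm),
                 stride = as.integer(s), receptive_field = as.integer(r),
                 embed_dim = as.integer(channels[length(channels)]),
                 grid = grid),
            class = "backbone_config")
}

#' Initialise backbone weights
#'
#' He-normal weight initialisation; zero biases; batch-norm scale/shift at
#' 1/0 with unit running variance.  Layers followed by batch normalization
#' carry no conv bias (it would be absorbed by the shift), and the final
#' layer carries neither, so that a zero-weight network maps every input to
#' the exact zero feature map (the hypersphere centre).
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the initialisation draw.
#' @return A list of class `backbone_net` with per-layer parameters plus the
#'   config.
#' @export
backbone_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  with_seed(seed, {
    k <- config$kernel
    cin <- config$in_channels
    L <- length(config$channels)
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      cout <- config$channels[l]
      fan_in <- k * k * cin
      bn <- config$batchnorm && l < L
      layers[[l]] <- list(
        w = array(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                  c(k, k, cin, cout)),
        b = numeric(cout),
        stride = config$strides[l],
        use_bias = !bn && l < L,
        bn = bn,
        gamma = rep(1, cout), beta = numeric(cout),
        rm = numeric(cout), rv = rep(1, cout))
      cin <- cout
    }
    structure(list(layers = layers, config = config, seed = as.integer(seed)),
              class = "backbone_net")
  })
}

# Coerce image input to an H x W x C x N array.
as_batch <- function(x, in_channels = 1) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) x <- array(x, c(dim(as.matrix(x)), 1, 1))
  else if (length(d) == 3) x <- array(x, c(d[1], d[2], 1, d[3]))  # H x W x N
  else if (length(d) != 4) stop("expected an image, H x W x N stack, or 4-d batch")
  if (dim(x)[3] != in_channels) stop("channel mismatch")
  x
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Channel-wise batch normalization of a (Ho, Wo, K, N) array.
bn_forward <- function(z, ly, training) {
  d <- dim(z)
  K <- d[3]
  zp <- aperm(z, c(1, 2, 4, 3))            # (Ho, Wo, N, K)
  m <- matrix(zp, ncol = K)                # rows: all positions; cols: channel
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2, mu)^2)      # biased variance, standard for BN
  } else {
    mu <- ly$rm
    va <- ly$rv
  }
  istd <- 1 / sqrt(va + bn_eps)
  xhat <- sweep(sweep(m, 2, mu), 2, istd, "*")
  out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  zbn <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(zbn = zbn, xhat = xhat, istd = istd, mu = mu, va = va)
}

# Gradient of BN w.r.t. its input and parameters; g has shape (Ho,Wo,K,N).
# In training mode the batch statistics depend on the input (full formula);
# in inference mode the running statistics are constants and only the
# elementwise rescaling propagates.
bn_backward <- function(g, bnc, ly) {
  d <- dim(g)
  K <- d[3]
  gy <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = K)
  m <- nrow(gy)
  dgamma <- colSums(gy * bnc$xhat)
  dbeta <- colSums(gy)
  dxhat <- sweep(gy, 2, ly$gamma, "*")
  if (isTRUE(bnc$training)) {
    # dx = istd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    t1 <- m * dxhat
    t2 <- matrix(colSums(dxhat), m, K, byrow = TRUE)
    t3 <- bnc$xhat * matrix(colSums(dxhat * bnc$xhat), m, K, byrow = TRUE)
    dx <- sweep(t1 - t2 - t3, 2, bnc$istd / m, "*")
  } else {
    dx <- sweep(dxhat, 2, bnc$istd, "*")
  }
  gz <- aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(gz = gz, dgamma = dgamma, dbeta = dbeta)
}

#' Backbone forward pass
#'
#' @param net a [backbone_init()] network.
#' @param x an `H x W` image, `H x W x N` stack, or `H x W x C x N` batch.
#' @param keep_cache keep per-layer activations for a backward pass.
#' @param training use batch statistics in the normalization layers (and
#'   update the running averages); inference mode (`FALSE`) uses the stored
#'   running statistics, making the forward pass deterministic per image.
#' @return A list: `phi` (`u x v x d x N` feature map), `cache` (if
#'   requested), and `net` (with updated running statistics when
#'   `training = TRUE`).
#' @export
backbone_forward <- function(net, x, keep_cache = FALSE, training = FALSE) {
  x <- as_batch(x, net$config$in_channels)
  pad <- net$config$kernel %/% 2
  L <- length(net$layers)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    z <- conv2d_forward(x, ly$w, ly$b, ly$stride, pad)
    bnc <- NULL
    if (ly$bn) {
      bnc <- bn_forward(z, ly, training)
      if (training) {
        net$layers[[l]]$rm <- (1 - bn_momentum) * ly$rm + bn_momentum * bnc$mu
        net$layers[[l]]$rv <- (1 - bn_momentum) * ly$rv + bn_momentum * bnc$va
      }
      z <- bnc$zbn
    }
    out <- if (l < L) pmax(z, 0) else z
    if (keep_cache) {
      if (!is.null(bnc)) {
        bnc <- bnc[c("xhat", "istd")]
        bnc$training <- training
      }
      cache[[l]] <- list(input = x, act = out, bn = bnc)
    }
    x <- out
  }
  list(phi = x, cache = cache, net = net)
}

#' Backbone backward pass
#'
#' Backpropagates a gradient at the feature map through the network,
#' returning parameter gradients and the gradient at every intermediate
#' activation — the latter is what Grad-CAM consumes.
#'
#' @param net the network used in the forward pass.
#' @param cache the `cache` from `backbone_forward(..., keep_cache = TRUE)`.
#' @param gphi gradient with respect to `phi` (same shape).
#' @param upto stop after reaching the output of layer `upto - 1`
#'   (1 = full pass).
#' @return List with `gw`/`gb`/`dgamma`/`dbeta` per layer and `gact`:
#'   `gact[[l]]` is the gradient at the *output* of layer `l`.
#' @export
backbone_backward <- function(net, cache, gphi, upto = 1L) {
  pad <- net$config$kernel %/% 2
  L <- length(net$layers)
  gw <- vector("list", L); gb <- vector("list", L)
  dgamma <- vector("list", L); dbeta <- vector("list", L)
  gact <- vector("list", L)
  g <- gphi
  for (l in L:1) {
    gact[[l]] <- g
    if (l < upto) break
    ly <- net$layers[[l]]
    if (l < L) g <- g * (cache[[l]]$act > 0)  # ReLU gate
    if (ly$bn) {
      bk_bn <- bn_backward(g, cache[[l]]$bn, ly)
      g <- bk_bn$gz
      dgamma[[l]] <- bk_bn$dgamma
      dbeta[[l]] <- bk_bn$dbeta
    } else {
      dgamma[[l]] <- numeric(length(ly$gamma))
      dbeta[[l]] <- numeric(length(ly$beta))
    }
    bk <- conv2d_backward(cache[[l]]$input, ly$w, g, ly$stride, pad)
    gw[[l]] <- bk$gw
    gb[[l]] <- if (ly$use_bias) bk$gb else numeric(length(bk$gb))
    g <- bk$gx
  }
  list(gw = gw, gb = gb, dgamma = dgamma, dbeta = dbeta, gact = gact, gx = g)
}

# SGD with momentum, weight decay on conv weights and optional global-norm
# gradient clipping.  `state` holds velocity buffers; returns updated
# (net, state).  Batch-norm scale/shift are updated without weight decay.
sgd_step <- function(net, grads, state, lr, momentum = 0.9,
                     weight_decay = 1e-4, grad_clip = 5) {
  if (is.null(state)) {
    state <- lapply(net$layers, function(ly)
      list(vw = array(0, dim(ly$w)), vb = numeric(length(ly$b)),
           vg = numeric(length(ly$gamma)), vbt = numeric(length(ly$beta))))
  }
  if (is.finite(grad_clip) && grad_clip > 0) {
    total <- sqrt(sum(vapply(seq_along(net$layers), function(l)
      sum(grads$gw[[l]]^2) + sum(grads$gb[[l]]^2) +
        sum(grads$dgamma[[l]]^2) + sum(grads$dbeta[[l]]^2), numeric(1))))
    if (total > grad_clip) {
      sc <- grad_clip / total
      for (l in seq_along(net$layers)) {
        grads$gw[[l]] <- grads$gw[[l]] * sc
        grads$gb[[l]] <- grads$gb[[l]] * sc
        grads$dgamma[[l]] <- grads$dgamma[[l]] * sc
        grads$dbeta[[l]] <- grads$dbeta[[l]] * sc
      }
    }
  }
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    gwl <- grads$gw[[l]] + weight_decay * ly$w
    state[[l]]$vw <- momentum * state[[l]]$vw + gwl
    net$layers[[l]]$w <- ly$w - lr * state[[l]]$vw
    if (ly$use_bias) {
      state[[l]]$vb <- momentum * state[[l]]$vb + grads$gb[[l]]
      net$layers[[l]]$b <- ly$b - lr * state[[l]]$vb
    }
    if (ly$bn) {
      state[[l]]$vg <- momentum * state[[l]]$vg + grads$dgamma[[l]]
      net$layers[[l]]$gamma <- ly$gamma - lr * state[[l]]$vg
      state[[l]]$vbt <- momentum * state[[l]]$vbt + grads$dbeta[[l]]
      net$layers[[l]]$beta <- ly$beta - lr * state[[l]]$vbt
    }
  }
  list(net = net, state = state)
}
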