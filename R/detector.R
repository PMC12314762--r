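#' Pseudo-Huber anomaly map from a feature map
#'
#' Maps each spatial location of the feature map to the pseudo-Huber norm of
#' its feature vector, `A_ij = sqrt(||phi_.ij||^2 + 1) - 1`: a smooth,
#' nonnegative distance from the hypersphere centre at the origin that is
#' quadratic near zero and linear in the tails.  `A_ij = 0` exactly when the
#' feature vector is zero.
#'
#' @param phi feature array `u x v x d` (one image) or `u x v x d x N`.
#' @return A `u x v` matrix (or `u x v x N` array) of nonnegative scores.
#' @examples
#' phi <- array(0, c(2, 2, 3)); phi[1, 1, ] <- c(1, 1, 1)
#' pseudo_huber_map(phi)[1, 1]  # sqrt(3 + 1) - 1 = 1
#' @export
pseudo_huber_map <- function(phi) {
  d <- dim(phi)
  if (length(d) == 3) d <- c(d, 1)
  if (length(dim(phi)) != 4) phi <- array(phi, d)
  if (any(!is.finite(phi))) stop("non-finite feature map")
  sq <- apply(phi^2, c(1, 2, 4), sum)
  a <- sqrt(sq + 1) - 1
  if (dim(a)[3] == 1) matrix(a, d[1], d[2]) else a
}

#' Breast-level anomaly score
#'
#' The breast-level score is the mean of the pixelwise anomaly scores over
#' the low-resolution grid.
#'
#' @param A a nonnegative anomaly map (matrix), or `u x v x N` array.
#' @return A scalar (or length-`N` vector).
#' @export
breast_score <- function(A) {
  if (length(A) == 0) stop("empty anomaly map")
  if (any(A < 0)) stop("anomaly map must be nonnegative")
  d <- dim(A)
  if (!is.null(d) && length(d) == 3) apply(A, 3, mean) else mean(A)
}

# Shared pseudo-Huber anomaly-objective loss on nonnegative scores.
# Per sample: (1 - y) * s  -  y * log(1 - exp(-s)), batch-averaged.
# exp(-s) is clamped to at most 1 - eps so the y = 1 branch stays finite at
# s = 0 (loss bounded by -log(eps)).
huber_objective_loss <- function(s, y, eps = 1e-6) {
  stopifnot(length(s) == length(y), all(y %in% c(0, 1)))
  if (any(s < 0)) stop("scores must be nonnegative")
  q <- pmin(exp(-s), 1 - eps)
  mean((1 - y) * s - y * log(1 - q))
}

# Gradient of huber_objective_loss w.r.t. s (batch mean included).
huber_objective_grad <- function(s, y, eps = 1e-6) {
  q <- pmin(exp(-s), 1 - eps)
  ((1 - y) - y * q / (1 - q)) / length(s)
}

#' FCDD detection loss
#'
#' Semisupervised one-class objective on breast-level anomaly scores
#' `s >= 0`: benign samples (`y = 0`) are pulled toward the hypersphere
#' centre (loss `s`), labelled anomalies (`y = 1`) are pushed away (loss
#' `-log(1 - exp(-s))`).  With no anomalies in the batch the objective is
#' purely one-class.  Batch-averaged.
#'
#' @param s nonnegative breast-level scores.
#' @param y labels in `{0, 1}` (benign / malignant).
#' @param eps clamp so that `exp(-s) <= 1 - eps`, keeping the anomalous
#'   branch finite at `s = 0`.
#' @return Scalar loss.
#' @examples
#' fcdd_loss(log(2), 1)  # -log(1 - 1/2) = log 2
#' @export
fcdd_loss <- function(s, y, eps = 1e-6) huber_objective_loss(s, y, eps)

#' HSC detection loss
#'
#' Hypersphere classification: the same pseudo-Huber objective as
#' [fcdd_loss()], applied to the globally pooled embedding rather than to a
#' spatial map, `h = sqrt(||z||^2 + 1) - 1`.  Not spatially explainable by
#' itself.
#'
#' @param z embedding matrix `d x N` (columns are pooled feature vectors).
#' @param y labels in `{0, 1}`.
#' @param eps as in [fcdd_loss()].
#' @return Scalar loss.
#' @export
hsc_loss <- function(z, y, eps = 1e-6) {
  z <- as.matrix(z)
  h <- sqrt(colSums(z^2) + 1) - 1
  huber_objective_loss(h, y, eps)
}

#' Global-average-pool embedding of a feature map
#'
#' @param phi `u x v x d x N` (or 3-d) feature array.
#' @return A `d x N` matrix.
#' @export
pooled_embedding <- function(phi) {
  d <- dim(phi)
  if (length(d) == 3) phi <- array(phi, c(d, 1))
  apply(phi, c(3, 4), mean)
}

#' BCE classification head and loss
#'
#' `bce_head` maps a feature map to a logit via global average pooling and a
#' linear layer; `bce_loss` is the numerically stable sigmoid cross-entropy
#' `max(l, 0) - l * y + log(1 + exp(-|l|))`, batch-averaged.
#'
#' @param phi feature array.
#' @param head list with weight vector `w` (length `d`) and scalar `b`.
#' @return `bce_head`: logit vector; `bce_loss`: scalar.
#' @export
bce_head <- function(phi, head) {
  z <- pooled_embedding(phi)
  as.numeric(crossprod(z, head$w)) + head$b
}

#' @rdname bce_head
#' @param logits logit vector.
#' @param y labels in `{0, 1}`.
#' @export
bce_loss <- function(logits, y) {
  stopifnot(length(logits) == length(y), all(y %in% c(0, 1)))
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

#' Contralateral symmetric anomaly map
#'
#' FCDD-Symmetric uses the contralateral breast as the normal-class centre:
#' the anomaly score at each location is the pseudo-Huber norm of the
#' *difference* between the ipsilateral and contralateral feature vectors,
#' `A_ij = sqrt(||phi_ipsi - phi_contra||^2 + 1) - 1`.  An identical pair
#' yields the zero map; a zero contralateral feature map reduces the
#' operation to [pseudo_huber_map()].
#'
#' @param phi_ipsi,phi_contra feature arrays of identical shape, both in the
#'   canonical orientation.
#' @return Anomaly map as in [pseudo_huber_map()].
#' @export
symmetric_anomaly_map <- function(phi_ipsi, phi_contra) {
  if (!identical(dim(phi_ipsi), dim(phi_contra))) stop("feature shapes differ")
  pseudo_huber_map(phi_ipsi - phi_contra)
}

#' Training configuration
#'
#' SGD-with-momentum defaults for the small fully convolutional backbone:
#' 50 epochs, batch 32, learning rate 1e-2 with cosine decay, momentum 0.9,
#' weight decay 1e-4, global gradient-norm clipping at 5 (the anomalous
#' branch of the pseudo-Huber objective has steep gradients when an anomaly
#' scores near zero).
#'
#' @param epochs,batch_size,lr,momentum,weight_decay,grad_clip,eps numeric
#'   optimizer settings.
#' @param lr_schedule `"cosine"` (decay to 0 over the run) or `"constant"`.
#' @param augment apply random up-down flips and small integer translations
#'   to each training batch (never at inference).  Label-preserving for
#'   anatomy that is statistically symmetric about the horizontal axis;
#'   left-right flips are *not* used because they would break the canonical
#'   chest-wall orientation.  Off by default: on phantoms it increased
#'   run-to-run variance without a reliable accuracy gain.
#' @param max_shift maximum augmentation translation in pixels.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 32, lr = 1e-2,
                         momentum = 0.9, weight_decay = 1e-4,
                         lr_schedule = c("cosine", "constant"),
                         grad_clip = 5, eps = 1e-6,
                         augment = FALSE, max_shift = 3) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, max_shift >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_schedule = lr_schedule, grad_clip = grad_clip, eps = eps,
                 augment = isTRUE(augment),
                 max_shift = as.integer(max_shift)),
            class = "train_config")
}

# Random up-down flip + integer translation of a (H, W, 1, N) batch (and an
# optional paired batch transformed identically, for contralateral pairs).
augment_batch <- function(xb, xb2 = NULL, max_shift = 3) {
  d <- dim(xb)
  H <- d[1]; W <- d[2]
  shift2 <- function(m, dr, dc) {
    out <- matrix(m[1, 1], H, W)  # pad with the corner (outside-breast) value
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  for (n in seq_len(d[4])) {
    flip <- runif(1) < 0.5
    dr <- sample.int(2 * max_shift + 1, 1) - max_shift - 1
    dc <- sample.int(2 * max_shift + 1, 1) - max_shift - 1
    m <- xb[, , 1, n]
    if (flip) m <- m[H:1, , drop = FALSE]
    if (dr != 0 || dc != 0) m <- shift2(m, dr, dc)
    xb[, , 1, n] <- m
    if (!is.null(xb2)) {
      m2 <- xb2[, , 1, n]
      if (flip) m2 <- m2[H:1, , drop = FALSE]
      if (dr != 0 || dc != 0) m2 <- shift2(m2, dr, dc)
      xb2[, , 1, n] <- m2
    }
  }
  list(x = xb, x2 = xb2)
}

detector_objectives <- c("fcdd", "fcdd-sym", "hsc", "bce")

#' Per-image z-score standardization
#'
#' Standardizes each image to zero mean and unit variance (SD floored at
#' 1e-6 so constant images map to zeros).  This is the model-input
#' normalization applied by default before the backbone: MIP intensities in
#' `[0, 1]` concentrate near zero and standardization puts them on the
#' scale the weight initialisation assumes.
#'
#' @param images `H x W` matrix or `H x W x N` array.
#' @return Array of the same shape.
#' @export
standardize_images <- function(images) {
  d <- dim(images)
  if (length(d) == 2) {
    s <- max(sd(as.vector(images)), 1e-6)
    return((images - mean(images)) / s)
  }
  for (i in seq_len(d[3])) {
    v <- images[, , i]
    images[, , i] <- (v - mean(v)) / max(sd(as.vector(v)), 1e-6)
  }
  images
}

# Apply a detector's recorded input normalization.
prep_images <- function(detector, images) {
  if (isTRUE(detector$standardize)) standardize_images(images) else images
}

#' Train an anomaly detector on unilateral breast images
#'
#' Optimises one of the four objectives over a stack of canonical-orientation
#' images.  FCDD averages the pseudo-Huber anomaly map into a breast score
#' and applies the semisupervised one-class loss; FCDD-Symmetric scores each
#' breast against its contralateral feature map (gradients flow through both
#' branches of the shared backbone); HSC applies the same loss to the pooled
#' embedding; BCE trains a conventional classifier head.  Benign-only
#' training is supported for the anomaly objectives (the anomalous loss
#' branch is simply absent).
#'
#' Initialisation and data order are derived deterministically from `seed`,
#' so a rerun with identical inputs reproduces the weights exactly.
#'
#' @param images `H x W x N` array of images in `[0, 1]`.
#' @param labels length-`N` vector in `{0, 1}`.
#' @param objective one of `"fcdd"`, `"fcdd-sym"`, `"hsc"`, `"bce"`.
#' @param backbone a [backbone_config()]; defaults to the standard stack at
#'   the input image size.
#' @param config a [train_config()].
#' @param contra for `"fcdd-sym"`: `H x W x N` array of the matching
#'   contralateral images (see [contralateral_index()]).
#' @param standardize apply per-image z-score standardization (see
#'   [standardize_images()]); recorded on the detector and applied
#'   consistently at inference.
#' @param center hypersphere centre for the FCDD/HSC objectives: `"zero"`
#'   (the plain formulation) or `"init-mean"` — the spatial mean feature
#'   vector of the training data under the freshly initialised network,
#'   held fixed throughout training.  With only benign training data the
#'   zero-centre objective admits the trivial collapse `phi == 0` (zero
#'   weights reach zero loss); anchoring the centre at the initial feature
#'   mean removes that degenerate minimiser, so `"init-mean"` is the
#'   recommended setting for benign-only (one-class) training.  Ignored by
#'   BCE and FCDD-Symmetric (whose centre is the contralateral breast).
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return An object of class `mip_detector`: backbone net, optional BCE
#'   head, objective, configs, per-epoch `loss_log`, and seed.
#' @export
train_detector <- function(images, labels,
                           objective = c("fcdd", "fcdd-sym", "hsc", "bce"),
                           backbone = NULL, config = train_config(),
                           contra = NULL, standardize = TRUE,
                           center = c("zero", "init-mean"), seed = 1L,
                           verbose = FALSE) {
  objective <- match.arg(objective)
  center <- match.arg(center)
  d <- dim(images)
  if (length(d) == 2) { images <- array(images, c(d, 1)); d <- dim(images) }
  stopifnot(length(d) == 3, length(labels) == d[3])
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (all(y == 1)) stop("training requires at least one benign image")
  if (objective == "fcdd-sym") {
    if (is.null(contra) || !identical(dim(contra), d))
      stop("fcdd-sym requires a contralateral image array matching `images`")
  }
  if (is.null(backbone)) backbone <- backbone_config(input_size = d[1:2])
  if (standardize) {
    images <- standardize_images(images)
    if (!is.null(contra)) contra <- standardize_images(contra)
  }
  N <- d[3]
  uv <- prod(backbone$grid)

  net <- backbone_init(backbone, seed = seed_stream(seed, "init"))
  ctr <- NULL
  if (center == "init-mean" && objective %in% c("fcdd", "hsc")) {
    sub <- seq_len(N)
    if (N > 64) sub <- with_seed(seed_stream(seed, "center"),
                                 sort(sample.int(N, 64)))
    phi0 <- backbone_forward(net, images[, , sub, drop = FALSE])$phi
    ctr <- apply(phi0, 3, mean)
  }
  head <- NULL
  if (objective == "bce") {
    head <- with_seed(seed_stream(seed, "head"), list(
      w = rnorm(backbone$embed_dim, sd = 1 / sqrt(backbone$embed_dim)),
      b = 0))
    head_state <- list(vw = numeric(backbone$embed_dim), vb = 0)
  }
  state <- NULL
  loss_log <- numeric(config$epochs)

  with_seed(seed_stream(seed, "order"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- if (config$lr_schedule == "cosine")
        config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      else config$lr
      idx <- sample.int(N)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- array(images[, , b, drop = FALSE], c(d[1], d[2], 1, length(b)))
        yb <- y[b]
        xcb <- if (objective == "fcdd-sym")
          array(contra[, , b, drop = FALSE], c(d[1], d[2], 1, length(b)))
        if (config$augment) {
          aug <- augment_batch(xb, xcb, config$max_shift)
          xb <- aug$x; xcb <- aug$x2
        }
        fw <- backbone_forward(net, xb, keep_cache = TRUE, training = TRUE)
        net <- fw$net
        phi <- fw$phi
        if (objective == "fcdd-sym") {
          fwc <- backbone_forward(net, xcb, keep_cache = TRUE,
                                  training = TRUE)
          net <- fwc$net
          dphi <- phi - fwc$phi
          A <- pseudo_huber_map(dphi)
          if (length(dim(A)) == 2) A <- array(A, c(dim(A), 1))
          s <- breast_score(A)
          loss <- huber_objective_loss(s, yb, config$eps)
          gs <- huber_objective_grad(s, yb, config$eps)
          dA <- sweep(array(1, dim(A)), 3, gs / uv, "*")
          denom <- sqrt(apply(dphi^2, c(1, 2, 4), sum) + 1)
          gphi <- dphi * aperm(array(dA / denom,
                    c(dim(A)[1], dim(A)[2], dim(A)[3], dim(phi)[3])),
                    c(1, 2, 4, 3))
          bk1 <- backbone_backward(net, fw$cache, gphi)
          bk2 <- backbone_backward(net, fwc$cache, -gphi)
          grads <- list(
            gw = Map(`+`, bk1$gw, bk2$gw),
            gb = Map(`+`, bk1$gb, bk2$gb),
            dgamma = Map(`+`, bk1$dgamma, bk2$dgamma),
            dbeta = Map(`+`, bk1$dbeta, bk2$dbeta))
        } else if (objective == "fcdd") {
          phie <- if (is.null(ctr)) phi else sweep(phi, 3, ctr, "-")
          A <- pseudo_huber_map(phie)
          if (length(dim(A)) == 2) A <- array(A, c(dim(A), 1))
          s <- breast_score(A)
          loss <- huber_objective_loss(s, yb, config$eps)
          gs <- huber_objective_grad(s, yb, config$eps)
          denom <- sqrt(apply(phie^2, c(1, 2, 4), sum) + 1)
          fac <- sweep(1 / denom, 3, gs / uv, "*")  # u x v x N
          gphi <- phie * aperm(array(fac, c(dim(fac), dim(phie)[3])), c(1, 2, 4, 3))
          grads <- backbone_backward(net, fw$cache, gphi)
        } else if (objective == "hsc") {
          z <- pooled_embedding(phi)
          if (!is.null(ctr)) z <- z - ctr
          h <- sqrt(colSums(z^2) + 1) - 1
          loss <- huber_objective_loss(h, yb, config$eps)
          gh <- huber_objective_grad(h, yb, config$eps)
          gz <- sweep(z, 2, gh / sqrt(colSums(z^2) + 1), "*")
          gphi <- aperm(array(gz / uv, c(dim(gz), dim(phi)[1], dim(phi)[2])),
                        c(3, 4, 1, 2))
          grads <- backbone_backward(net, fw$cache, gphi)
        } else {  # bce
          z <- pooled_embedding(phi)
          logits <- as.numeric(crossprod(z, head$w)) + head$b
          loss <- bce_loss(logits, yb)
          gl <- (stats::plogis(logits) - yb) / length(yb)
          gz <- outer(head$w, gl)          # d x N
          gphi <- aperm(array(gz / uv, c(dim(gz), dim(phi)[1], dim(phi)[2])),
                        c(3, 4, 1, 2))
          grads <- backbone_backward(net, fw$cache, gphi)
          gw_head <- as.numeric(z %*% gl)
          head_state$vw <- config$momentum * head_state$vw +
            gw_head + config$weight_decay * head$w
          head_state$vb <- config$momentum * head_state$vb + sum(gl)
          head$w <- head$w - lr * head_state$vw
          head$b <- head$b - lr * head_state$vb
        }
        if (!is.finite(loss))
          stop(sprintf("NaN/Inf loss at epoch %d (objective %s); reduce lr",
                       epoch, objective))
        upd <- sgd_step(net, grads, state, lr, config$momentum,
                        config$weight_decay, config$grad_clip)
        net <- upd$net; state <- upd$state
        ep_loss <- ep_loss + loss * length(b)
      }
      loss_log[epoch] <- ep_loss / N
      if (verbose) message(sprintf("epoch %3d  lr %.4g  loss %.5f",
                                   epoch, lr, loss_log[epoch]))
    }
  })
  structure(list(net = net, head = head, objective = objective,
                 backbone = backbone, train = config,
                 standardize = standardize, center = ctr,
                 loss_log = loss_log, seed = as.integer(seed)),
            class = "mip_detector")
}

#' @export
print.mip_detector <- function(x, ...) {
  cat(sprintf("mip_detector: objective=%s, %d conv layers, grid %dx%d, r=%d px, s=%d\n",
              x$objective, length(x$net$layers), x$backbone$grid[1],
              x$backbone$grid[2], x$backbone$receptive_field, x$backbone$stride))
  cat(sprintf("  final training loss: %.5f (%d epochs)\n",
              utils::tail(x$loss_log, 1), length(x$loss_log)))
  invisible(x)
}

#' Low-resolution anomaly map(s) for images
#'
#' @param detector a trained `mip_detector` (FCDD-family or HSC).
#' @param images `H x W` matrix or `H x W x N` array.
#' @param contra contralateral images (required for `"fcdd-sym"`).
#' @return `u x v` matrix or `u x v x N` array of nonnegative scores.
#' @export
anomaly_map <- function(detector, images, contra = NULL) {
  phi <- backbone_forward(detector$net, prep_images(detector, images))$phi
  if (detector$objective == "fcdd-sym") {
    if (is.null(contra)) stop("fcdd-sym scoring needs contralateral images")
    phic <- backbone_forward(detector$net, prep_images(detector, contra))$phi
    symmetric_anomaly_map(phi, phic)
  } else {
    if (!is.null(detector$center)) phi <- sweep(phi, 3, detector$center, "-")
    pseudo_huber_map(phi)
  }
}

#' Image-level scores from a trained detector
#'
#' FCDD and FCDD-Symmetric: mean of the anomaly map.  HSC: pseudo-Huber
#' norm of the pooled embedding.  BCE: the classifier logit.  Higher always
#' means more anomalous/malignant.
#'
#' @inheritParams anomaly_map
#' @return Numeric vector of length `N`.
#' @export
detector_scores <- function(detector, images, contra = NULL) {
  if (detector$objective %in% c("fcdd", "fcdd-sym")) {
    A <- anomaly_map(detector, images, contra)
    breast_score(A)
  } else if (detector$objective == "hsc") {
    z <- pooled_embedding(
      backbone_forward(detector$net, prep_images(detector, images))$phi)
    z <- as.matrix(z)
    if (!is.null(detector$center)) z <- z - detector$center
    sqrt(colSums(z^2) + 1) - 1
  } else {
    bce_head(backbone_forward(detector$net, prep_images(detector, images))$phi,
             detector$head)
  }
}

#' Index of the contralateral image for each manifest row
#'
#' @param manifest a cohort manifest data frame.
#' @return Integer vector: `idx[i]` is the row of the opposite-laterality
#'   image of the same exam (`NA` if absent).
#' @export
contralateral_index <- function(manifest) {
  key <- paste(manifest$exam_id, manifest$laterality)
  opp <- paste(manifest$exam_id,
               ifelse(manifest$laterality == "left", "right", "left"))
  match(opp, key)
}
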