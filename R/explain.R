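#' Construct an explanation map object
#'
#' @param pixels full-resolution nonnegative map matrix.
#' @param source one of `"fcdd"`, `"fcdd-sym"`, `"hsc-gradcam"`,
#'   `"bce-gradcam"`.
#' @param normalization `"raw"`, `"local"` or `"global"`.
#' @return An `explanation_map` object.
#' @export
explanation_map <- function(pixels,
                            source = c("fcdd", "fcdd-sym", "hsc-gradcam",
                                       "bce-gradcam"),
                            normalization = c("raw", "local", "global")) {
  source <- match.arg(source)
  normalization <- match.arg(normalization)
  if (normalization == "raw" && any(pixels < 0))
    stop("raw explanation maps must be nonnegative")
  if (normalization != "raw" && (any(pixels < 0) || any(pixels > 1)))
    stop("normalized explanation maps must lie in [0, 1]")
  structure(list(pixels = pixels, source = source,
                 normalization = normalization),
            class = "explanation_map")
}

# Centred square Gaussian kernel, normalised to sum 1.
gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  ax <- seq(-half, half)
  k <- outer(exp(-0.5 * (ax / sigma)^2), exp(-0.5 * (ax / sigma)^2))
  k / sum(k)
}

#' Upsample a low-resolution anomaly map with a fixed Gaussian kernel
#'
#' The model's native explanation: each cell of the low-resolution anomaly
#' map deposits its score as a fixed (non-learned) Gaussian bump of kernel
#' size `r` (the backbone's receptive field) centred on the cell's
#' receptive-field centre, cells being `s` pixels apart (the output stride).
#' This is a transposed convolution with a normalised Gaussian kernel, so
#' the operation is linear, preserves nonnegativity, and conserves total
#' mass except where bumps are truncated at the image boundary.
#'
#' @param A low-resolution anomaly map (`u x v` matrix, nonnegative).
#' @param r kernel size in pixels (receptive field; must be `>= s`).
#' @param s output stride in pixels.
#' @param sigma Gaussian width; defaults to `r / 4`.
#' @param out_size `c(H, W)` of the full-resolution output; defaults to
#'   `c(u, v) * s`.
#' @param source label recorded on the returned map.
#' @return An [explanation_map()] with `normalization = "raw"`.
#' @export
upsample_heatmap <- function(A, r, s, sigma = r / 4,
                             out_size = dim(A) * s, source = "fcdd") {
  stopifnot(is.matrix(A))
  if (any(A < 0)) stop("anomaly map must be nonnegative")
  if (r < s) stop("kernel size r must cover the stride s")
  kern <- gaussian_kernel(r, sigma)
  H <- out_size[1]; W <- out_size[2]
  out <- matrix(0, H, W)
  half <- (r - 1) %/% 2
  for (i in seq_len(nrow(A))) {
    # receptive-field centre of cell i: pixel floor((i - 0.5) * s) + 1
    ci <- floor((i - 0.5) * s) + 1
    rows <- (ci - half):(ci + r - 1 - half)
    rok <- rows >= 1 & rows <= H
    for (j in seq_len(ncol(A))) {
      a <- A[i, j]
      if (a == 0) next
      cj <- floor((j - 0.5) * s) + 1
      cols <- (cj - half):(cj + r - 1 - half)
      cok <- cols >= 1 & cols <= W
      out[rows[rok], cols[cok]] <- out[rows[rok], cols[cok]] +
        a * kern[rok, cok, drop = FALSE]
    }
  }
  explanation_map(out, source = source)
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping for the comparator models:
#' channel weights are the spatial means of the gradient of a scalar target
#' with respect to the activations of a convolutional layer; the map is the
#' ReLU of the weighted channel sum, bilinearly upsampled to image size.
#' The target is the classifier logit for BCE and the pooled pseudo-Huber
#' anomaly score `h` for HSC; adding a constant to the target leaves the
#' map unchanged.
#'
#' @param detector a trained `mip_detector` with objective `"bce"` or
#'   `"hsc"`.
#' @param image a single `H x W` image.
#' @param layer index of the convolutional layer whose activations are
#'   weighted; defaults to the last layer.
#' @return An [explanation_map()] (`H x W`, raw).
#' @export
gradcam <- function(detector, image, layer = NULL) {
  if (!detector$objective %in% c("bce", "hsc"))
    stop("gradcam is defined for the BCE and HSC comparators")
  stopifnot(is.matrix(image))
  L <- length(detector$net$layers)
  if (is.null(layer)) layer <- L
  if (layer < 1 || layer > L) stop("layer index out of range")
  fw <- backbone_forward(detector$net, prep_images(detector, image),
                         keep_cache = TRUE)
  phi <- fw$phi
  uv <- prod(dim(phi)[1:2])
  # d(target)/d(phi)
  if (detector$objective == "bce") {
    gz <- detector$head$w
  } else {
    z <- pooled_embedding(phi)[, 1]
    if (!is.null(detector$center)) z <- z - detector$center
    gz <- z / sqrt(sum(z^2) + 1)
  }
  gphi <- aperm(array(gz / uv, c(length(gz), dim(phi)[1], dim(phi)[2], 1)),
                c(2, 3, 1, 4))
  act <- fw$cache[[layer]]$act
  if (layer == L) {
    gact <- gphi
  } else {
    bk <- backbone_backward(detector$net, fw$cache, gphi, upto = layer + 1L)
    gact <- bk$gact[[layer]]
  }
  weights <- apply(gact[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (k in seq_along(weights)) cam <- cam + weights[k] * act[, , k, 1]
  cam <- pmax(cam, 0)
  up <- resize_bilinear(cam, nrow(image), ncol(image))
  explanation_map(pmax(up, 0),
                  source = paste0(detector$objective, "-gradcam"))
}

#' Normalize a set of explanation maps for display
#'
#' `local` min-max scales every map independently to `[0, 1]` (facilitates
#' comparisons between models on one breast); `global` uses a single
#' min/max over the whole set (facilitates comparisons across cases for one
#' model).  A constant map normalizes to all zeros.
#'
#' @param maps a list of [explanation_map()] objects (or plain matrices).
#' @param mode `"local"` or `"global"`.
#' @return A list of `explanation_map` objects in `[0, 1]`.
#' @export
normalize_maps <- function(maps, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (length(maps) == 0) stop("empty map list")
  px <- lapply(maps, function(m) if (inherits(m, "explanation_map")) m$pixels else m)
  src <- vapply(maps, function(m)
    if (inherits(m, "explanation_map")) m$source else "fcdd", character(1))
  scale01 <- function(m, lo, hi) {
    if (hi > lo) (m - lo) / (hi - lo) else m * 0
  }
  if (mode == "global") {
    lo <- min(vapply(px, min, numeric(1)))
    hi <- max(vapply(px, max, numeric(1)))
    out <- lapply(px, scale01, lo = lo, hi = hi)
  } else {
    out <- lapply(px, function(m) scale01(m, min(m), max(m)))
  }
  Map(function(m, s) explanation_map(m, source = s, normalization = mode),
      out, src)
}

#' Write an explanation map (with optional truth-mask contour) as PNG
#'
#' Writes the `[0, 1]`-normalized map as a grayscale PNG; with a truth
#' mask, writes an RGB overlay instead (map in the red channel, the
#' underlying image in gray, mask boundary in green) for visual review.
#'
#' @param map an [explanation_map()] (normalized) or matrix in `[0, 1]`.
#' @param path output PNG path.
#' @param image optional underlying image for the overlay.
#' @param truth_mask optional binary mask whose boundary is drawn.
#' @return The path, invisibly.
#' @export
write_heatmap_png <- function(map, path, image = NULL, truth_mask = NULL) {
  m <- if (inherits(map, "explanation_map")) map$pixels else map
  m <- pmin(pmax(m, 0), 1)
  if (is.null(image) && is.null(truth_mask)) {
    png::writePNG(m, path)
    return(invisible(path))
  }
  base <- if (is.null(image)) m * 0 else pmin(pmax(image, 0), 1)
  rgb <- array(0, c(dim(m), 3))
  rgb[, , 1] <- pmin(1, base * 0.7 + m)
  rgb[, , 2] <- base * 0.7
  rgb[, , 3] <- base * 0.7
  if (!is.null(truth_mask)) {
    mk <- truth_mask != 0
    # boundary = mask pixels with at least one non-mask 4-neighbour
    pad <- function(mm) rbind(FALSE, cbind(FALSE, mm, FALSE), FALSE)
    p <- pad(mk)
    nb <- p[1:nrow(mk), 2:(ncol(mk) + 1)] & p[3:(nrow(mk) + 2), 2:(ncol(mk) + 1)] &
      p[2:(nrow(mk) + 1), 1:ncol(mk)] & p[2:(nrow(mk) + 1), 3:(ncol(mk) + 2)]
    edge <- mk & !nb
    rgb[, , 2][edge] <- 1
    rgb[, , 1][edge] <- 0
    rgb[, , 3][edge] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Pixelwise AUC of an explanation map against a truth mask
#'
#' Rank-based (Mann-Whitney) AUC of the map values, with pixels inside the
#' annotation labelled abnormal and all others normal; ties count one half.
#' Higher values indicate greater spatial agreement with the annotation.
#' The statistic is invariant under strictly monotone transforms of the
#' map, so local min-max normalization does not change it.  For a
#' single-class mask (e.g. a benign image with an empty mask) the AUC is
#' undefined and `NA` is returned.
#'
#' @param map an [explanation_map()] or plain matrix.
#' @param truth_mask binary matrix of the same size.
#' @return AUC in `[0, 1]`, or `NA_real_` if undefined.
#' @export
pixelwise_auc <- function(map, truth_mask) {
  m <- if (inherits(map, "explanation_map")) map$pixels else map
  if (!identical(dim(m), dim(truth_mask))) stop("map and mask sizes differ")
  roc_auc(as.vector(m), as.vector(truth_mask != 0))
}
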