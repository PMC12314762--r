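#' Subtraction maximum-intensity projection
#'
#' Computes the voxelwise difference of the first post-contrast and the
#' pre-contrast volume, clips negative differences to zero (subtraction MIPs
#' visualise enhancement; negative values are noise or motion), and projects
#' the maximum along the chosen axis, yielding a 2-D bilateral MIP.
#'
#' @param pre,post 3-D intensity arrays of equal shape (e.g. read from NIfTI
#'   with `RNifti::readNifti()`).
#' @param axis projection axis (1, 2 or 3).
#' @return A matrix (the remaining two dimensions, in order).
#' @examples
#' pre <- array(0, c(4, 4, 3)); post <- pre; post[2, 3, 1] <- 5
#' subtraction_mip(pre, post)[2, 3]
#' @export
subtraction_mip <- function(pre, post, axis = 3) {
  if (!identical(dim(pre), dim(post))) stop("pre and post shapes differ")
  if (length(dim(pre)) != 3) stop("expected 3-d volumes")
  if (!axis %in% 1:3) stop("axis out of range")
  if (any(!is.finite(pre)) || any(!is.finite(post))) stop("non-finite intensities")
  diffv <- pmax(post - pre, 0)
  apply(diffv, setdiff(1:3, axis), max)
}

#' Split a bilateral MIP into two canonical single-breast images
#'
#' Columns `[1, midline]` become the left image; the remaining columns are
#' mirrored horizontally so that both outputs share one canonical
#' orientation (chest wall on the same side), which lets a single model
#' serve both lateralities and supports contralateral pairing.
#'
#' @param mip bilateral MIP matrix.
#' @param midline split column (last column of the left half); defaults to
#'   `floor(W / 2)`.
#' @return List with `left` and `right` matrices (widths differ by at most 1).
#' @seealso [join_bilateral()] for the exact inverse.
#' @export
split_bilateral <- function(mip, midline = NULL) {
  w <- ncol(mip)
  if (is.null(w) || w < 2) stop("degenerate MIP width")
  if (is.null(midline)) midline <- w %/% 2
  if (midline < 1 || midline >= w) stop("midline outside image")
  list(left = mip[, seq_len(midline), drop = FALSE],
       right = mirror_horizontal(mip[, (midline + 1):w, drop = FALSE]))
}

#' Reassemble a bilateral MIP from its canonical halves
#'
#' Exact inverse of [split_bilateral()]: un-mirrors the right half and
#' concatenates.
#'
#' @param left,right canonical single-breast matrices.
#' @return The bilateral MIP matrix.
#' @export
join_bilateral <- function(left, right) {
  cbind(left, mirror_horizontal(right))
}

# Align-corners bilinear resampling of a matrix to target size.
resize_bilinear <- function(m, target_h, target_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == target_h && w == target_w) return(m)
  interp_rows <- function(mm, n_out) {
    n_in <- nrow(mm)
    if (n_in == n_out) return(mm)
    if (n_in == 1) return(matrix(mm, n_out, ncol(mm), byrow = TRUE))
    xo <- seq(1, n_in, length.out = n_out)
    apply(mm, 2, function(col) approx(seq_len(n_in), col, xout = xo)$y)
  }
  m <- interp_rows(m, target_h)
  t(interp_rows(t(m), target_w))
}

#' Normalize intensities and resample to the model input size
#'
#' Clips intensities to the given quantiles (robust to hot pixels), min-max
#' scales the result to `[0, 1]`, and resamples to the target size with
#' align-corners bilinear interpolation (corner pixels are preserved
#' exactly).  A constant input maps to all zeros rather than dividing by a
#' zero range.
#'
#' @param pixels image matrix.
#' @param target_h,target_w output size; defaults keep the input size.
#' @param clip_quantiles length-2 vector of lower/upper clip quantiles.
#' @return A `target_h x target_w` matrix with values in `[0, 1]`.
#' @export
normalize_and_resize <- function(pixels, target_h = nrow(pixels),
                                 target_w = ncol(pixels),
                                 clip_quantiles = c(0, 0.995)) {
  if (length(pixels) == 0) stop("empty image")
  q <- quantile(pixels, clip_quantiles, names = FALSE)
  px <- pmin(pmax(pixels, q[1]), q[2])
  rng <- q[2] - q[1]
  px <- if (rng > 0) (px - q[1]) / rng else px * 0
  resize_bilinear(px, target_h, target_w)
}
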