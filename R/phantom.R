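#' Configuration for the synthetic breast-MIP phantom cohort
#'
#' Builds and validates the parameter set that controls phantom generation.
#' Phantoms emulate the statistical structure that a screening anomaly
#' detector faces on subtraction-MIP images: a half-ellipse breast region,
#' smooth parenchymal-enhancement (BPE) texture whose amplitude grows with
#' BPE category, approximate mirror symmetry between the two breasts of an
#' exam, and two lesion phenotypes — compact bright masses and diffuse
#' low-contrast nonmass enhancement (NME) — with pixel-level truth masks.
#'
#' Lesion geometry defaults are expressed in pixels at a 128x128 reference
#' frame and are scaled linearly (areas quadratically) when another image
#' size is requested, so a cohort rendered at 64x64 has the same relative
#' lesion load as the default.
#'
#' @param image_height,image_width phantom size in pixels per breast.
#' @param n_patients number of patients in the cohort.
#' @param exams_per_patient probability vector over 1, 2, ... exams.
#' @param prevalence breast-level malignancy rate in `[0, 1]`.
#' @param known_cancer_fraction fraction of malignant exams flagged as known
#'   cancer at scan time (the flag applies to both breasts of the exam, as a
#'   known-cancer indication is an exam-level property).  The default 0.94,
#'   combined with `prevalence = 0.2`, leaves a residual prevalence of about
#'   1.85% once known-cancer exams are removed — the imbalanced screening
#'   condition.
#' @param bpe_mix probabilities over BPE categories
#'   minimal / mild / moderate / marked.
#' @param bpe_amplitudes texture amplitude per BPE category; must be strictly
#'   increasing.
#' @param mass_params list with `radius_range` (half-max radius, px) and
#'   `contrast_range`.
#' @param nme_params list with `area_range` (px^2), `contrast_range` (lower
#'   than the mass range) and `irregularity` (smoothing scale of the noise
#'   field that is thresholded into the NME mask, px).
#' @param lesion_type_mix probabilities over `c(mass, NME)`.
#' @param stage_cuts mask-area cut points (px^2) separating the
#'   Tis/T1/T2/T3-like size bins.
#' @param symmetry_rho correlation in `[0, 1]` between the left and right
#'   background fields of one exam.
#' @param field_scale smoothing scale (px) of the low-pass Gaussian random
#'   field used as BPE texture.
#' @param base_level mean enhancement level inside the breast region.
#' @param noise_sigma additive pixel noise SD.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `phantom_config` (a validated list).
#' @examples
#' cfg <- phantom_config(n_patients = 10, image_height = 64, image_width = 64)
#' cfg$receptive_scale
#' @export
phantom_config <- function(image_height = 128,
                           image_width = 128,
                           n_patients = 100,
                           exams_per_patient = c(0.45, 0.30, 0.25),
                           prevalence = 0.2,
                           known_cancer_fraction = 0.94,
                           bpe_mix = c(minimal = 0.43, mild = 0.30,
                                       moderate = 0.17, marked = 0.10),
                           bpe_amplitudes = c(minimal = 0.05, mild = 0.09,
                                              moderate = 0.14, marked = 0.22),
                           mass_params = list(radius_range = c(4, 10),
                                              contrast_range = c(0.25, 0.55)),
                           nme_params = list(area_range = c(80, 500),
                                             contrast_range = c(0.10, 0.22),
                                             irregularity = 2.5),
                           lesion_type_mix = c(mass = 0.6, NME = 0.4),
                           stage_cuts = c(160, 280, 430),
                           symmetry_rho = 0.8,
                           field_scale = 6,
                           base_level = 0.15,
                           noise_sigma = 0.02,
                           seed = 1L) {
  stopifnot(image_height >= 16, image_width >= 16,
            n_patients >= 1,
            prevalence >= 0, prevalence <= 1,
            known_cancer_fraction >= 0, known_cancer_fraction <= 1,
            symmetry_rho >= 0, symmetry_rho <= 1,
            noise_sigma >= 0, field_scale > 0)
  if (abs(sum(bpe_mix) - 1) > 1e-8) stop("bpe_mix must sum to 1")
  if (abs(sum(exams_per_patient) - 1) > 1e-8)
    stop("exams_per_patient must sum to 1")
  if (abs(sum(lesion_type_mix) - 1) > 1e-8)
    stop("lesion_type_mix must sum to 1")
  if (length(bpe_amplitudes) != 4 || any(diff(bpe_amplitudes) <= 0))
    stop("bpe_amplitudes must be strictly increasing over the four BPE levels")
  if (any(mass_params$contrast_range < 0) || any(nme_params$contrast_range < 0))
    stop("contrast ranges must be nonnegative")
  if (any(diff(stage_cuts) <= 0)) stop("stage_cuts must be increasing")

  # linear scale factor relative to the 128x128 reference frame
  sc <- sqrt((image_height * image_width) / (128 * 128))
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              n_patients = as.integer(n_patients),
              exams_per_patient = exams_per_patient,
              prevalence = prevalence,
              known_cancer_fraction = known_cancer_fraction,
              bpe_mix = bpe_mix,
              bpe_amplitudes = bpe_amplitudes,
              mass_params = list(
                radius_range = mass_params$radius_range * sc,
                contrast_range = mass_params$contrast_range),
              nme_params = list(
                area_range = nme_params$area_range * sc^2,
                contrast_range = nme_params$contrast_range,
                irregularity = nme_params$irregularity * sc),
              lesion_type_mix = lesion_type_mix,
              stage_cuts = stage_cuts * sc^2,
              symmetry_rho = symmetry_rho,
              field_scale = field_scale * sc,
              base_level = base_level,
              noise_sigma = noise_sigma,
              receptive_scale = sc,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

bpe_levels <- c("minimal", "mild", "moderate", "marked")

#' Half-ellipse breast support mask
#'
#' The breast region is modelled as a half-ellipse attached to the chest
#' wall, which in the canonical orientation runs along the left image edge.
#'
#' @param h,w image size in pixels.
#' @return A logical `h x w` matrix, `TRUE` inside the breast.
#' @export
breast_mask <- function(h, w) {
  if (h <= 0 || w <= 0) stop("non-positive image dimensions")
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ry <- 0.42 * h
  rx <- 0.85 * w
  ((cc - 1) / rx)^2 + ((rr - (h + 1) / 2) / ry)^2 <= 1
}

# Separable Gaussian smoothing with reflected edges; sigma in pixels.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  g <- g / sum(g)
  pad_reflect <- function(m, k) {
    top <- m[k:1, , drop = FALSE]
    bot <- m[nrow(m):(nrow(m) - k + 1), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_cols <- function(m) {
    mp <- pad_reflect(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(g)) out <- out + g[i] * mp[(i - 1) + seq_len(nrow(m)), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

# A smooth standardised Gaussian random field (mean 0, SD 1) of size h x w.
smooth_field <- function(h, w, scale) {
  f <- gaussian_smooth(matrix(rnorm(h * w), h, w), scale)
  f <- f - mean(f)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

mirror_horizontal <- function(m) m[, ncol(m):1, drop = FALSE]

#' Generate one bilateral pair of background (benign) phantom breasts
#'
#' The two breasts of an exam share a common low-pass Gaussian random field
#' with weight `symmetry_rho`, plus an independent field with weight
#' `sqrt(1 - rho^2)`, so the pixelwise correlation between the left breast
#' and the mirrored right breast equals `rho`.  The field is scaled by the
#' exam's BPE amplitude, placed on a constant base enhancement level inside
#' the half-ellipse breast mask, degraded with additive Gaussian noise, and
#' clipped to `[0, 1]`.  The right image is mirrored so that anatomy faces
#' the midline, as on a bilateral MIP.
#'
#' Uses the current R RNG state; seed the stream (or pass `seed`) for
#' reproducibility.
#'
#' @param config a [phantom_config()].
#' @param bpe BPE category of the exam.
#' @param seed optional seed applied locally without disturbing the caller's
#'   RNG state.
#' @return A list with `left` and `right` pixel matrices in `[0, 1]` (native
#'   orientation: mirror the right image to obtain the canonical view).
#' @export
generate_background_pair <- function(config, bpe = "minimal", seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_background_pair(config, bpe)))
  bpe <- match.arg(bpe, bpe_levels)
  h <- config$image_height; w <- config$image_width
  rho <- config$symmetry_rho
  amp <- config$bpe_amplitudes[[bpe]]
  msk <- breast_mask(h, w)

  shared <- smooth_field(h, w, config$field_scale)
  fl <- rho * shared + sqrt(1 - rho^2) * smooth_field(h, w, config$field_scale)
  fr <- rho * shared + sqrt(1 - rho^2) * smooth_field(h, w, config$field_scale)

  render <- function(f) {
    px <- (config$base_level + amp * f) * msk
    if (config$noise_sigma > 0) px <- px + matrix(rnorm(h * w, sd = config$noise_sigma), h, w)
    pmin(pmax(px, 0), 1)
  }
  list(left = render(fl), right = mirror_horizontal(render(fr)))
}

#' Render a single lesion inside a breast mask
#'
#' Masses are anisotropic Gaussian bumps; the truth mask is the (elliptical)
#' region above half-maximum, so a nominal half-max radius `r` yields a mask
#' area between `pi*(r/2)^2` and `pi*(1.5*r)^2`.  NME lesions are produced by
#' thresholding a mid-frequency noise field inside a local elliptical
#' neighbourhood, giving irregular, possibly multi-lobed masks with lower
#' contrast.  The truth mask is geometric, i.e. independent of the drawn
#' contrast, so a zero-contrast lesion still has a nonempty mask (and an
#' all-zero intensity field).
#'
#' @param kind `"mass"` or `"NME"`.
#' @param params the matching `mass_params` / `nme_params` list from a
#'   [phantom_config()].
#' @param breast_mask logical support matrix; the lesion mask is guaranteed
#'   to lie entirely inside it.
#' @param seed optional local seed.
#' @return A list with `intensity` (additive enhancement field) and `mask`
#'   (logical truth mask).
#' @export
render_lesion <- function(kind = c("mass", "NME"), params, breast_mask,
                          seed = NULL) {
  kind <- match.arg(kind)
  if (!any(breast_mask)) stop("breast mask is empty")
  if (!is.null(seed)) return(with_seed(seed, render_lesion(kind, params, breast_mask)))
  h <- nrow(breast_mask); w <- ncol(breast_mask)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  for (attempt in seq_len(100)) {
    if (kind == "mass") {
      r <- runif(1, params$radius_range[1], params$radius_range[2])
      contrast <- runif(1, params$contrast_range[1], params$contrast_range[2])
      aspect <- runif(1, 0.6, 1)
      theta <- runif(1, 0, pi)
      ctr <- sample(which(breast_mask), 1)
      cy <- (ctr - 1) %% h + 1
      cx <- (ctr - 1) %/% h + 1
      u <- (rr - cy) * cos(theta) + (cc - cx) * sin(theta)
      v <- -(rr - cy) * sin(theta) + (cc - cx) * cos(theta)
      # half-max radius r along the major axis, aspect*r along the minor
      q <- (u / r)^2 + (v / (aspect * r))^2
      mask <- q <= 1
      sig2 <- 1 / (2 * log(2))  # exp(-q/(2*sig2)) = 1/2 at q = 1
      intensity <- contrast * exp(-q / (2 * sig2))
      intensity[intensity < contrast * 0.01] <- 0
    } else {
      area <- runif(1, params$area_range[1], params$area_range[2])
      contrast <- runif(1, params$contrast_range[1], params$contrast_range[2])
      reach <- sqrt(3 * area / pi)  # loose neighbourhood radius
      ctr <- sample(which(breast_mask), 1)
      cy <- (ctr - 1) %% h + 1
      cx <- (ctr - 1) %/% h + 1
      d2 <- ((rr - cy) / reach)^2 + ((cc - cx) / (0.8 * reach))^2
      region <- d2 <= 1 & breast_mask
      if (sum(region) < 4) next
      f <- smooth_field(h, w, params$irregularity)
      # keep the top pixels of the noise field until the target area is hit
      n_keep <- max(3L, min(sum(region), as.integer(round(area))))
      vals <- f[region]
      thr <- sort(vals, decreasing = TRUE)[n_keep]
      mask <- region & (f >= thr)
      ramp <- gaussian_smooth(mask * 1, params$irregularity)
      if (max(ramp) > 0) ramp <- ramp / max(ramp)
      intensity <- contrast * ramp
      intensity[!mask & intensity < 0.25 * contrast] <- 0
    }
    if (any(mask) && all(breast_mask[mask])) {
      return(list(intensity = intensity, mask = mask))
    }
  }
  stop("lesion could not be placed inside the breast mask after 100 attempts")
}

stage_bins <- c("Tis-like", "T1-like", "T2-like", "T3-like")

stage_from_area <- function(area, cuts) {
  stage_bins[findInterval(area, cuts) + 1]
}

#' Generate a synthetic screening cohort
#'
#' Draws patients, exams and bilateral breast pairs from a
#' [phantom_config()].  At most one breast per exam is malignant; malignant
#' breasts receive a lesion (mass or NME) with a pixel truth mask and a size
#' bin (`stage_proxy`) assigned from the mask area.  Malignant exams are
#' flagged as known cancer with probability `known_cancer_fraction`; the
#' flag is exam-level, so the contralateral benign breast of a known-cancer
#' exam is flagged too (those images are excluded from imbalanced-task test
#' sets downstream).  The realised breast-level malignancy fraction is
#' binomial around `prevalence`.
#'
#' All images are stored in the canonical orientation (chest wall on the
#' left edge), so one detector can serve both lateralities and contralateral
#' pairs are directly comparable.  The cohort is a deterministic function of
#' the configuration, including its seed.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory; when given, images and masks are
#'   written as 8-bit grayscale PNGs and the manifest as
#'   `manifest.csv`, with `image_path` / `mask_path` columns filled in.
#' @return (invisibly, when `out_dir` is given) A list of class
#'   `phantom_cohort`: `manifest` (data frame, one row per unilateral breast
#'   image), `images` (`H x W x N` array in `[0, 1]`) and `masks`
#'   (`H x W x N` 0/1 array), plus the `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    h <- config$image_height; w <- config$image_width
    msk <- breast_mask(h, w)

    rows <- list()
    imgs <- list()
    masks <- list()
    n_img <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", p)
      n_exams <- sample.int(length(config$exams_per_patient), 1,
                            prob = config$exams_per_patient)
      bpe <- sample(bpe_levels, 1, prob = config$bpe_mix)  # patient-level
      for (e in seq_len(n_exams)) {
        eid <- sprintf("%s-E%02d", pid, e)
        exam_malignant <- runif(1) < min(2 * config$prevalence, 1)
        mal_side <- if (exam_malignant) sample(c("left", "right"), 1) else NA
        known <- exam_malignant && runif(1) < config$known_cancer_fraction
        pair <- generate_background_pair(config, bpe = bpe)
        pair$right <- mirror_horizontal(pair$right)  # canonical orientation
        for (side in c("left", "right")) {
          px <- pair[[side]]
          lesion_mask <- matrix(FALSE, h, w)
          lesion_type <- "none"
          stage <- "none"
          label <- 0L
          if (exam_malignant && identical(side, mal_side)) {
            lesion_type <- sample(names(config$lesion_type_mix), 1,
                                  prob = config$lesion_type_mix)
            params <- if (lesion_type == "mass") config$mass_params else config$nme_params
            les <- render_lesion(lesion_type, params, msk)
            px <- pmin(pmax(px + les$intensity, 0), 1)
            lesion_mask <- les$mask
            stage <- stage_from_area(sum(lesion_mask), config$stage_cuts)
            label <- 1L
          }
          n_img <- n_img + 1L
          rows[[n_img]] <- data.frame(
            patient_id = pid, exam_id = eid, laterality = side,
            label = label, known_cancer = known, bpe = bpe,
            lesion_type = lesion_type, stage_proxy = stage,
            image_path = NA_character_, mask_path = NA_character_,
            stringsAsFactors = FALSE)
          imgs[[n_img]] <- px
          masks[[n_img]] <- lesion_mask
        }
      }
    }
    manifest <- do.call(rbind, rows)
    if (config$prevalence > 0 && sum(manifest$label) == 0)
      warning("no malignant breast realised; cohort too small for prevalence ",
              config$prevalence)
    images <- array(unlist(imgs), c(h, w, n_img))
    mask_arr <- array(as.numeric(unlist(masks)), c(h, w, n_img))

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(n_img)) {
        stem <- sprintf("%s_%s", manifest$exam_id[i], manifest$laterality[i])
        ip <- file.path(out_dir, paste0(stem, ".png"))
        png::writePNG(images[, , i], ip, dpi = NULL)
        manifest$image_path[i] <- ip
        if (manifest$label[i] == 1) {
          mp <- file.path(out_dir, paste0(stem, "_mask.png"))
          png::writePNG(mask_arr[, , i], mp)
          manifest$mask_path[i] <- mp
        }
      }
      write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    }
    out <- structure(list(manifest = manifest, images = images,
                          masks = mask_arr, config = config),
                     class = "phantom_cohort")
    if (is.null(out_dir)) out else invisible(out)
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("phantom_cohort: %d breasts / %d exams / %d patients (%dx%d px)\n",
              nrow(m), length(unique(m$exam_id)),
              length(unique(m$patient_id)),
              x$config$image_height, x$config$image_width))
  pv <- prevalence_summary(m$label)
  cat(sprintf("  malignant: %d (%s%%); known-cancer images: %d\n",
              pv$n_pos, format(pv$percent), sum(m$known_cancer)))
  invisible(x)
}
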