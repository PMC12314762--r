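manifest_required_cols <- c("patient_id", "exam_id", "laterality", "label",
                            "known_cancer", "bpe", "lesion_type",
                            "stage_proxy", "image_path", "mask_path")

#' Validate a cohort manifest
#'
#' Checks the required schema (see [read_manifest()]); unknown columns are
#' allowed and preserved.  Errors name the first offending row.
#'
#' @param manifest data frame to validate.
#' @return The manifest, invisibly, if valid.
#' @export
validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0)
    stop("empty manifest")
  missing <- setdiff(manifest_required_cols, names(manifest))
  if (length(missing) > 0)
    stop("manifest missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!manifest$label %in% c(0, 1))
  if (length(bad) > 0)
    stop(sprintf("label outside {0,1} at row %d", bad[1]))
  bad <- which(!manifest$laterality %in% c("left", "right"))
  if (length(bad) > 0)
    stop(sprintf("invalid laterality at row %d", bad[1]))
  if (!is.logical(manifest$known_cancer))
    stop("known_cancer must be logical")
  invisible(manifest)
}

#' Read / write a cohort manifest CSV
#'
#' The manifest has one row per unilateral breast image with the columns
#' `patient_id, exam_id, laterality, label, known_cancer, bpe, lesion_type,
#' stage_proxy, image_path, mask_path`.  Reading validates the schema
#' strictly; unknown extra columns are preserved; a write/read round trip
#' is lossless.
#'
#' @param path CSV file path.
#' @return `read_manifest`: the validated data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(m) == 0) stop("empty manifest: ", path)
  if ("known_cancer" %in% names(m))
    m$known_cancer <- as.logical(m$known_cancer)
  for (col in c("image_path", "mask_path"))  # all-NA columns read as logical
    if (col %in% names(m)) m[[col]] <- as.character(m[[col]])
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load manifest images (and masks) from disk into arrays
#'
#' @param manifest a validated manifest with `image_path` filled in.
#' @return List with `images` (`H x W x N`) and `masks` (`H x W x N`, zero
#'   where no mask file is recorded).
#' @export
load_cohort_images <- function(manifest) {
  validate_manifest(manifest)
  imgs <- lapply(manifest$image_path, function(p) {
    px <- png::readPNG(p)
    if (length(dim(px)) == 3) px <- px[, , 1]
    px
  })
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  images <- array(unlist(imgs), c(h, w, length(imgs)))
  masks <- array(0, c(h, w, length(imgs)))
  for (i in seq_along(imgs)) {
    mp <- manifest$mask_path[i]
    if (!is.na(mp) && nzchar(mp)) {
      mk <- png::readPNG(mp)
      if (length(dim(mk)) == 3) mk <- mk[, , 1]
      masks[, , i] <- as.numeric(mk > 0.5)
    }
  }
  list(images = images, masks = masks)
}

manifest_image_id <- function(manifest) {
  paste(manifest$exam_id, manifest$laterality, sep = "_")
}
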