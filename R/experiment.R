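#' Pixelwise explainability evaluation on a set of images
#'
#' Generates a full-resolution explanation map for each requested image —
#' the native Gaussian-upsampled anomaly map for the FCDD objectives,
#' Grad-CAM saliency for BCE and HSC — and scores it against the pixel
#' truth mask with [pixelwise_auc()].  Benign images (empty masks) have
#' undefined pixelwise AUC and are skipped, matching an explanation test
#' set restricted to malignancies.
#'
#' @param detector a trained `mip_detector`.
#' @param cohort a `phantom_cohort` (or any list with `manifest`, `images`,
#'   `masks` arrays).
#' @param idx manifest row indices to explain; defaults to all malignant
#'   rows.
#' @param sigma Gaussian upsampling width; defaults to `r / 4`.
#' @return Data frame: `image_id`, `pixelwise_auc`, plus the `lesion_type`,
#'   `stage_proxy` and `bpe` strata of each image.
#' @export
explain_scores <- function(detector, cohort, idx = NULL, sigma = NULL) {
  manifest <- cohort$manifest
  if (is.null(idx)) idx <- which(manifest$label == 1)
  if (length(idx) == 0) stop("no malignant images to explain")
  r <- detector$backbone$receptive_field
  s <- detector$backbone$stride
  if (is.null(sigma)) sigma <- r / 4
  contra_all <- contralateral_index(manifest)
  out <- lapply(idx, function(i) {
    img <- cohort$images[, , i]
    if (detector$objective %in% c("fcdd", "fcdd-sym")) {
      contra <- if (detector$objective == "fcdd-sym")
        cohort$images[, , contra_all[i]] else NULL
      A <- anomaly_map(detector, img, contra = contra)
      em <- upsample_heatmap(A, r, s, sigma = sigma, out_size = dim(img),
                             source = detector$objective)
    } else {
      em <- gradcam(detector, img)
    }
    data.frame(image_id = manifest_image_id(manifest)[i],
               pixelwise_auc = pixelwise_auc(em, cohort$masks[, , i]),
               lesion_type = manifest$lesion_type[i],
               stage_proxy = manifest$stage_proxy[i],
               bpe = manifest$bpe[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Train one detector on the given manifest rows of a cohort.
train_on_split <- function(cohort, train_idx, model, backbone, train_cfg,
                           seed) {
  manifest <- cohort$manifest
  imgs <- cohort$images[, , train_idx, drop = FALSE]
  labs <- manifest$label[train_idx]
  contra <- NULL
  if (model == "fcdd-sym") {
    ci <- contralateral_index(manifest)[train_idx]
    keep <- !is.na(ci)
    imgs <- imgs[, , keep, drop = FALSE]
    labs <- labs[keep]
    contra <- cohort$images[, , ci[keep], drop = FALSE]
  }
  train_detector(imgs, labs, objective = model, backbone = backbone,
                 config = train_cfg, contra = contra, seed = seed)
}

score_on_split <- function(detector, cohort, test_idx) {
  contra <- NULL
  if (detector$objective == "fcdd-sym") {
    ci <- contralateral_index(cohort$manifest)[test_idx]
    contra <- cohort$images[, , ci, drop = FALSE]
  }
  detector_scores(detector, cohort$images[, , test_idx, drop = FALSE],
                  contra = contra)
}

#' Run a full phantom screening experiment
#'
#' End-to-end orchestration of the pipeline on one synthetic cohort:
#' simulate (or accept) a cohort, build patient-grouped cross-validation
#' folds per task, train every requested model on each (task, fold, seed)
#' cell, score the held-out images, aggregate detection metrics with chance
#' baselines and paired Wilcoxon comparisons, and (optionally) evaluate
#' pixelwise explainability on the malignant test images of the balanced
#' task.  A single global seed fans out deterministically to the phantom,
#' fold-assignment and per-cell training seeds, so reruns with the same
#' configuration are identical and (fold, seed) pairing across models is
#' exact.
#'
#' @param cohort a `phantom_cohort`, or a [phantom_config()] to simulate.
#' @param models subset of `c("fcdd", "fcdd-sym", "hsc", "bce")`.
#' @param tasks subset of `c("balanced", "imbalanced")`.
#' @param k number of cross-validation folds.
#' @param n_seeds training seeds per fold.
#' @param backbone a [backbone_config()] sized to the cohort images, or
#'   `NULL` for the default.
#' @param train_cfg a [train_config()].
#' @param seed global integer seed.
#' @param explain evaluate pixelwise explainability (balanced task only).
#' @param out_dir optional directory for score CSVs, the report and a run
#'   log; per-cell score files already present are reused (resumability)
#'   unless `force = TRUE`.
#' @param force overwrite existing per-cell score files.
#' @param verbose print progress.
#' @return A list of class `mip_experiment`: `scores` (long table),
#'   `report` (a [metrics_report()]), `explain` (data frame or `NULL`),
#'   `cohort`.
#' @export
run_experiment <- function(cohort, models = c("fcdd", "bce"),
                           tasks = "balanced", k = 5, n_seeds = 1,
                           backbone = NULL, train_cfg = train_config(),
                           seed = 1L, explain = TRUE, out_dir = NULL,
                           force = FALSE, verbose = FALSE) {
  stopifnot(all(models %in% detector_objectives), length(models) >= 1,
            all(tasks %in% c("balanced", "imbalanced")), n_seeds >= 1)
  if (inherits(cohort, "phantom_config")) cohort <- generate_cohort(cohort)
  manifest <- cohort$manifest
  d <- dim(cohort$images)
  if (is.null(backbone)) backbone <- backbone_config(input_size = d[1:2])
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  image_ids <- manifest_image_id(manifest)

  scores <- NULL
  explain_df <- NULL
  for (task in tasks) {
    folds <- grouped_kfold(manifest, k = k,
                           seed = seed_stream(seed, "folds", task),
                           task = task)
    for (model in models) {
      for (fd in folds) {
        for (si in seq_len(n_seeds)) {
          cell_file <- if (!is.null(out_dir))
            file.path(out_dir, sprintf("scores_%s_%s_f%d_s%d.csv",
                                       task, model, fd$fold, si))
          if (!is.null(cell_file) && file.exists(cell_file) && !force) {
            cell <- read.csv(cell_file, stringsAsFactors = FALSE)
          } else {
            tseed <- seed_stream(seed, "train", task, model, fd$fold, si)
            if (verbose)
              message(sprintf("[%s/%s] fold %d seed %d (train n=%d)",
                              task, model, fd$fold, si, length(fd$train_idx)))
            det <- train_on_split(cohort, fd$train_idx, model, backbone,
                                  train_cfg, tseed)
            cell <- data.frame(
              image_id = image_ids[fd$test_idx],
              score = score_on_split(det, cohort, fd$test_idx),
              label = manifest$label[fd$test_idx],
              fold = fd$fold, seed = si, model = model, task = task,
              bpe = manifest$bpe[fd$test_idx],
              lesion_type = manifest$lesion_type[fd$test_idx],
              stage_proxy = manifest$stage_proxy[fd$test_idx],
              stringsAsFactors = FALSE)
            if (!is.null(cell_file)) write.csv(cell, cell_file,
                                               row.names = FALSE)
            if (explain && task == "balanced" && si == 1) {
              mal_test <- fd$test_idx[manifest$label[fd$test_idx] == 1]
              if (length(mal_test) > 0) {
                ex <- explain_scores(det, cohort, idx = mal_test)
                ex$model <- model; ex$fold <- fd$fold
                explain_df <- rbind(explain_df, ex)
              }
            }
          }
          scores <- rbind(scores, cell)
        }
      }
    }
  }
  report <- metrics_report(cell_metrics(scores), scores = scores,
                           seed = seed_stream(seed, "boot"))
  if (!is.null(out_dir)) {
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
    jsonlite::write_json(
      list(seed = seed, models = models, tasks = tasks, k = k,
           n_seeds = n_seeds, n_images = nrow(manifest),
           image_size = d[1:2],
           prevalence = prevalence_summary(manifest$label)$percent),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  }
  structure(list(scores = scores, report = report, explain = explain_df,
                 cohort = cohort),
            class = "mip_experiment")
}

#' @export
print.mip_experiment <- function(x, ...) {
  print(x$report)
  if (!is.null(x$explain)) {
    agg <- tapply(x$explain$pixelwise_auc, x$explain$model, mean,
                  na.rm = TRUE)
    for (m in names(agg))
      cat(sprintf("  pixelwise AUC [%s]: %.3f (n=%d malignant images)\n",
                  m, agg[[m]], sum(x$explain$model == m)))
  }
  invisible(x)
}

#' Expected chance-level AUPR by simulation
#'
#' Draws uniform random scores for a label vector with the given class
#' counts and averages the resulting AUPR (and AUC) over replicates — the
#' random-guess baseline for a screening task, which for AUPR equals the
#' positive-class prevalence.
#'
#' @param n_pos,n_total class counts.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return List with `mean_aupr`, `mean_auc`, `prevalence`.
#' @export
random_baseline <- function(n_pos, n_total, n_rep = 200, seed = 1L) {
  stopifnot(n_pos > 0, n_pos < n_total)
  labels <- c(rep(1, n_pos), rep(0, n_total - n_pos))
  with_seed(seed, {
    ap <- numeric(n_rep); au <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      sc <- runif(n_total)
      ap[i] <- aupr(sc, labels)
      au[i] <- roc_auc(sc, labels)
    }
    list(mean_aupr = mean(ap), mean_auc = mean(au),
         prevalence = n_pos / n_total)
  })
}
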