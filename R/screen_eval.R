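#' Patient-grouped k-fold split with task-aware test filtering
#'
#' Partitions patients (never individual breasts) into `k` near-equal folds,
#' so no patient contributes images to both the training and the test side
#' of any fold.  For the imbalanced screening task, images flagged as known
#' cancer are removed from every test fold — they do not occur in a
#' screening population — but are retained in the training folds, where
#' supplementing with known cancers helps the semisupervised objectives.
#' Class imbalance is otherwise preserved as realised in the cohort.
#'
#' @param manifest cohort manifest data frame.
#' @param k number of folds.
#' @param seed integer seed for the patient shuffle.
#' @param task `"balanced"` (all images eligible for test) or
#'   `"imbalanced"`.
#' @return A list of `k` fold splits, each with `fold`, `task`, `train_idx`
#'   and `test_idx` (row indices into `manifest`).
#' @export
grouped_kfold <- function(manifest, k = 5, seed = 1L,
                          task = c("balanced", "imbalanced")) {
  task <- match.arg(task)
  pats <- unique(manifest$patient_id)
  if (k > length(pats)) stop("more folds than patients")
  fold_of <- with_seed(seed, {
    shuffled <- sample(pats)
    stats::setNames(rep_len(seq_len(k), length(pats)),
                    shuffled)
  })
  lapply(seq_len(k), function(f) {
    test_pat <- names(fold_of)[fold_of == f]
    test_idx <- which(manifest$patient_id %in% test_pat)
    train_idx <- setdiff(seq_len(nrow(manifest)), test_idx)
    if (task == "imbalanced")
      test_idx <- test_idx[!manifest$known_cancer[test_idx]]
    list(fold = f, task = task, train_idx = train_idx, test_idx = test_idx)
  })
}

#' Per-(model, task, fold, seed) detection metrics from a score table
#'
#' @param scores data frame with columns `image_id`, `score`, `label`,
#'   `fold`, `seed`, `model`, `task`.
#' @return Data frame with one row per (model, task, fold, seed) cell:
#'   AUC, AUPR, and the Youden / 95% / 97%-sensitivity operating points
#'   (threshold, sensitivity, specificity, PPV).
#' @export
cell_metrics <- function(scores) {
  req <- c("image_id", "score", "label", "fold", "seed", "model", "task")
  if (!all(req %in% names(scores)))
    stop("score table must have columns: ", paste(req, collapse = ", "))
  cells <- unique(scores[c("model", "task", "fold", "seed")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- scores[scores$model == cl$model & scores$task == cl$task &
                    scores$fold == cl$fold & scores$seed == cl$seed, ]
    yj <- youden_point(sub$score, sub$label)
    s95 <- fixed_sensitivity_point(sub$score, sub$label, 0.95)
    s97 <- fixed_sensitivity_point(sub$score, sub$label, 0.97)
    data.frame(cl,
               n = nrow(sub), prevalence = mean(sub$label),
               auc = roc_auc(sub$score, sub$label),
               aupr = aupr(sub$score, sub$label),
               youden_threshold = yj$threshold,
               youden_sens = yj$sensitivity, youden_spec = yj$specificity,
               youden_ppv = yj$ppv,
               spec_at_sens95 = s95$specificity,
               spec_at_sens97 = s97$specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate a cell-metric table into a screening metrics report
#'
#' Summarises per-cell metrics as mean +/- SD over exactly the
#' folds-by-seeds cells, attaches the chance baselines (AUC 0.5; AUPR equal
#' to the task prevalence), and computes pairwise paired Wilcoxon
#' signed-rank p-values between models on every metric, pairing cells by
#' (fold, seed).
#'
#' @param cells output of [cell_metrics()].
#' @param scores optional score table (as in [cell_metrics()]); when given,
#'   a percentile bootstrap CI of the pooled AUC is attached per
#'   (model, task), resampling breasts from the first seed's pooled test
#'   scores.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed seed for the bootstrap draws.
#' @return A `metrics_report` object: `cells`, `summary` (per model/task
#'   mean/sd), `baselines`, `comparisons` (pairwise p-values), and `cis`
#'   (when `scores` is supplied).
#' @export
metrics_report <- function(cells, scores = NULL, n_boot = 200, seed = 1L) {
  metric_cols <- c("auc", "aupr", "youden_sens", "youden_spec", "youden_ppv",
                   "spec_at_sens95", "spec_at_sens97")
  grp <- unique(cells[c("model", "task")])
  summ <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    g <- grp[i, ]
    sub <- cells[cells$model == g$model & cells$task == g$task, ]
    out <- data.frame(g, n_cells = nrow(sub))
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(sub[[mc]])
      out[[paste0(mc, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[mc]]) else NA_real_
    }
    out
  }))
  baselines <- do.call(rbind, lapply(unique(cells$task), function(tk) {
    sub <- cells[cells$task == tk, ]
    data.frame(task = tk, baseline_auc = 0.5,
               baseline_aupr = mean(sub$prevalence))
  }))
  comparisons <- NULL
  for (tk in unique(cells$task)) {
    mods <- unique(cells$model[cells$task == tk])
    if (length(mods) < 2) next
    prs <- utils::combn(mods, 2, simplify = FALSE)
    for (pr in prs) {
      a <- cells[cells$task == tk & cells$model == pr[1], ]
      b <- cells[cells$task == tk & cells$model == pr[2], ]
      key <- function(d) paste(d$fold, d$seed)
      b <- b[match(key(a), key(b)), ]
      if (nrow(a) < 5 || anyNA(b$auc)) next
      for (mc in metric_cols) {
        comparisons <- rbind(comparisons, data.frame(
          task = tk, model_a = pr[1], model_b = pr[2], metric = mc,
          mean_a = mean(a[[mc]]), mean_b = mean(b[[mc]]),
          p_value = wilcoxon_compare(a[[mc]], b[[mc]]),
          stringsAsFactors = FALSE))
      }
    }
  }
  cis <- NULL
  if (!is.null(scores)) {
    first_seed <- min(scores$seed)
    for (i in seq_len(nrow(grp))) {
      g <- grp[i, ]
      sub <- scores[scores$model == g$model & scores$task == g$task &
                      scores$seed == first_seed, ]
      ci <- bootstrap_ci(sub$score, sub$label, roc_auc, n_boot = n_boot,
                         seed = seed_stream(seed, "ci", g$model, g$task))
      cis <- rbind(cis, data.frame(g, metric = "auc",
                                   lo = ci["lo"], hi = ci["hi"],
                                   row.names = NULL))
    }
  }
  structure(list(cells = cells, summary = summ, baselines = baselines,
                 comparisons = comparisons, cis = cis),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Screening detection metrics (mean ± SD over folds x seeds)\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  [%s] %-9s AUC %.2f±%.2f  AUPR %.2f±%.2f  spec@95 %.2f  spec@97 %.2f\n",
      s$task[i], s$model[i], s$auc_mean[i], s$auc_sd[i],
      s$aupr_mean[i], s$aupr_sd[i],
      s$spec_at_sens95_mean[i], s$spec_at_sens97_mean[i]))
  }
  for (i in seq_len(nrow(x$baselines)))
    cat(sprintf("  baseline [%s]: AUC 0.5, AUPR %.4g (prevalence)\n",
                x$baselines$task[i], x$baselines$baseline_aupr[i]))
  invisible(x)
}

#' Stratified metric summaries
#'
#' Splits a score table by one or more manifest strata (BPE category,
#' lesion type, size bin) and reports AUC/AUPR with counts per stratum.
#' Strata below `min_n` images (or with a single class) are flagged in the
#' output rather than silently dropped.  For lesion-level strata
#' (`lesion_type`, `stage_proxy`) the benign class is shared across strata:
#' each stratum is evaluated as its malignant images against all benign
#' images.
#'
#' @param scores score table as in [cell_metrics()], joined with the strata
#'   columns.
#' @param strata_keys character vector of stratum column names.
#' @param min_n minimum image count for an unflagged stratum.
#' @return Data frame of per-stratum summaries.
#' @export
stratified_report <- function(scores, strata_keys, min_n = 10) {
  lesion_level <- c("lesion_type", "stage_proxy")
  out <- NULL
  for (key in strata_keys) {
    if (!key %in% names(scores)) stop("unknown strata key: ", key)
    lv <- unique(scores[[key]])
    lv <- lv[!lv %in% c("none", NA)]
    for (v in lv) {
      if (key %in% lesion_level) {
        sub <- scores[scores$label == 0 | scores[[key]] == v, ]
      } else {
        sub <- scores[scores[[key]] == v, ]
      }
      both <- length(unique(sub$label)) == 2
      out <- rbind(out, data.frame(
        stratum_key = key, stratum = as.character(v),
        n = nrow(sub), n_pos = sum(sub$label == 1),
        auc = if (both) roc_auc(sub$score, sub$label) else NA_real_,
        aupr = if (both) aupr(sub$score, sub$label) else NA_real_,
        flagged = nrow(sub) < min_n || !both,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Render a metrics report as a Markdown table
#'
#' @param report a [metrics_report()].
#' @return Character vector of Markdown lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
report_markdown <- function(report) {
  s <- report$summary
  fmt <- function(m, sdv) {
    ifelse(is.na(sdv), sprintf("%.2f", m), sprintf("%.2f ± %.2f", m, sdv))
  }
  lines <- c(
    "| Task | Model | AUC | AUPR | PPV (Youden) | Spec (Youden) | Sens (Youden) | Spec@95%Sens | Spec@97%Sens |",
    "|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      s$task[i], s$model[i],
      fmt(s$auc_mean[i], s$auc_sd[i]), fmt(s$aupr_mean[i], s$aupr_sd[i]),
      fmt(s$youden_ppv_mean[i], s$youden_ppv_sd[i]),
      fmt(s$youden_spec_mean[i], s$youden_spec_sd[i]),
      fmt(s$youden_sens_mean[i], s$youden_sens_sd[i]),
      fmt(s$spec_at_sens95_mean[i], s$spec_at_sens95_sd[i]),
      fmt(s$spec_at_sens97_mean[i], s$spec_at_sens97_sd[i])))
  }
  for (i in seq_len(nrow(report$baselines)))
    lines <- c(lines, "",
               sprintf("Random-guess baseline (%s): AUC 0.5, AUPR %.4g.",
                       report$baselines$task[i],
                       report$baselines$baseline_aupr[i]))
  lines
}
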