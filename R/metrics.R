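#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with the standard tie correction: tied
#' score pairs count one half.  Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 labels.
#' @return AUC in `[0, 1]`; `NA_real_` when only one class is present.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated area following the average-precision convention:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over distinct score thresholds taken
#' in decreasing order (tied scores enter together).  For uniformly random
#' scores the expected AP equals the positive-class prevalence, which makes
#' the prevalence the natural chance baseline in imbalanced screening.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`; `NA_real_` when only one class is present.
#' @export
aupr <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y)
  if (n1 == 0 || n1 == length(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp_last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(yy)[grp_last]
  n <- grp_last
  prec <- tp / n
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

operating_point <- function(criterion, threshold, scores, labels) {
  y <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  structure(list(criterion = criterion, threshold = threshold,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("operating_point [%s] thr=%.4g sens=%.3f spec=%.3f ppv=%s\n",
              x$criterion, x$threshold, x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv))))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

# Candidate thresholds: every distinct score plus one above the maximum
# (the all-negative rule).  Classification rule: positive if score >= t.
candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  c(u, u[length(u)] + 1)
}

#' Operating point maximizing the Youden index
#'
#' Sweeps every distinct score threshold (rule: positive when
#' `score >= threshold`), maximizing `J = sensitivity + specificity - 1`.
#' Ties in `J` are broken toward higher specificity (the higher threshold) —
#' in a screening context the more conservative call at equal J.
#'
#' @inheritParams roc_auc
#' @return An `operating_point` (threshold, sensitivity, specificity, PPV,
#'   confusion counts).
#' @export
youden_point <- function(scores, labels) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both classes required")
  thr <- candidate_thresholds(scores)
  best <- NULL; best_j <- -Inf; best_spec <- -Inf
  for (t in thr) {
    op <- operating_point("youden", t, scores, labels)
    j <- op$sensitivity + op$specificity - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && op$specificity > best_spec)) {
      best <- op; best_j <- j; best_spec <- op$specificity
    }
  }
  best
}

#' Operating point at a fixed sensitivity target
#'
#' Chooses the largest threshold whose empirical sensitivity is at least the
#' target (the constraint is met, not approximated); reports specificity and
#' PPV there.  A threshold below the minimum score always attains
#' sensitivity 1, so the constraint is always satisfiable.
#'
#' @inheritParams roc_auc
#' @param target required sensitivity, e.g. `0.95` or `0.97`.
#' @return An `operating_point`.
#' @export
fixed_sensitivity_point <- function(scores, labels, target = 0.95) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both classes required")
  stopifnot(target > 0, target <= 1)
  thr <- candidate_thresholds(scores)
  crit <- sprintf("sens%02d", round(100 * target))
  best <- NULL
  for (t in thr) {  # increasing thresholds; keep the largest feasible
    op <- operating_point(crit, t, scores, labels)
    if (op$sensitivity >= target) best <- op
  }
  best
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired metric values (pairing unit: the
#' same cross-validation fold and seed).  Zero differences are dropped
#' (Wilcoxon convention); if all differences are zero the samples are
#' indistinguishable and `p = 1` is returned.  The exact null distribution
#' is used for `n <= 25` untied differences, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b equal-length numeric vectors of paired metric values.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_compare(c(2.1, 3.2, 4.3, 5.4, 6.5, 7.6),
#'                  c(1, 2, 3, 4, 5, 6))  # all positive, n = 6: p = 2/2^6
#' @export
wilcoxon_compare <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) return(1.0)
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= 25 && !ties
  suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = !use_exact)$p.value)
}

#' Percentile bootstrap confidence interval for a score-based metric
#'
#' Resamples with replacement at the chosen unit (individual breasts, or
#' whole patients to respect within-patient clustering), recomputes the
#' metric, and returns the 2.5/97.5 percentile interval.  Resamples
#' containing a single class (where AUC-type metrics are undefined) are
#' redrawn; if more than half of the attempted resamples are degenerate the
#' function aborts with a diagnostic.
#'
#' @inheritParams roc_auc
#' @param metric_fn function `(scores, labels) -> scalar`, e.g. [roc_auc()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (the interval is deterministic given it).
#' @param unit `"breast"` or `"patient"`.
#' @param patient_id required when `unit = "patient"`.
#' @param conf confidence level.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric_fn = roc_auc, n_boot = 1000,
                         seed = 1L, unit = c("breast", "patient"),
                         patient_id = NULL, conf = 0.95) {
  unit <- match.arg(unit)
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both classes required in the original sample")
  if (unit == "patient" && is.null(patient_id))
    stop("patient_id required for patient-level resampling")
  n <- length(scores)
  with_seed(seed, {
    vals <- numeric(n_boot)
    attempts <- 0L
    for (i in seq_len(n_boot)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 2L * n_boot)
          stop("metric undefined on more than half of bootstrap resamples")
        if (unit == "breast") {
          idx <- sample.int(n, n, replace = TRUE)
        } else {
          pats <- unique(patient_id)
          pick <- sample(pats, length(pats), replace = TRUE)
          idx <- unlist(lapply(pick, function(p) which(patient_id == p)),
                        use.names = FALSE)
        }
        v <- metric_fn(scores[idx], labels[idx])
        if (!is.na(v)) break
      }
      vals[i] <- v
    }
    alpha <- (1 - conf) / 2
    ci <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
    c(lo = ci[1], hi = ci[2])
  })
}

#' Prevalence arithmetic for a label set
#'
#' @param labels 0/1 or logical labels (or counts via `n_pos`/`n_total`).
#' @param n_pos,n_total alternative count interface.
#' @return List with `n_pos`, `n_total`, `fraction`, and `percent` (the
#'   fraction in percent at 3 significant digits, the reporting convention
#'   used throughout the package).
#' @examples
#' prevalence_summary(n_pos = 221, n_total = 11934)$percent  # 1.85
#' @export
prevalence_summary <- function(labels = NULL, n_pos = NULL, n_total = NULL) {
  if (!is.null(labels)) {
    n_pos <- sum(as.logical(labels))
    n_total <- length(labels)
  }
  stopifnot(n_total > 0, n_pos >= 0, n_pos <= n_total)
  frac <- n_pos / n_total
  list(n_pos = n_pos, n_total = n_total, fraction = frac,
       percent = signif(100 * frac, 3))
}
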