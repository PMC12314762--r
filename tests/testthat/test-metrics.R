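test_that("roc_auc matches pair counting and pROC on random data", {
  # 6-point hand case
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.05)
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_auc(sc, y), auc_pairs(sc, y))

  set.seed(1)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # plenty of ties
    yy <- rbinom(30, 1, 0.4)
    if (sum(yy) %in% c(0, 30)) next
    expect_equal(roc_auc(s, yy), auc_pairs(s, yy))
    expect_equal(roc_auc(s, yy),
                 as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                                direction = "<"))))
  }
  expect_true(is.na(roc_auc(1:4, c(1, 1, 1, 1))))
})

test_that("auc and aupr are perfect for separating scores and invariant to monotone maps", {
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1)
  expect_equal(roc_auc(sc, y), 1.0)
  expect_equal(aupr(sc, y), 1.0)
  set.seed(2)
  s <- rnorm(40); yy <- rbinom(40, 1, 0.3)
  expect_equal(roc_auc(plogis(2 * s), yy), roc_auc(s, yy))
})

test_that("aupr equals the hand-computed average precision on a small case", {
  # scores desc: 0.9(1), 0.8(0), 0.7(1), 0.6(1), 0.5(0)
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  y <- c(1, 0, 1, 1, 0)
  # AP = 1/3*(1/1) + 1/3*(2/3) + 1/3*(3/4)
  expect_equal(aupr(sc, y), (1 + 2 / 3 + 3 / 4) / 3, tolerance = 1e-12)
  # tie grouping: both tied scores enter at once
  expect_equal(aupr(c(1, 1), c(1, 0)), 0.5)
})

test_that("mean aupr of random scores equals the class prevalence", {
  rb <- random_baseline(n_pos = 400, n_total = 2000, n_rep = 200, seed = 5)
  expect_lt(abs(rb$mean_aupr - 0.2), 0.01)
  expect_lt(abs(rb$mean_auc - 0.5), 0.01)
})

test_that("the youden point maximizes J and matches an exhaustive scan", {
  op <- youden_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$ppv, 1)

  # all scores equal: degenerate; the tie rule prefers the all-negative call
  op2 <- youden_point(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(op2$sensitivity + op2$specificity - 1, 0)
  expect_equal(op2$specificity, 1)
  expect_equal(op2$sensitivity, 0)

  set.seed(3)
  for (rep in 1:5) {
    s <- round(runif(20), 2)
    y <- rbinom(20, 1, 0.5)
    if (sum(y) %in% c(0, 20)) next
    op <- youden_point(s, y)
    # exhaustive oracle over every candidate threshold
    js <- vapply(c(sort(unique(s)), max(s) + 1), function(t) {
      sens <- mean(s[y == 1] >= t); spec <- mean(s[y == 0] < t)
      sens + spec - 1
    }, numeric(1))
    expect_equal(op$sensitivity + op$specificity - 1, max(js),
                 tolerance = 1e-12)
    # counts recompute the reported rates exactly
    ct <- op$counts
    expect_equal(op$sensitivity, ct["TP"] / (ct["TP"] + ct["FN"]),
                 ignore_attr = TRUE)
    expect_equal(op$specificity, ct["TN"] / (ct["TN"] + ct["FP"]),
                 ignore_attr = TRUE)
  }
})

test_that("fixed-sensitivity operating points meet the constraint tightly", {
  # separable
  op <- fixed_sensitivity_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.95)
  expect_equal(op$specificity, 1)

  # forcing all three positives to be captured drives the threshold to 0.1
  op2 <- fixed_sensitivity_point(c(0.9, 0.8, 0.1, 0.5), c(1, 1, 1, 0), 0.97)
  expect_equal(op2$threshold, 0.1)
  expect_equal(op2$specificity, 0)
  expect_equal(op2$sensitivity, 1)

  # monotonicity: a lower target can only raise (or keep) specificity
  set.seed(4)
  for (rep in 1:10) {
    s <- runif(40); y <- rbinom(40, 1, 0.3)
    if (sum(y) %in% c(0, 40)) next
    s95 <- fixed_sensitivity_point(s, y, 0.95)$specificity
    s97 <- fixed_sensitivity_point(s, y, 0.97)$specificity
    expect_gte(s95, s97)
  }
})

test_that("wilcoxon signed-rank handles exact, tie and zero cases", {
  expect_equal(wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6)), 1.0)
  # n = 6, all differences positive: exact two-sided p = 2 / 2^6
  expect_equal(wilcoxon_compare(c(2, 3, 4, 5, 6, 7) + 0.1 * (1:6),
                                c(1, 2, 3, 4, 5, 6)), 2 / 64)
  a <- c(1.2, 0.8, 2.5, 3.1, 0.3, 1.9, 2.2)
  b <- c(0.9, 1.1, 2.0, 2.8, 0.6, 1.5, 2.6)
  expect_equal(wilcoxon_compare(a, b), wilcoxon_compare(b, a))
  expect_error(wilcoxon_compare(1:3, 2:4), "length")
})

test_that("bootstrap intervals are deterministic, degenerate-safe and calibrated", {
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  y <- c(0, 0, 0, 1, 1, 1)
  ci <- bootstrap_ci(sc, y, roc_auc, n_boot = 100, seed = 3)
  expect_equal(unname(ci), c(1, 1))  # separable: zero-width at 1
  ci2 <- bootstrap_ci(sc, y, roc_auc, n_boot = 100, seed = 3)
  expect_identical(ci, ci2)

  # patient-level resampling keeps patients intact
  pid <- c("a", "a", "b", "b", "c", "c")
  ci3 <- bootstrap_ci(sc, y, roc_auc, n_boot = 50, seed = 4,
                      unit = "patient", patient_id = pid)
  expect_true(ci3["lo"] <= ci3["hi"])

  # coverage of the percentile interval for AUC under a known model
  set.seed(11)
  n <- 60; true_auc <- pnorm(1 / sqrt(2))  # binormal, d' = 1
  cover <- 0; nsim <- 200
  for (i in 1:nsim) {
    yy <- rbinom(n, 1, 0.5)
    ss <- rnorm(n, mean = yy)
    ci <- bootstrap_ci(ss, yy, roc_auc, n_boot = 200, seed = i)
    cover <- cover + (true_auc >= ci["lo"] && true_auc <= ci["hi"])
  }
  expect_gt(cover / nsim, 0.87)
  expect_lte(cover / nsim, 0.99)
})

test_that("prevalence arithmetic reproduces printed screening rates", {
  expect_equal(prevalence_summary(n_pos = 221, n_total = 11934)$percent, 1.85)
  expect_equal(prevalence_summary(n_pos = 81, n_total = 342)$percent, 23.7)
  expect_equal(prevalence_summary(c(1, 1, 0, 0, 0))$fraction, 0.4)
})
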