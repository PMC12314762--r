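make_manifest <- function(n_pat = 10, imgs_per_pat = 2, seed = 1) {
  set.seed(seed)
  n <- n_pat * imgs_per_pat
  data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n_pat)), each = imgs_per_pat),
    exam_id = rep(sprintf("P%02d-E01", seq_len(n_pat)), each = imgs_per_pat),
    laterality = rep(c("left", "right"), n_pat),
    label = rbinom(n, 1, 0.3),
    known_cancer = rep(FALSE, n),
    bpe = sample(c("minimal", "mild"), n, replace = TRUE),
    lesion_type = "none", stage_proxy = "none",
    image_path = NA_character_, mask_path = NA_character_,
    stringsAsFactors = FALSE)
}

test_that("grouped folds partition patients exactly and disjointly", {
  m <- make_manifest(10)
  folds <- grouped_kfold(m, k = 5, seed = 2)
  test_pats <- lapply(folds, function(f) unique(m$patient_id[f$test_idx]))
  expect_true(all(lengths(test_pats) == 2))
  expect_equal(sort(unlist(test_pats)), sort(unique(m$patient_id)))
  for (f in folds) {
    expect_length(intersect(m$patient_id[f$train_idx],
                            m$patient_id[f$test_idx]), 0)
  }
  expect_error(grouped_kfold(m, k = 11), "more folds than patients")
})

test_that("imbalanced folds exclude known cancers from test but keep them in training", {
  m <- make_manifest(12, seed = 3)
  kc_exams <- unique(m$exam_id[m$label == 1])[1:2]
  m$known_cancer <- m$exam_id %in% kc_exams
  folds <- grouped_kfold(m, k = 4, seed = 7, task = "imbalanced")
  kc_rows <- which(m$known_cancer)
  for (f in folds) {
    expect_length(intersect(f$test_idx, kc_rows), 0)
    # held-out patients = everyone not on the training side (a patient whose
    # images are all known-cancer can vanish from the filtered test set)
    own_pats <- setdiff(unique(m$patient_id),
                        unique(m$patient_id[f$train_idx]))
    other_kc <- kc_rows[!m$patient_id[kc_rows] %in% own_pats]
    expect_true(all(other_kc %in% f$train_idx))
  }
  # every known-cancer image appears in the training side of the folds that
  # do not hold its patient out
  appearances <- vapply(kc_rows, function(r)
    sum(vapply(folds, function(f) r %in% f$train_idx, logical(1))),
    numeric(1))
  expect_true(all(appearances == 3))  # k - 1 folds
})

test_that("cell metrics and report aggregate over fold-seed cells", {
  set.seed(5)
  cells <- expand.grid(fold = 1:3, seed = 1:2)
  scores <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- 40
    y <- rbinom(n, 1, 0.3)
    do.call(rbind, lapply(c("fcdd", "bce"), function(mod) {
      sep <- if (mod == "fcdd") 1.5 else 0.7
      data.frame(image_id = sprintf("i%03d", 1:n),
                 score = rnorm(n, mean = sep * y),
                 label = y, fold = cells$fold[i], seed = cells$seed[i],
                 model = mod, task = "balanced",
                 stringsAsFactors = FALSE)
    }))
  }))
  cm <- cell_metrics(scores)
  expect_equal(nrow(cm), 12)  # 2 models x 3 folds x 2 seeds
  rep <- metrics_report(cm)
  expect_equal(rep$summary$n_cells, c(6, 6))
  expect_equal(rep$baselines$baseline_auc, 0.5)
  # baseline AUPR is the mean realised prevalence
  expect_equal(rep$baselines$baseline_aupr, mean(cm$prevalence))
  # the stronger model wins AUC in the paired comparison
  cmp <- rep$comparisons
  row <- cmp[cmp$metric == "auc", ]
  expect_equal(nrow(row), 1)
  better <- if (row$mean_a > row$mean_b) row$model_a else row$model_b
  expect_equal(better, "fcdd")
  md <- report_markdown(rep)
  expect_true(any(grepl("^\\| balanced \\| fcdd", md)))
})

test_that("stratified reports conserve counts and flag thin strata", {
  set.seed(6)
  n <- 60
  scores <- data.frame(
    image_id = sprintf("i%03d", 1:n),
    score = runif(n), label = rbinom(n, 1, 0.4),
    fold = 1, seed = 1, model = "fcdd", task = "balanced",
    bpe = sample(c("minimal", "marked"), n, replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  out <- stratified_report(scores, "bpe", min_n = 10)
  expect_equal(sum(out$n), n)  # bpe strata partition the images
  expect_true(out$flagged[out$n < 10] |> all())
  expect_error(stratified_report(scores, "nonexistent"), "unknown strata key")

  # single stratum reproduces the unstratified metric
  scores$bpe <- "minimal"
  one <- stratified_report(scores, "bpe")
  expect_equal(one$auc, roc_auc(scores$score, scores$label))
})

test_that("manifest I/O validates schema and round-trips", {
  m <- make_manifest(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(m2, m)

  m$extra <- seq_len(nrow(m))  # unknown columns preserved
  write_manifest(m, path)
  expect_equal(read_manifest(path)$extra, m$extra)

  bad <- m; bad$label[3] <- 2
  expect_error(validate_manifest(bad), "row 3")
  bad2 <- m; bad2$laterality[2] <- "up"
  expect_error(validate_manifest(bad2), "row 2")
  expect_error(validate_manifest(m[0, ]), "empty")
  expect_error(validate_manifest(m[, -1]), "patient_id")
  expect_error(read_manifest(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("contralateral indexing pairs exam sides", {
  m <- make_manifest(3)
  ci <- contralateral_index(m)
  expect_equal(m$exam_id[ci], m$exam_id)
  expect_true(all(m$laterality[ci] != m$laterality))
})

test_that("seed streams are deterministic, label-sensitive and in range", {
  expect_identical(seed_stream(7, "train", 2), seed_stream(7, "train", 2))
  expect_false(seed_stream(7, "train", 2) == seed_stream(7, "train", 3))
  expect_false(seed_stream(7, "a") == seed_stream(8, "a"))
  s <- vapply(1:50, function(i) seed_stream(i, "x"), integer(1))
  expect_true(all(s >= 1 & s < 2^31 - 1))
})

test_that("metrics report attaches bootstrap CIs when scores are supplied", {
  set.seed(8)
  n <- 50
  scores <- do.call(rbind, lapply(1:2, function(f) {
    y <- rbinom(n, 1, 0.3)
    data.frame(image_id = sprintf("f%d_%d", f, 1:n),
               score = rnorm(n, mean = 1.2 * y), label = y,
               fold = f, seed = 1, model = "fcdd", task = "balanced",
               stringsAsFactors = FALSE)
  }))
  rep <- metrics_report(cell_metrics(scores), scores = scores, n_boot = 50)
  expect_equal(nrow(rep$cis), 1)
  expect_true(rep$cis$lo <= rep$cis$hi)
  expect_true(rep$cis$hi <= 1)
})
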