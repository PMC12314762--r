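test_that("pseudo-Huber map matches its closed form", {
  phi <- array(0, c(2, 2, 3))
  expect_equal(pseudo_huber_map(phi), matrix(0, 2, 2))

  phi[1, 1, ] <- c(1, 1, 1)          # ||phi||^2 = 3 -> sqrt(4) - 1 = 1
  phi[2, 2, ] <- c(0.1, 0, 0)        # ||phi|| = 0.1
  A <- pseudo_huber_map(phi)
  expect_equal(A[1, 1], 1)
  expect_equal(A[2, 2], sqrt(1.01) - 1, tolerance = 1e-9)
  expect_true(all(A >= 0))

  set.seed(1)
  phib <- array(rnorm(4 * 3 * 5 * 2), c(4, 3, 5, 2))
  A2 <- pseudo_huber_map(phib)
  brute <- sqrt(apply(phib^2, c(1, 2, 4), sum) + 1) - 1
  expect_equal(A2, brute, tolerance = 1e-12)
})

test_that("breast score is the plain mean of the anomaly map", {
  expect_equal(breast_score(matrix(3, 4, 4)), 3)
  expect_equal(breast_score(matrix(c(0, 0, 0, 4), 2, 2)), 1)
  set.seed(2)
  A <- matrix(abs(rnorm(35)), 5, 7)
  expect_equal(breast_score(A), sum(A) / 35)
  expect_error(breast_score(matrix(numeric(0), 0, 0)), "empty")
})

test_that("fcdd and hsc losses match independent closed forms", {
  expect_equal(fcdd_loss(0, 0), 0)
  expect_equal(fcdd_loss(log(2), 1), log(2), tolerance = 1e-9)
  expect_lt(fcdd_loss(50, 1), 1e-6)  # anomalous branch vanishes at high s
  # benign branch increasing, anomalous branch decreasing in s
  expect_gt(fcdd_loss(2, 0), fcdd_loss(1, 0))
  expect_lt(fcdd_loss(2, 1), fcdd_loss(1, 1))
  # finite at the guarded s = 0 singularity
  expect_true(is.finite(fcdd_loss(0, 1)))

  z0 <- matrix(0, 4, 1)
  expect_equal(hsc_loss(z0, 0), 0)
  z <- matrix(c(1, 1, 1, 0), 4, 1)  # ||z||^2 = 3 -> h = 1
  expect_equal(hsc_loss(z, 1), -log(1 - exp(-1)), tolerance = 1e-9)

  # agreement with an independent implementation on random batches
  set.seed(3)
  for (rep in 1:5) {
    s <- abs(rnorm(8)); y <- rbinom(8, 1, 0.4)
    ref <- mean(ifelse(y == 0, s, -log(1 - pmin(exp(-s), 1 - 1e-6))))
    expect_equal(fcdd_loss(s, y), ref, tolerance = 1e-6)
    zz <- matrix(rnorm(3 * 8), 3, 8)
    h <- sqrt(colSums(zz^2) + 1) - 1
    refh <- mean(ifelse(y == 0, h, -log(1 - pmin(exp(-h), 1 - 1e-6))))
    expect_equal(hsc_loss(zz, y), refh, tolerance = 1e-6)
  }
})

test_that("hsc loss decreases as an anomalous embedding grows", {
  h_of <- function(a) hsc_loss(matrix(c(a, 0), 2, 1), 1)
  expect_lt((h_of(2 + 1e-5) - h_of(2 - 1e-5)) / 2e-5, 0)
})

test_that("bce loss matches the textbook form and saturates", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(20, 1), 1e-8)
  expect_lt(bce_loss(-20, 0), 1e-8)
  set.seed(4)
  l <- rnorm(10, sd = 3); y <- rbinom(10, 1, 0.5)
  ref <- -mean(y * log(plogis(l)) + (1 - y) * log(1 - plogis(l)))
  expect_equal(bce_loss(l, y), ref, tolerance = 1e-9)
})

test_that("symmetric anomaly map reduces correctly in its limit cases", {
  set.seed(5)
  phi <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_equal(symmetric_anomaly_map(phi, phi), matrix(0, 4, 4))
  zero <- array(0, dim(phi))
  expect_equal(symmetric_anomaly_map(phi, zero), pseudo_huber_map(phi))
  phic <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  brute <- sqrt(apply((phi - phic)^2, c(1, 2), sum) + 1) - 1
  expect_equal(symmetric_anomaly_map(phi, phic), brute, tolerance = 1e-12)
  expect_error(symmetric_anomaly_map(phi, array(0, c(4, 4, 5))), "shapes")
})

test_that("training is deterministic given identical seed, config and data", {
  co <- tiny_cohort()
  idx <- 1:20
  bb <- backbone_config(channels = c(3, 6), strides = c(2, 2),
                        input_size = c(64, 64))
  tc <- train_config(epochs = 3, lr = 0.02, batch_size = 8)
  d1 <- train_detector(co$images[, , idx], co$manifest$label[idx], "fcdd",
                       backbone = bb, config = tc, seed = 5)
  d2 <- train_detector(co$images[, , idx], co$manifest$label[idx], "fcdd",
                       backbone = bb, config = tc, seed = 5)
  expect_identical(d1$net$layers, d2$net$layers)
  expect_identical(d1$loss_log, d2$loss_log)
})

test_that("benign-only FCDD training ranks held-out malignancies higher on average", {
  # One-class mode: no labelled anomalies.  The init-mean centre removes
  # the trivial zero-weight minimiser (see ?train_detector), and with a
  # few hundred benign training images the mean anomaly score of unseen
  # malignant breasts exceeds the benign mean.  The margin is modest —
  # small lesions barely move a mean-pooled score without the anomalous
  # loss branch — so this asserts the ordering, not a detection level.
  cfg <- phantom_config(n_patients = 80, image_height = 64, image_width = 64,
                        seed = 301)
  co <- generate_cohort(cfg)
  m <- co$manifest
  ben <- which(m$label == 0)
  train_ben <- ben[1:200]
  held <- setdiff(seq_len(nrow(m)), train_ben)
  bb <- backbone_config(channels = c(8, 16, 32, 64), input_size = c(64, 64))
  tc <- train_config(epochs = 40, lr = 0.02, batch_size = 16)
  det <- train_detector(co$images[, , train_ben], m$label[train_ben], "fcdd",
                        backbone = bb, config = tc, center = "init-mean",
                        standardize = FALSE, seed = 13)
  sc <- detector_scores(det, co$images[, , held])
  expect_gt(mean(sc[m$label[held] == 1]), mean(sc[m$label[held] == 0]))
  # and the centre did its job: no collapse to the zero feature map
  expect_gt(mean(sc), 1e-4)
})

test_that("training loss decreases on average over epochs", {
  det <- tiny_fcdd()
  ll <- det$loss_log
  k <- 5
  ma <- stats::filter(ll, rep(1 / k, k), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
  # nearly monotone in the moving average: no sustained increase
  expect_lt(sum(diff(ma) > 0) / length(ma), 0.35)
})

test_that("anomaly maps and scores are nonnegative for the anomaly objectives", {
  co <- tiny_cohort()
  det <- tiny_fcdd()
  A <- anomaly_map(det, co$images[, , 1:8])
  expect_true(all(A >= 0))
  expect_true(all(detector_scores(det, co$images[, , 1:8]) >= 0))
})

test_that("a translated lesion moves the anomaly-map argmax accordingly", {
  det <- tiny_fcdd()
  s <- det$backbone$stride
  base <- matrix(0.1, 64, 64)
  put_lesion <- function(r0, c0) {
    img <- base
    img[r0 + (-2:2), c0 + (-2:2)] <- 0.9
    img
  }
  k <- 3  # shift in grid cells
  a1 <- anomaly_map(det, put_lesion(24, 24))
  a2 <- anomaly_map(det, put_lesion(24 + k * s, 24))
  p1 <- which(a1 == max(a1), arr.ind = TRUE)[1, ]
  p2 <- which(a2 == max(a2), arr.ind = TRUE)[1, ]
  expect_lte(abs((p2["row"] - p1["row"]) - k), 1)
  expect_lte(abs(p2["col"] - p1["col"]), 1)
})

test_that("degenerate training inputs are rejected with clear errors", {
  co <- tiny_cohort()
  expect_error(train_detector(co$images[, , 1:4], rep(1, 4), "fcdd"),
               "benign")
  expect_error(train_detector(co$images[, , 1:4], c(0, 1, 0, 2), "fcdd"),
               "0/1")
  expect_error(train_detector(co$images[, , 1:4], c(0, 1, 0, 1), "fcdd-sym"),
               "contralateral")
})
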