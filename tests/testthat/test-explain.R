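test_that("delta input produces a unit-mass Gaussian bump at the cell centre", {
  A <- matrix(0, 8, 8)
  A[4, 5] <- 1
  em <- upsample_heatmap(A, r = 9, s = 4, out_size = c(32, 32))
  expect_s3_class(em, "explanation_map")
  out <- em$pixels
  expect_equal(sum(out), 1, tolerance = 1e-9)  # interior: mass conserved
  pk <- which(out == max(out), arr.ind = TRUE)[1, ]
  # receptive-field centre of cell (4, 5) at stride 4
  expect_equal(unname(pk["row"]), floor(3.5 * 4) + 1)
  expect_equal(unname(pk["col"]), floor(4.5 * 4) + 1)
  expect_true(all(out >= 0))
})

test_that("upsampling is linear and zero-preserving", {
  expect_true(all(upsample_heatmap(matrix(0, 4, 4), 5, 2)$pixels == 0))
  set.seed(1)
  # interior-supported maps (border cells zero) conserve mass exactly
  A1 <- matrix(0, 8, 8); A1[3:6, 3:6] <- abs(rnorm(16))
  A2 <- matrix(0, 8, 8); A2[3:6, 3:6] <- abs(rnorm(16))
  u1 <- upsample_heatmap(A1, 9, 4)$pixels
  u2 <- upsample_heatmap(A2, 9, 4)$pixels
  u12 <- upsample_heatmap(A1 + A2, 9, 4)$pixels
  expect_equal(u12, u1 + u2, tolerance = 1e-12)
  expect_equal(sum(u1), sum(A1), tolerance = 1e-6)
  expect_error(upsample_heatmap(A1, r = 2, s = 4), "cover the stride")
})

test_that("grad-cam matches the analytic map for a linear single-channel target", {
  # Network: one conv layer, one channel; BCE head weight 1, bias 0.
  # Target = mean(act); d(target)/d(act) = 1/(uv) everywhere, so the CAM is
  # proportional to the activation itself.
  cfg <- backbone_config(channels = 1, kernel = 3, strides = 1,
                         input_size = c(12, 12))
  net <- backbone_init(cfg, seed = 3)
  det <- structure(list(net = net, head = list(w = 1, b = 0),
                        objective = "bce", backbone = cfg,
                        standardize = FALSE),
                   class = "mip_detector")
  set.seed(4)
  img <- matrix(runif(144), 12, 12)
  act <- backbone_forward(net, img)$phi[, , 1, 1]
  em <- gradcam(det, img)
  expect_equal(em$pixels, pmax(act, 0) / prod(cfg$grid), tolerance = 1e-9)
})

test_that("grad-cam of a bias-free network on zero input is the zero map", {
  cfg <- backbone_config(channels = c(4, 8), strides = c(1, 2),
                         input_size = c(16, 16))
  net <- backbone_init(cfg, seed = 5)
  for (l in 1:2) net$layers[[l]]$b[] <- 0
  det <- structure(list(net = net,
                        head = list(w = rnorm(8), b = 0),
                        objective = "bce", backbone = cfg,
                        standardize = FALSE),
                   class = "mip_detector")
  em <- gradcam(det, matrix(0, 16, 16))
  expect_true(all(em$pixels == 0))
})

test_that("grad-cam is invariant to constant shifts of the target", {
  cfg <- backbone_config(channels = c(4, 8), strides = c(1, 2),
                         input_size = c(16, 16))
  net <- backbone_init(cfg, seed = 6)
  set.seed(6)
  img <- matrix(runif(256), 16, 16)
  w <- rnorm(8)
  d1 <- structure(list(net = net, head = list(w = w, b = 0),
                       objective = "bce", backbone = cfg,
                       standardize = FALSE), class = "mip_detector")
  d2 <- structure(list(net = net, head = list(w = w, b = 42),
                       objective = "bce", backbone = cfg,
                       standardize = FALSE), class = "mip_detector")
  expect_equal(gradcam(d1, img)$pixels, gradcam(d2, img)$pixels,
               tolerance = 1e-12)
})

test_that("map normalization follows the local and global conventions", {
  m1 <- matrix(seq(0, 1, length.out = 16), 4, 4)
  m2 <- matrix(seq(0, 10, length.out = 16), 4, 4)

  one <- normalize_maps(list(m1), "local")[[1]]
  oneg <- normalize_maps(list(m1), "global")[[1]]
  expect_equal(one$pixels, oneg$pixels)

  glob <- normalize_maps(list(m1, m2), "global")
  expect_equal(max(glob[[1]]$pixels), 0.1, tolerance = 1e-12)
  expect_equal(max(glob[[2]]$pixels), 1)

  loc <- normalize_maps(list(m1, m2, matrix(5, 2, 2)), "local")
  expect_equal(range(loc[[1]]$pixels), c(0, 1))
  expect_equal(range(loc[[2]]$pixels), c(0, 1))
  expect_true(all(loc[[3]]$pixels == 0))  # constant map -> zeros
  expect_error(normalize_maps(list(), "local"), "empty")
})

test_that("pixelwise AUC agrees with brute-force pair counting", {
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(pixelwise_auc(mask, mask), 1.0)
  expect_equal(pixelwise_auc(matrix(0.5, 2, 2), mask), 0.5)
  expect_equal(pixelwise_auc(1 - mask, mask), 0.0)
  expect_true(is.na(pixelwise_auc(matrix(1, 2, 2), matrix(0, 2, 2))))

  set.seed(7)
  for (rep in 1:10) {
    mp <- matrix(sample(seq(0, 1, 0.25), 25, replace = TRUE), 5, 5)
    mk <- matrix(rbinom(25, 1, 0.3), 5, 5)
    if (sum(mk) == 0 || sum(mk) == 25) next
    expect_equal(pixelwise_auc(mp, mk),
                 auc_pairs(as.vector(mp), as.vector(mk)))
  }
})

test_that("pixelwise AUC is invariant under monotone transforms and local normalization", {
  set.seed(8)
  mp <- matrix(runif(64), 8, 8)
  mk <- matrix(rbinom(64, 1, 0.2), 8, 8)
  a0 <- pixelwise_auc(mp, mk)
  expect_equal(pixelwise_auc(exp(3 * mp), mk), a0)
  loc <- normalize_maps(list(mp), "local")[[1]]
  expect_equal(pixelwise_auc(loc, mk), a0)
})

test_that("fcdd explanations beat a shuffled-map null on phantom lesions", {
  co <- tiny_cohort()
  det <- tiny_fcdd()
  mal <- which(co$manifest$label == 1)
  ex <- explain_scores(det, co, idx = mal)
  real <- ex$pixelwise_auc
  # null: same maps scored against the truth masks of *other* lesions
  r <- det$backbone$receptive_field; s <- det$backbone$stride
  set.seed(9)
  perm <- sample(length(mal))
  while (any(perm == seq_along(mal))) perm <- sample(length(mal))
  null <- vapply(seq_along(mal), function(i) {
    A <- anomaly_map(det, co$images[, , mal[i]])
    em <- upsample_heatmap(A, r, s, out_size = c(64, 64))
    pixelwise_auc(em, co$masks[, , mal[perm[i]]])
  }, numeric(1))
  expect_gt(mean(real), mean(null))
  expect_lt(wilcox.test(real, null, paired = TRUE,
                        alternative = "greater")$p.value, 0.01)
})

test_that("heat-map PNG writer produces gray maps and contour overlays", {
  dir <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 64), 8, 8)
  p1 <- file.path(dir, "map.png")
  write_heatmap_png(m, p1)
  expect_equal(dim(png::readPNG(p1)), c(8, 8))
  mk <- matrix(0, 8, 8); mk[3:5, 3:5] <- 1
  p2 <- file.path(dir, "overlay.png")
  write_heatmap_png(m, p2, image = m * 0 + 0.5, truth_mask = mk)
  ov <- png::readPNG(p2)
  expect_equal(dim(ov), c(8, 8, 3))
  expect_equal(ov[3, 3, 2], 1)  # mask boundary drawn in green
  expect_lt(ov[4, 4, 2], 1)     # interior is not boundary
})
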