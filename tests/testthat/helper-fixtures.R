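# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# Small 64x64 phantom cohort used by several module tests.
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- phantom_config(n_patients = 25, image_height = 64,
                          image_width = 64, seed = 101)
    .fixtures$tiny <- generate_cohort(cfg)
  }
  .fixtures$tiny
}

# A small FCDD detector trained on the tiny cohort (shared by detector and
# explainability tests so the suite trains it only once).
tiny_fcdd <- function() {
  if (is.null(.fixtures$fcdd)) {
    co <- tiny_cohort()
    bb <- backbone_config(channels = c(4, 8, 16, 32), input_size = c(64, 64))
    tc <- train_config(epochs = 40, lr = 0.04, batch_size = 16)
    .fixtures$fcdd <- train_detector(co$images, co$manifest$label, "fcdd",
                                     backbone = bb, config = tc, seed = 7)
  }
  .fixtures$fcdd
}

# Brute-force pair-counting AUC oracle (ties count one half).
auc_pairs <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
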