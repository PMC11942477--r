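# Small configurations used throughout: L = 16 with a patch-4, two-stage
# vision encoder keeps every forward pass fast while exercising the same
# code paths as the full-size model.

tiny_cfg <- function(...) {
  toy_model_config(L = 16L, d_model = 16L, heads = 2L, n_seq_layers = 1L,
                   depths = c(1L, 2L), patch_size = 4L, dropout = 0, ...)
}

tiny_seq <- "ACGUACGUACGUACGU"

test_that("config validation enforces the shape contracts", {
  expect_error(model_config(L = 100), "divisible by 16")
  expect_error(model_config(L = 112, d_model = 66, heads = 12), "divisible")
  cfg <- model_config(L = 112, d_model = 64, heads = 8,
                      depths = c(2, 2, 6, 2), patch_size = 2)
  expect_equal(cfg$Lv, 7L)           # L / 16
  expect_equal(cfg$Lt, 112L)         # L - k + 3 at k = 3
  expect_equal(cfg$G, c(56L, 28L, 14L, 7L))
  expect_equal(cfg$C, c(8L, 16L, 32L, 64L))
})

test_that("sequence encoder yields Lt x D position-sensitive embeddings", {
  m <- duet_model(tiny_cfg(), "classify", seed = 2)
  Tl <- sequence_encode(m, tiny_seq)
  expect_equal(dim(Tl), c(16L, 16L))  # Lt = 16 - 3 + 3
  expect_true(all(is.finite(Tl)))
  # deterministic forward
  expect_identical(Tl, sequence_encode(m, tiny_seq))
  # swapping two interior bases changes the embedding (positions are live)
  Tl2 <- sequence_encode(m, "ACGUACGAUCGUACGU")
  expect_false(isTRUE(all.equal(Tl, Tl2)))
})

test_that("vision encoder downsamples to Lv tokens and is deterministic", {
  m <- duet_model(tiny_cfg(), "classify", seed = 2)
  st <- build_feature_stack(tiny_seq)
  Vl <- vision_encode(m, st)
  expect_equal(dim(Vl), c(2L, 16L))   # G_S = 16 / (4 * 2)
  expect_identical(Vl, vision_encode(m, st))
  # an all-zero stack still produces finite outputs
  zero <- array(0, c(16, 16, 24))
  expect_true(all(is.finite(vision_encode(m, zero))))
})

test_that("window attention rows are normalized in both encoders", {
  m <- duet_model(tiny_cfg(), "classify", seed = 3)
  va <- vision_encode(m, build_feature_stack(tiny_seq), return_attention = TRUE)
  expect_gt(length(va$attention), 0)
  for (A in va$attention) {
    sums <- apply(A, 3, rowSums)
    expect_true(max(abs(sums - 1)) < 1e-8)
  }
  sa <- sequence_encode(m, tiny_seq, return_attention = TRUE)
  for (A in sa$attention) expect_true(max(abs(apply(A, 3, rowSums) - 1)) < 1e-8)
})

test_that("fusion preserves shapes and normalizes rows before activation", {
  m <- duet_model(tiny_cfg(), "classify", seed = 4)
  Tl <- sequence_encode(m, tiny_seq)
  Vl <- vision_encode(m, build_feature_stack(tiny_seq))
  fu <- fuse_embeddings(m, Tl, Vl)
  expect_equal(dim(fu$Tl), dim(Tl))
  expect_equal(dim(fu$Vl), dim(Vl))
  # fused rows are SeLU(layer-normalized(x)): recover x = SeLU^-1(y) and
  # check zero row mean (the layer-norm contract, beta = 0 at init)
  inv_selu <- function(y) ifelse(y > 0, y / 1.0507009873554805,
                                 log(y / (1.0507009873554805 * 1.6732632423543772) + 1))
  pre <- inv_selu(fu$Tl)
  expect_lt(max(abs(rowMeans(pre))), 1e-5)
  expect_equal(model_config()$fusion_layers, 2L)
})

test_that("classification head pools C = Lt + Lv positions onto a simplex", {
  m <- duet_model(tiny_cfg(), "classify", n_classes = 13, seed = 5)
  Tl <- sequence_encode(m, tiny_seq)
  Vl <- vision_encode(m, build_feature_stack(tiny_seq))
  fu <- fuse_embeddings(m, Tl, Vl)
  p <- classify_head(m, fu$Tl, fu$Vl)
  expect_length(p, 13)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  expect_equal(attr(p, "pooled_positions"), 16L + 2L)
  expect_error(duet_model(tiny_cfg(), "classify", n_classes = 1), "n_classes")
})

test_that("structure head returns a symmetric probability matrix", {
  m <- duet_model(tiny_cfg(), "rss", seed = 6)
  st <- build_feature_stack(tiny_seq)
  pm <- rss_head(m, st, tiny_seq)
  expect_equal(dim(pm), c(16L, 16L))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(pm, t(pm), tolerance = 1e-12)
  expect_identical(pm, rss_head(m, st, tiny_seq))
})

test_that("skip connections are live wiring in the structure head", {
  m <- duet_model(tiny_cfg(), "rss", seed = 6)
  st <- build_feature_stack(tiny_seq)
  base <- rss_head(m, st, tiny_seq)
  # zero the stage-1 contribution that only flows through the skip path:
  # perturbing the first upsample weight must change the output
  m2 <- m
  m2$params$rss.up1.W <- m2$params$rss.up1.W * 0
  expect_false(isTRUE(all.equal(base, rss_head(m2, st, tiny_seq))))
})

test_that("attention primitive satisfies its degenerate identities", {
  q <- matrix(rnorm(12), 3, 4)
  kv1 <- matrix(rnorm(4), 1, 4)
  out <- attend(q, kv1, heads = 2)
  # a single key receives softmax weight 1: every query returns that row
  expect_equal(out, matrix(rep(kv1, each = 3), 3, 4), tolerance = 1e-12)
  one <- matrix(rnorm(4), 1, 4)
  expect_equal(attend(one, one, heads = 2), one, tolerance = 1e-12)
  res <- attend(q, matrix(rnorm(20), 5, 4), heads = 2, return_attention = TRUE)
  expect_true(max(abs(apply(res$attention, 3, rowSums) - 1)) < 1e-6)
  w <- attend_weights(4, seed = 1)
  out2 <- attend(q, q, heads = 2, weights = w)
  expect_equal(dim(out2), c(3L, 4L))
  expect_error(attend(q, matrix(0, 2, 6)), "feature dimension")
})

test_that("attention diagnostics recover delta and uniform limits", {
  n <- 6
  eye <- array(diag(n), c(n, n, 1))
  st <- attention_stats(eye, seq_len(n))
  expect_equal(st$mean_distance, 0)
  expect_equal(st$mean_entropy, 0)
  unif <- array(1 / n, c(n, n, 1))
  st2 <- attention_stats(unif, seq_len(n))
  expect_equal(st2$mean_entropy, log(n))
  # uniform attention over equally spaced keys: brute-force mean |offset|
  expected <- mean(abs(outer(seq_len(n), seq_len(n), "-")))
  expect_equal(st2$mean_distance, expected)
  bad <- array(runif(n * n), c(n, n, 1))
  expect_error(attention_stats(bad, seq_len(n)), "sum to 1")
})

test_that("loss closed forms hold", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-10)
  expect_equal(multiclass_ce(matrix(1 / 13, 1, 13), 5L), log(13))
  expect_equal(multiclass_ce(rbind(c(1, 0), c(0, 1)), c(1L, 2L)), 0,
               tolerance = 1e-10)
  expect_error(bce_loss(c(0.5, 0.5), 1), "shapes")
})

test_that("gradients reach every parameter group in both tasks", {
  ns <- asNamespace("rnaduet")
  for (task in c("classify", "rss")) {
    m <- duet_model(tiny_cfg(), task, seed = 8)
    seqs <- c(tiny_seq, "GGGGAAAACCCCUUUU")
    ids <- ns$prepare_ids(m, seqs)
    X0 <- ns$patch_input(featurize_sequences(seqs, L = 16), 4L)
    tape <- ns$new_tape(m)
    if (task == "classify") {
      Tn <- ns$fwd_sequence(m, tape, ids)
      Vn <- ns$fwd_vision(m, tape, X0, 2L)$vl
      fu <- ns$fwd_fusion(m, tape, Tn, Vn, 2L)
      loss <- ns$ad_ce_logits(ns$fwd_classify(m, tape, fu$T, fu$V, 2L), c(1L, 2L))
    } else {
      tgt <- rep(c(0, 1), length.out = 2 * 16 * 16)
      loss <- ns$ad_bce_logits(ns$fwd_rss(m, tape, X0, ids, 2L), tgt)
    }
    ns$ad_backward(loss)
    g <- ns$collect_grads(tape)
    expect_setequal(names(g), names(m$params))
    nonzero <- vapply(g, function(x) any(x != 0), logical(1))
    expect_true(all(nonzero),
                info = paste(task, "dead:", paste(names(g)[!nonzero], collapse = ",")))
  }
})

test_that("training reduces the loss on a tiny separable problem", {
  spec <- synth_spec(n_records = 24, L = 16, seed = 3, noise = 0,
                     motifs = c(A = "GGCC", B = "AUAU"))
  df <- motif_dataset(spec)
  m <- duet_model(tiny_cfg(dropout = 0.1), "classify", n_classes = 2, seed = 1)
  fit <- train_classifier(m, df, epochs = 5, batch_size = 8, lr = 1e-3,
                          adam_eps = 1e-4, seed = 1)
  expect_lt(min(fit$history$train_loss[4:5]), fit$history$train_loss[1])
  p <- predict_classifier(fit$model, df$seq[1])
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(colnames(p), c("A", "B"))
})

test_that("model save/load round-trips through RDS", {
  m <- duet_model(tiny_cfg(), "classify", seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$params, m$params)
  st <- build_feature_stack(tiny_seq)
  expect_identical(vision_encode(m, st), vision_encode(m2, st))
})
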