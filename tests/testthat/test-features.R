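test_that("sequence normalization maps case, T and unknowns", {
  expect_equal(unclass(rna_sequence("acgt")), "ACGU")
  expect_equal(unclass(rna_sequence("ACGX")), "ACGN")
  expect_error(rna_sequence("ACGX", strict = TRUE), "illegal")
  expect_error(rna_sequence(""), "at least one base")
})

test_that("maximum-matching map reproduces hand-derived fragments", {
  expect_true(all(lpss_matrix("AAAA") == 0))
  m <- lpss_matrix("GAAAC")
  expect_equal(m[1, 5], 1)
  expect_equal(sum(m), 2)  # every proper sub-fragment is 0
  expect_equal(lpss_matrix("GGGAAACCC")[1, 9], 3)
})

test_that("maximum-matching map is symmetric, monotone and bounded", {
  set.seed(11)
  for (rep in 1:10) {
    L <- sample(5:12, 1)
    h <- sample(0:3, 1)
    s <- random_seq(L)
    m <- lpss_matrix(s, pair_rules(min_loop = h))
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    for (i in seq_len(L - 1)) for (j in (i + 1):L) {
      expect_lte(m[i, j], floor((j - i + 1) / 2))
      if (j < L) expect_lte(m[i, j], m[i, j + 1])
      if (i > 1) expect_lte(m[i, j], m[i - 1, j])
    }
  }
})

test_that("pairing-ambiguity maps match direct counting on small cases", {
  r0 <- pair_rules(min_loop = 0)
  s <- srs_maps("AUU", r0)
  expect_equal(unname(s[1, 3, "A"]), 1)  # A pairs with U at 2 and 3
  expect_equal(unname(s[1, 3, "U"]), 0)
  expect_true(all(srs_maps("ACGU", pair_rules(min_loop = 3)) == 0))
  set.seed(21)
  for (rep in 1:5) {
    s <- random_seq(sample(4:10, 1))
    h <- sample(0:2, 1)
    rules <- pair_rules(min_loop = h)
    maps <- srs_maps(s, rules)
    expect_equal(maps[, , 5], maps[, , 1] + maps[, , 2] + maps[, , 3] + maps[, , 4])
  }
})

test_that("A-U availability maps follow the first-rule-only definition", {
  expect_true(all(bms_maps("GGCC", pair_rules(min_loop = 0)) == 0))
  b <- bms_maps("AAU", pair_rules(min_loop = 0))
  expect_equal(unname(b[1, 3, "A"]), 2)
  expect_equal(unname(b[1, 3, "U"]), 1)
  expect_equal(unname(b[1, 3, "ALL"]), 3)
  expect_true(all(bms_maps("AU", pair_rules(min_loop = 1)) == 0))
  # G-U and G-C pairs must not contribute even though globally admissible
  b2 <- bms_maps("GUAU", pair_rules(min_loop = 0))
  expect_equal(unname(b2[1, 2, "G"]), 0)
})

test_that("stacking propensity follows the decayed outward/inward sums", {
  r0 <- pair_rules(min_loop = 0)
  expect_equal(rcm_matrix("GC", r0)[1, 2], 3)
  expect_equal(rcm_matrix("GGCC", r0)[2, 3], 3 + exp(-1 / 2) * 3)
  # outward stops at first inadmissible offset
  expect_equal(rcm_matrix("AGCA", r0)[2, 3], 3)
  # inadmissible cells are zero
  expect_equal(rcm_matrix("AA", r0)[1, 2], 0)
  expect_error(rcm_matrix("GC", r0, sigma = 0), "sigma")
  m <- rcm_matrix("GGGCCC", r0, sigma = 2)
  expect_identical(m, t(m))
  expect_true(all(is.finite(m)) && all(m >= 0))
})

test_that("distance maps encode positions and one-hot bases", {
  expect_equal(spatial_distance("AA")[1, 2], 1)
  expect_equal(spatial_distance("AC")[1, 2], sqrt(3))
  expect_equal(unname(diag(spatial_distance("ACGU"))), rep(0, 4))
  md <- manhattan_distance("ACGUN")
  expect_equal(md[1, 1], 0)
  expect_equal(md[1, 2], 2)
  expect_equal(md[1, 5], 1)  # base vs N (all-zero one-hot)
  expect_identical(md, t(md))
})

test_that("contact channels are the reduced Kronecker one-hot products", {
  full <- bps_tensor("ACGU", reduced = FALSE)
  expect_equal(dim(full)[3], 16)
  # one-hot partition: the 16 channels sum to 1 everywhere
  expect_true(all(apply(full, c(1, 2), sum) == 1))
  red <- bps_tensor("ACGU")
  expect_equal(dim(red)[3], 10)
  expect_equal(dim(full)[3] - dim(red)[3], 6)
  # a deleted channel is the transpose of its kept reverse
  expect_equal(full[, , "UA"], t(full[, , "AU"]))
  expect_equal(full[, , "GC"], t(full[, , "CG"]))
  bp <- bps_tensor("AU")
  expect_equal(unname(bp[1, 2, "AU"]), 1)
  expect_equal(unname(bp[2, 2, "UU"]), 1)
  expect_equal(unname(bp[1, 2, "UU"]), 0)
})

test_that("kept plus transposed deleted contact channels partition unity", {
  set.seed(5)
  s <- random_seq(9)
  red <- bps_tensor(s)
  hetero <- c("AC", "AG", "AU", "CG", "CU", "GU")
  tot <- apply(red, c(1, 2), sum)
  for (ch in hetero) tot <- tot + t(red[, , ch])
  expect_true(all(tot == 1))
})

test_that("feature stack has 24 registered channels in fixed order", {
  st <- build_feature_stack("GGGAAAUUUCCCAAAG")
  expect_s3_class(st, "feature_stack")
  expect_equal(dim(st), c(16, 16, 24))
  expect_identical(dimnames(st)[[3]], feature_registry())
  expect_length(feature_registry(), 24)
  # single-letter sequence degenerates every pairing channel
  st0 <- build_feature_stack("AAAA", normalize = FALSE)
  for (ch in c("LPSS", "RCM", "SRS_ALL", "BMS_ALL", "MANHATTAN"))
    expect_true(all(st0[, , ch] == 0), info = ch)
  expect_true(all(st0[, , "BPS_AA"] == 1))
})

test_that("max-normalization caps non-contact channels at 1", {
  s <- "GGGAAACCCAUAUGCGC"
  st <- build_feature_stack(s, normalize = TRUE)
  for (ch in 1:14) {
    mx <- max(st[, , ch])
    expect_true(isTRUE(all.equal(mx, 1)) || mx == 0)
  }
  raw <- build_feature_stack(s, normalize = FALSE)
  expect_gt(max(raw[, , "LPSS"]), 1)
  # contact channels never rescaled
  expect_equal(raw[, , "BPS_GG"], st[, , "BPS_GG"])
})

test_that("featurization is deterministic and finite", {
  s <- "GGGAAACCCAUAUGCGC"
  expect_identical(build_feature_stack(s), build_feature_stack(s))
  st <- build_feature_stack(s)
  expect_true(all(is.finite(st)))
  expect_true(all(st[, , -(13:14)] >= 0))
})

test_that("fixed-length featurization pads with zeroed rows and columns", {
  out <- featurize_sequences(c(a = "GGGAAACCC"), L = 16)
  st <- out[[1]]
  expect_equal(dim(st), c(16, 16, 24))
  expect_true(all(st[10:16, , ] == 0))
  expect_true(all(st[, 10:16, ] == 0))
  # truncation keeps the head
  long <- featurize_sequences(c(a = strrep("GA", 20)), L = 16)[[1]]
  expect_equal(long[, , "BPS_AA"],
               build_feature_stack(strrep("GA", 8))[, , "BPS_AA"])
})

test_that("feature-set container round-trips", {
  seqs <- c(x = "GGGAAACCC", y = "AUAUAUAUA")
  stacks <- featurize_sequences(seqs, L = 12)
  path <- tempfile(fileext = ".rds")
  write_feature_set(stacks, names(seqs), path)
  fs <- read_feature_set(path)
  expect_equal(fs$ids, c("x", "y"))
  expect_equal(fs$registry, feature_registry())
  expect_equal(fs$features[[1]], unclass(stacks[[1]]), ignore_attr = TRUE)
  expect_equal(fs$params$min_loop, 3L)
})
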