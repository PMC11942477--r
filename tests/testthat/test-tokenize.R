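test_that("k-mer tokenization yields L - k + 3 bracketed tokens", {
  ts <- tokenize_kmers("ACGUA", k = 3)
  expect_equal(ts$tokens, c("[CLS]", "ACG", "CGU", "GUA", "[SEP]"))
  expect_equal(tokenize_kmers("A", k = 1)$tokens, c("[CLS]", "A", "[SEP]"))
  expect_equal(tokenize_kmers("ACGU", k = 4)$tokens, c("[CLS]", "ACGU", "[SEP]"))
  expect_error(tokenize_kmers("AC", k = 3), "shorter than k")
  expect_error(tokenize_kmers("AC", k = 0), "k must be")
})

test_that("token count law holds over random lengths and k", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    L <- k + sample(0:40, 1)
    s <- random_seq(L)
    expect_length(tokenize_kmers(s, k)$tokens, L - k + 3)
  }
})

test_that("vocabulary is deterministic, complete and lexicographic", {
  v1 <- build_vocab(1)
  expect_length(v1, 4 + 4)
  v3 <- build_vocab(3)
  expect_length(v3, 64 + 4)
  expect_identical(v3, build_vocab(3))
  kmers <- names(v3)[-(1:4)]
  expect_identical(kmers, sort(kmers))
  expect_equal(unname(v3[c("[PAD]", "[UNK]", "[CLS]", "[SEP]")]), 1:4)
})

test_that("encoding falls back to UNK and decoding inverts tokenization", {
  v <- build_vocab(3)
  ids <- encode_tokens(c("[CLS]", "ACG", "NNN", "[SEP]"), v)
  expect_equal(ids[3], unname(v[["[UNK]"]]))
  set.seed(7)
  for (rep in 1:10) {
    s <- random_seq(sample(4:30, 1))
    k <- sample(1:4, 1)
    expect_equal(decode_kmers(tokenize_kmers(s, k)), s)
  }
})

test_that("plain-text vocabulary round-trips with line-number ids", {
  v <- build_vocab(2)
  path <- tempfile()
  write_vocab(v, path)
  expect_equal(readLines(path)[1], "[PAD]")
  expect_identical(read_vocab(path), v)
})
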