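test_that("random structures are nested, loop-respecting and admissible", {
  rules <- pair_rules()
  for (seed in 1:8) {
    st <- random_structure(40, h = 3, seed = seed)
    pr <- matrix_to_pairs(st$pairs)
    expect_true(is_nested(st$pairs))
    if (nrow(pr) > 0) {
      expect_true(all(pr[, 2] - pr[, 1] > 3))
      bases <- strsplit(unclass(st$seq), "")[[1]]
      for (r in seq_len(nrow(pr))) {
        bp <- sort(bases[pr[r, ]])
        expect_true(any(vapply(rules$pairs, function(p)
          identical(sort(p), bp), logical(1))))
      }
      # nested ground truth: each position in at most one pair
      expect_lte(max(table(as.vector(pr))), 1)
    }
  }
  expect_error(random_structure(3, h = 3), "at least")
})

test_that("generated structures are fixed points of render-then-parse", {
  for (seed in c(2, 9, 33)) {
    st <- random_structure(60, h = 3, seed = seed)
    expect_equal(parse_dotbracket(st$dotbracket), st$pairs)
  }
})

test_that("structure generation is deterministic in the seed", {
  a <- random_structure(50, seed = 99)
  b <- random_structure(50, seed = 99)
  expect_identical(a, b)
  c <- random_structure(50, seed = 100)
  expect_false(identical(a$seq, c$seq))
})

test_that("planted-motif datasets are balanced, seeded and scannable", {
  spec <- synth_spec(n_records = 40, L = 30, seed = 5, noise = 0)
  df <- motif_dataset(spec)
  expect_equal(nrow(df), 40)
  expect_true(max(abs(diff(table(df$label)))) <= 1)
  expect_identical(df, motif_dataset(spec))
  spec2 <- synth_spec(n_records = 40, L = 30, seed = 6, noise = 0)
  expect_false(identical(df, motif_dataset(spec2)))
  # noise-free: every record contains its own motif verbatim, and a
  # motif scanner resolves all but chance occurrences of the other motif
  has <- vapply(names(spec$motifs), function(cl)
    grepl(spec$motifs[[cl]], df$seq, fixed = TRUE), logical(nrow(df)))
  expect_true(all(has[cbind(seq_len(nrow(df)), match(df$label, colnames(has)))]))
  unambiguous <- rowSums(has) == 1
  expect_gt(mean(unambiguous), 0.9)
  calls <- colnames(has)[max.col(has, ties.method = "first")]
  expect_equal(mean(calls[unambiguous] == df$label[unambiguous]), 1)
  expect_error(synth_spec(motifs = c(A = strrep("G", 40)), L = 30), "longer")
})

test_that("interaction datasets plant the motif in a hairpin stem", {
  spec <- synth_spec(n_records = 30, L = 60, seed = 4, noise = 0,
                     task = "interaction", motifs = c(site = "GGCCGG"))
  df <- interaction_dataset(spec)
  expect_equal(sum(df$label == "1"), 10)  # 1:2 positive:negative default
  pos <- df$seq[df$label == "1"]
  neg <- df$seq[df$label == "0"]
  expect_true(all(grepl("GGCCGG", pos)))
  expect_false(any(grepl("GGCCGG", neg)))
  # the reverse complement of the motif is present: the stem's other strand
  expect_true(all(grepl("CCGGCC", pos)))
  expect_identical(df, interaction_dataset(spec))
})

test_that("fixture writer emits the package's own readable formats", {
  dir <- tempfile()
  spec <- synth_spec(n_records = 10, L = 24, seed = 2)
  write_synth_dataset(spec, dir)
  seqs <- read_fasta(file.path(dir, "classification.fasta"))
  labs <- read_labels(file.path(dir, "classification.tsv"))
  expect_equal(names(seqs), labs$id)
  expect_equal(nchar(unname(seqs)), rep(24, 10))
  sdir <- tempfile()
  sspec <- synth_spec(n_records = 4, L = 30, seed = 2, task = "structure")
  write_synth_dataset(sspec, sdir)
  seqs <- read_fasta(file.path(sdir, "structure.fasta"))
  structs <- read_dotbracket_file(file.path(sdir, "structure.dbn"))
  expect_length(structs, 4)
  expect_equal(nrow(structs[[1]]), 30)
})
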