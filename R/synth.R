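#' Specification of a synthetic dataset
#'
#' Bundles the parameters of the seeded fixture generators.  The defaults
#' are the package's reference toy study conditions: 400 records of length
#' 112 with two planted 6-mer motif classes and a 5% per-base motif
#' mutation rate.
#'
#' @param n_records Number of records.
#' @param L Sequence length.
#' @param seed Integer seed; all generation is deterministic given it.
#' @param task One of `"structure"`, `"classification"`, `"interaction"`.
#' @param motifs Named character vector, class label -> motif string.
#' @param noise Per-base motif mutation probability in `[0, 1)`.
#' @param pos_fraction Positive fraction for the interaction task
#'   (default 1/3, i.e. a 1:2 positive:negative ratio).
#' @return List of class `"synth_spec"`.
#' @export
synth_spec <- function(n_records = 400L, L = 112L, seed = 1L,
                       task = c("classification", "structure", "interaction"),
                       motifs = c(A = "GGCCGG", B = "AUAUAU"),
                       noise = 0.05, pos_fraction = 1 / 3) {
  task <- match.arg(task)
  stopifnot(n_records >= 1, L >= 1, noise >= 0, noise < 1,
            pos_fraction > 0, pos_fraction < 1)
  if (any(nchar(motifs) > L)) stop("motif longer than sequence length L")
  structure(list(n_records = as.integer(n_records), L = as.integer(L),
                 seed = as.integer(seed), task = task, motifs = motifs,
                 noise = noise, pos_fraction = pos_fraction),
            class = "synth_spec")
}

#' Random nested secondary structure with a compatible sequence
#'
#' Generates a uniform-background sequence and a random valid nested
#' structure by a recursive pair-or-leave process: each position either
#' pairs with a randomly chosen admissible downstream position (with
#' probability `pair_prob`) or stays unpaired, recursing into the enclosed
#' and following fragments, so the result is nested by construction and
#' every pair respects the minimum loop.  Paired positions receive
#' complementary bases drawn from G-C, A-U and G-U with 2:2:1 weights
#' (orientations equiprobable); unpaired positions are uniform over ACGU.
#'
#' @param L Sequence length (must be at least `h + 2` for any pair to form).
#' @param h Minimum hairpin loop.
#' @param seed Integer seed.
#' @param pair_prob Probability that a position opens a pair.
#' @return List with `seq` ([rna_sequence()]), `pairs` (L x L matrix) and
#'   `dotbracket`.
#' @export
random_structure <- function(L, h = 3L, seed = 1L, pair_prob = 0.4) {
  L <- as.integer(L)
  if (L < h + 2L) stop("L must be at least h + 2 to admit any pair")
  with_seed(seed, {
    pairs <- matrix(integer(0), ncol = 2)
    recurse <- function(i, j) {
      while (i <= j) {
        if (j - i > h && runif(1) < pair_prob) {
          cand <- (i + h + 1L):j
          k <- cand[sample.int(length(cand), 1L)]
          pairs <<- rbind(pairs, c(i, k))
          recurse(i + 1L, k - 1L)
          i <- k + 1L
        } else {
          i <- i + 1L
        }
      }
    }
    recurse(1L, L)
    bases <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    pair_pool <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                      c("G", "U"), c("U", "G"))
    pool_w <- c(1, 1, 1, 1, 0.5, 0.5)  # G-C : A-U : G-U = 2 : 2 : 1
    if (nrow(pairs) > 0) {
      for (r in seq_len(nrow(pairs))) {
        bp <- pair_pool[[sample.int(6L, 1L, prob = pool_w)]]
        bases[pairs[r, 1]] <- bp[1]
        bases[pairs[r, 2]] <- bp[2]
      }
    }
    pm <- pairs_to_matrix(pairs, L)
    list(seq = rna_sequence(paste(bases, collapse = "")), pairs = pm,
         dotbracket = pairs_to_dotbracket(pm))
  })
}

#' Seeded structure dataset
#'
#' A list of `n` independent [random_structure()] draws (seeds derived from
#' the spec seed), for training and evaluating the structure head.
#'
#' @param spec A [synth_spec()] (task `"structure"`).
#' @param h Minimum hairpin loop.
#' @param pair_prob Pairing probability passed to [random_structure()].
#' @return List of `random_structure()` results.
#' @export
structure_dataset <- function(spec, h = 3L, pair_prob = 0.4) {
  lapply(seq_len(spec$n_records), function(i) {
    random_structure(spec$L, h = h, seed = spec$seed * 10000L + i,
                     pair_prob = pair_prob)
  })
}

mutate_motif <- function(motif, noise) {
  if (noise <= 0) return(motif)
  ch <- strsplit(motif, "")[[1]]
  hit <- runif(length(ch)) < noise
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

plant <- function(background, motif) {
  L <- nchar(background)
  m <- nchar(motif)
  at <- sample.int(L - m + 1L, 1L)
  paste0(substr(background, 1L, at - 1L), motif,
         substr(background, at + m, L))
}

random_bases <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

#' Planted-motif classification dataset
#'
#' Balanced multi-class records: a record of class `c` is a uniform random
#' background with `motifs[c]` planted at a random position, each motif
#' base independently mutated with probability `noise`.  Classes are
#' assigned round-robin so counts are balanced within one.
#'
#' @param spec A [synth_spec()].
#' @return Data frame with columns `id`, `seq`, `label`.
#' @export
motif_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  classes <- names(spec$motifs)
  with_seed(spec$seed, {
    label <- classes[(seq_len(spec$n_records) - 1L) %% length(classes) + 1L]
    seqs <- vapply(label, function(cl) {
      plant(random_bases(spec$L), mutate_motif(spec$motifs[[cl]], spec$noise))
    }, character(1))
    data.frame(id = sprintf("rec%04d", seq_len(spec$n_records)),
               seq = unname(seqs), label = label,
               stringsAsFactors = FALSE)
  })
}

#' Planted-motif interaction dataset
#'
#' A CLIP-style binary task.  Positives carry the (noise-mutated) motif of
#' the first spec motif embedded in the stem of a hairpin — the motif, a
#' random loop of at least `h` bases, and the reverse complement of the
#' motif — emulating a double-strand-preferring RNA-binding protein.
#' Negatives are uniform random sequences re-drawn until they do not
#' contain the exact motif.  The positive fraction defaults to 1:2.
#'
#' @param spec A [synth_spec()].
#' @param h Minimum hairpin loop.
#' @return Data frame with columns `id`, `seq`, `label` (`"1"`/`"0"`).
#' @export
interaction_dataset <- function(spec, h = 3L) {
  stopifnot(inherits(spec, "synth_spec"))
  motif <- spec$motifs[[1]]
  m <- nchar(motif)
  comp <- c(A = "U", U = "A", G = "C", C = "G", N = "N")
  n_pos <- round(spec$n_records * spec$pos_fraction)
  need <- 2L * m + h
  if (need > spec$L) stop("hairpin (2 * motif + loop) longer than L")
  with_seed(spec$seed, {
    make_pos <- function() {
      mm <- mutate_motif(motif, spec$noise)
      rc <- paste(rev(comp[strsplit(mm, "")[[1]]]), collapse = "")
      lens <- h:min(h + 4L, spec$L - 2L * m)
      loop_len <- lens[sample.int(length(lens), 1L)]
      hairpin <- paste0(mm, random_bases(loop_len), rc)
      plant(random_bases(spec$L), hairpin)
    }
    make_neg <- function() {
      repeat {
        s <- random_bases(spec$L)
        if (!grepl(motif, s, fixed = TRUE)) return(s)
      }
    }
    lab <- c(rep("1", n_pos), rep("0", spec$n_records - n_pos))
    seqs <- vapply(lab, function(l) if (l == "1") make_pos() else make_neg(),
                   character(1))
    data.frame(id = sprintf("rec%04d", seq_len(spec$n_records)),
               seq = unname(seqs), label = lab, stringsAsFactors = FALSE)
  })
}

#' Write a synthetic dataset as FASTA + TSV (+ dot-bracket)
#'
#' Emits exactly the formats the readers in this package consume: a FASTA
#' of the sequences, a 2-column label TSV for labeled tasks, and a
#' dot-bracket sidecar file for the structure task.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisible character vector of the written paths.
#' @export
write_synth_dataset <- function(spec, dir, prefix = spec$task) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  if (spec$task == "structure") {
    ds <- structure_dataset(spec)
    seqs <- setNames(vapply(ds, function(d) unclass(d$seq), character(1)),
                     sprintf("rec%04d", seq_along(ds)))
    write_fasta(seqs, fa)
    db <- file.path(dir, paste0(prefix, ".dbn"))
    write_dotbracket_file(lapply(ds, `[[`, "dotbracket"), db)
    paths <- c(fa, db)
  } else {
    df <- if (spec$task == "classification") motif_dataset(spec)
          else interaction_dataset(spec)
    write_fasta(setNames(df$seq, df$id), fa)
    tsv <- file.path(dir, paste0(prefix, ".tsv"))
    write_labels(df, tsv)
    paths <- c(fa, tsv)
  }
  invisible(paths)
}
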