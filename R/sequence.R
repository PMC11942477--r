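#' Validated RNA sequence
#'
#' Normalizes a raw base string to the `{A,C,G,U,N}` alphabet: lower case is
#' upper-cased, DNA `T` is mapped to `U` (so one alphabet serves RNA and DNA
#' input), and any other IUPAC or unknown symbol becomes `N`.  `N` never
#' pairs and carries an all-zero one-hot encoding in every feature.
#'
#' @param x Character scalar of bases.
#' @param strict If `TRUE`, characters outside `{A,C,G,U,T,N}` (after case
#'   folding) are an error instead of being mapped to `N`.
#' @return A character scalar of class `"rna_sequence"`.
#' @examples
#' rna_sequence("acgt")   # "ACGU"
#' @export
rna_sequence <- function(x, strict = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  if (nchar(s) < 1L) stop("sequence must contain at least one base")
  bad <- gsub("[ACGUN]", "", s)
  if (nchar(bad) > 0L) {
    if (strict) stop("illegal characters in sequence: ",
                     paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
    s <- gsub("[^ACGUN]", "N", s)
  }
  structure(s, class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("<rna_sequence> length", nchar(unclass(x)), "\n")
  cat(unclass(x), "\n")
  invisible(x)
}

as_rna_sequence <- function(x) {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x)
}

# Integer codes A=1, C=2, G=3, U=4, N=0; the order matches seq_onehot().
seq_codes <- function(seq) {
  s <- strsplit(unclass(as_rna_sequence(seq)), "")[[1]]
  unname(c(A = 1L, C = 2L, G = 3L, U = 4L, N = 0L)[s])
}

# L x 4 one-hot matrix in A,C,G,U column order; N rows are all zero.
seq_onehot <- function(seq) {
  codes <- seq_codes(seq)
  oh <- matrix(0, length(codes), 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  on <- codes > 0L
  oh[cbind(which(on), codes[on])] <- 1
  oh
}

#' Base-pairing rules
#'
#' The admissibility model used by every structural feature: an ordered list
#' of unordered base pairs plus a minimum hairpin loop.  Positions `i < j`
#' (0-based) may pair only when their bases form one of the listed pairs and
#' `j - i > min_loop`.  The default is the canonical Watson-Crick pairs plus
#' the G-U wobble, in the order A-U, G-C, G-U; the "first rule" (A-U) is the
#' one the BMS maps are restricted to.
#'
#' @param pairs List of length-2 character vectors of bases.
#' @param min_loop Nonnegative integer; minimum number of unpaired bases a
#'   hairpin loop must enclose (steric default 3).
#' @return An object of class `"pair_rules"`.
#' @export
pair_rules <- function(pairs = list(c("A", "U"), c("G", "C"), c("G", "U")),
                       min_loop = 3L) {
  stopifnot(is.list(pairs), length(pairs) >= 1L,
            is.numeric(min_loop), min_loop >= 0)
  pairs <- lapply(pairs, function(p) {
    p <- toupper(as.character(p))
    stopifnot(length(p) == 2L, all(p %in% c("A", "C", "G", "U")))
    p
  })
  structure(list(pairs = pairs, min_loop = as.integer(min_loop)),
            class = "pair_rules")
}

# 4x4 0/1 admissibility matrix over coded bases, optionally restricted to
# the first `n_rules` pairing rules.
rules_matrix <- function(rules, n_rules = length(rules$pairs)) {
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  m <- matrix(0L, 4L, 4L)
  for (p in rules$pairs[seq_len(n_rules)]) {
    i <- code[[p[1]]]; j <- code[[p[2]]]
    m[i, j] <- 1L; m[j, i] <- 1L
  }
  m
}

# Admissible partner positions (1-based) of position p within [lo, hi].
admissible_partners <- function(codes, rules, p, lo = 1L, hi = length(codes),
                                n_rules = length(rules$pairs)) {
  adm <- rules_matrix(rules, n_rules)
  h <- rules$min_loop
  q <- setdiff(lo:hi, p)
  q[vapply(q, function(qq) {
    abs(qq - p) > h && codes[p] > 0L && codes[qq] > 0L &&
      adm[codes[p], codes[qq]] == 1L
  }, logical(1))]
}
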