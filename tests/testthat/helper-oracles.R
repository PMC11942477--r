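# Independent brute-force oracles for the structural feature maps.  These
# deliberately avoid the package's dynamic-programming code paths: the
# maximum matching is found by exhaustive recursive enumeration of
# non-crossing pairings, and the interval counts by direct quadruple loops.

random_seq <- function(L, with_n = FALSE) {
  alpha <- c("A", "C", "G", "U", if (with_n) "N")
  paste(sample(alpha, L, replace = TRUE), collapse = "")
}

oracle_admissible <- function(bases, rules, i, j, first_only = FALSE) {
  if (abs(j - i) <= rules$min_loop) return(FALSE)
  pairs <- if (first_only) rules$pairs[1] else rules$pairs
  bp <- sort(c(bases[i], bases[j]))
  any(vapply(pairs, function(p) identical(sort(p), bp), logical(1)))
}

# maximum number of non-crossing admissible pairs in bases[i..j],
# by enumeration: position i is unpaired, or paired with each admissible k
oracle_max_matching <- function(bases, rules, i, j) {
  if (i >= j) return(0L)
  best <- oracle_max_matching(bases, rules, i + 1L, j)
  for (k in (i + 1L):j) {
    if (!oracle_admissible(bases, rules, i, k)) next
    cand <- 1L + oracle_max_matching(bases, rules, i + 1L, k - 1L) +
      (if (k < j) oracle_max_matching(bases, rules, k + 1L, j) else 0L)
    if (cand > best) best <- cand
  }
  best
}

oracle_lpss <- function(seq, rules) {
  bases <- strsplit(seq, "")[[1]]
  L <- length(bases)
  m <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i < j) m[i, j] <- oracle_max_matching(bases, rules, i, j)
  }
  m + t(m)
}

# count of positions of base `b` in [i..j] with >= threshold admissible
# partners inside [i..j]
oracle_partner_count <- function(seq, rules, threshold, first_only = FALSE) {
  bases <- strsplit(seq, "")[[1]]
  L <- length(bases)
  out <- array(0, c(L, L, 4L), dimnames = list(NULL, NULL, c("A", "U", "C", "G")))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i >= j) next
    for (ch in c("A", "U", "C", "G")) {
      cnt <- 0L
      for (p in i:j) {
        if (bases[p] != ch) next
        partners <- sum(vapply(i:j, function(q)
          q != p && oracle_admissible(bases, rules, p, q, first_only),
          logical(1)))
        if (partners >= threshold) cnt <- cnt + 1L
      }
      out[i, j, ch] <- cnt
      out[j, i, ch] <- cnt
    }
  }
  out
}

# nestedness check: no two pairs (i,j), (k,l) with i < k < j < l
is_nested <- function(pm) {
  pr <- matrix_to_pairs(pm)
  if (nrow(pr) < 2) return(TRUE)
  for (a in seq_len(nrow(pr) - 1)) for (b in (a + 1):nrow(pr)) {
    i <- pr[a, 1]; j <- pr[a, 2]; k <- pr[b, 1]; l <- pr[b, 2]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(FALSE)
  }
  TRUE
}
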