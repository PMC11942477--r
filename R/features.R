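#' Maximum-matching (Nussinov) interval map
#'
#' Entry `(i,j)` (1-based here; the definition is positional) is the maximum
#' number of non-crossing admissible base pairs that can be formed using
#' only positions inside the fragment `[i..j]` — the classic Nussinov
#' maximum-matching recursion evaluated for every fragment at once.  The
#' matrix is symmetric with zero diagonal.
#'
#' @param seq An [rna_sequence()] or raw base string.
#' @param rules A [pair_rules()] object.
#' @return An L x L numeric matrix of pair counts.
#' @examples
#' lpss_matrix("GGGAAACCC")[1, 9]   # 3 stacked pairs
#' @export
lpss_matrix <- function(seq, rules = pair_rules()) {
  codes <- seq_codes(seq)
  lpss_cpp(codes, rules_matrix(rules), rules$min_loop)
}

#' Pairing-ambiguity (SRS) interval maps
#'
#' For each base channel (A, U, C, G) the entry `(i,j)` counts the positions
#' of that base inside `[i..j]` that have at least two admissible partner
#' positions inside the same fragment — bases that could pair in more than
#' one way, a proxy for structural ambiguity.  A fifth aggregate channel is
#' the elementwise sum of the four.
#'
#' @inheritParams lpss_matrix
#' @return An L x L x 5 array, channels `A,U,C,G,ALL`.
#' @export
srs_maps <- function(seq, rules = pair_rules()) {
  codes <- seq_codes(seq)
  m <- partner_count_maps_cpp(codes, rules_matrix(rules), rules$min_loop, 2L)
  add_aggregate(m, c("A", "U", "C", "G"))
}

#' A-U availability (BMS) interval maps
#'
#' Same layout as [srs_maps()], but a position is counted when it has at
#' least one admissible partner inside the fragment under the first pairing
#' rule only (A-U); the four base channels are again summed into a fifth
#' aggregate channel.
#'
#' @inheritParams lpss_matrix
#' @return An L x L x 5 array, channels `A,U,C,G,ALL`.
#' @export
bms_maps <- function(seq, rules = pair_rules()) {
  codes <- seq_codes(seq)
  m <- partner_count_maps_cpp(codes, rules_matrix(rules, n_rules = 1L),
                              rules$min_loop, 1L)
  add_aggregate(m, c("A", "U", "C", "G"))
}

add_aggregate <- function(m, names4) {
  L <- dim(m)[1]
  out <- array(0, c(L, L, 5L), dimnames = list(NULL, NULL, c(names4, "ALL")))
  out[, , 1:4] <- m
  out[, , 5] <- m[, , 1] + m[, , 2] + m[, , 3] + m[, , 4]
  out
}

#' Stacking-propensity (RCM) matrix
#'
#' A CDPfold-style soft pairing score.  For an admissible pair `(i,j)` the
#' score accumulates Gaussian-decayed pair weights along the potential helix
#' through `(i,j)`: outward over `(i-t, j+t)` for t = 0, 1, ... and inward
#' over `(i+t, j-t)` for t = 1, 2, ..., each direction stopping at the first
#' out-of-range or inadmissible offset.  Inadmissible cells are 0.
#'
#' @inheritParams lpss_matrix
#' @param sigma Positive decay width of the Gaussian `exp(-t^2 / (2 sigma^2))`.
#' @param weights Named numeric pair weights; names are unordered pairs
#'   written as two bases.
#' @return A symmetric L x L numeric matrix.
#' @export
rcm_matrix <- function(seq, rules = pair_rules(), sigma = 1,
                       weights = c(AU = 2, GC = 3, GU = 0.8)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  codes <- seq_codes(seq)
  rcm_cpp(codes, rules_matrix(rules), rules$min_loop,
          weights_matrix(weights), sigma)
}

weights_matrix <- function(weights) {
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  w <- matrix(0, 4L, 4L)
  for (nm in names(weights)) {
    b <- strsplit(toupper(nm), "")[[1]]
    stopifnot(length(b) == 2L, all(b %in% names(code)))
    w[code[[b[1]]], code[[b[2]]]] <- weights[[nm]]
    w[code[[b[2]]], code[[b[1]]]] <- weights[[nm]]
  }
  w
}

#' Positional (spatial) distance map
#'
#' Every position `p` (0-based) is encoded as its binary index on
#' `B = ceiling(log2(max(L, 2)))` bits, most-significant bit first,
#' concatenated with the one-hot encoding of its base; the map holds the
#' Euclidean distances between these code vectors.
#'
#' @inheritParams lpss_matrix
#' @return A symmetric L x L numeric matrix with zero diagonal.
#' @export
spatial_distance <- function(seq) {
  oh <- seq_onehot(seq)
  L <- nrow(oh)
  B <- max(1L, ceiling(log2(max(L, 2))))
  bits <- vapply(seq_len(B), function(b) {
    bitwAnd(bitwShiftR(0:(L - 1), B - b), 1L)
  }, numeric(L))
  if (L == 1L) bits <- matrix(bits, nrow = 1L)
  as.matrix(stats::dist(cbind(bits, oh)))
}

#' One-hot Manhattan distance map
#'
#' L1 distance between the one-hot base encodings of the two positions:
#' 0 for identical bases, 2 for two distinct unambiguous bases, and 1
#' between a base and `N` (whose one-hot vector is all zero).
#'
#' @inheritParams lpss_matrix
#' @return A symmetric L x L numeric matrix with zero diagonal.
#' @export
manhattan_distance <- function(seq) {
  as.matrix(stats::dist(seq_onehot(seq), method = "manhattan"))
}

bps_labels16 <- function() {
  b <- c("A", "C", "G", "U")
  as.vector(t(outer(b, b, paste0)))  # AA AC AG AU CA CC ...
}

bps_labels10 <- function() {
  c("AA", "AC", "AG", "AU", "CC", "CG", "CU", "GG", "GU", "UU")
}

#' Base-identity contact channels (BPS)
#'
#' The Kronecker product of the per-position one-hot encodings yields 16
#' ordered channels, where channel `(b1, b2)` has entry `(i,j) = 1` iff
#' `base[i] = b1` and `base[j] = b2`.  Because the channel of a reversed
#' label is exactly the transpose of the original channel, the 6 hetero
#' channels whose label reverses an earlier one (CA, GA, UA, GC, UC, UG)
#' are redundant and dropped, leaving 10 channels.
#'
#' @inheritParams lpss_matrix
#' @param reduced If `FALSE`, return all 16 ordered channels.
#' @return An L x L x 10 (or 16) 0/1 array with channel dimnames.
#' @export
bps_tensor <- function(seq, reduced = TRUE) {
  oh <- seq_onehot(seq)
  L <- nrow(oh)
  labs <- bps_labels16()
  out <- array(0, c(L, L, 16L), dimnames = list(NULL, NULL, labs))
  k <- 0L
  for (b1 in 1:4) for (b2 in 1:4) {
    k <- k + 1L
    out[, , k] <- tcrossprod(oh[, b1], oh[, b2])
  }
  if (!reduced) return(out)
  out[, , bps_labels10(), drop = FALSE]
}

#' Channel registry of the structural feature stack
#'
#' The fixed, serialization-stable order of the 24 channels:
#' maximum-matching map, stacking propensity, 5 pairing-ambiguity maps,
#' 5 A-U availability maps, the two distance maps, and the 10 reduced
#' base-identity contact channels.
#'
#' @return Character vector of 24 channel names.
#' @export
feature_registry <- function() {
  c("LPSS", "RCM",
    paste0("SRS_", c("A", "U", "C", "G", "ALL")),
    paste0("BMS_", c("A", "U", "C", "G", "ALL")),
    "SPATIAL", "MANHATTAN",
    paste0("BPS_", bps_labels10()))
}

#' Assemble the 24-channel structural feature stack
#'
#' Computes every structural channel for one sequence and stacks them in
#' registry order into an L x L x 24 array.  With `normalize = TRUE`
#' (the model-input default) each non-BPS channel is divided by its own
#' maximum; identically-zero channels are left as zeros, and the 0/1 BPS
#' channels are never rescaled.
#'
#' @inheritParams rcm_matrix
#' @param normalize Divide each non-BPS channel by its matrix maximum.
#' @return An object of class `"feature_stack"`: an L x L x 24 numeric
#'   array with channel dimnames and a `params` attribute recording
#'   `min_loop`, `sigma`, `weights` and `normalize`.
#' @export
build_feature_stack <- function(seq, rules = pair_rules(), sigma = 1,
                                weights = c(AU = 2, GC = 3, GU = 0.8),
                                normalize = TRUE) {
  seq <- as_rna_sequence(seq)
  L <- nchar(unclass(seq))
  reg <- feature_registry()
  norm1 <- function(m) {
    if (!normalize) return(m)
    mx <- max(m)
    if (mx > 0) m / mx else m
  }
  chans <- c(norm1(lpss_matrix(seq, rules)),
             norm1(rcm_matrix(seq, rules, sigma, weights)),
             apply(srs_maps(seq, rules), 3L, norm1),
             apply(bms_maps(seq, rules), 3L, norm1),
             norm1(spatial_distance(seq)),
             norm1(manhattan_distance(seq)),
             bps_tensor(seq))
  out <- array(chans, c(L, L, 24L), dimnames = list(NULL, NULL, reg))
  structure(out, class = c("feature_stack", "array"),
            params = list(min_loop = rules$min_loop, sigma = sigma,
                          weights = weights, normalize = normalize))
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x)
  cat("<feature_stack>", d[3], "channels of", d[1], "x", d[2], "\n")
  invisible(x)
}

#' Featurize sequences to a fixed length
#'
#' Normalizes a set of sequences to a common length L (sequences longer
#' than L keep their first L bases; shorter ones are right-padded with `N`)
#' and builds one feature stack per sequence.  Rows and columns belonging
#' to padded positions are zeroed in every channel so that padding carries
#' no signal.
#'
#' @param seqs Character vector (or list) of sequences, optionally named.
#' @param L Target length.
#' @param crop `"head"` keeps the first L bases, `"center"` the middle L.
#' @inheritParams build_feature_stack
#' @return A list of `feature_stack` objects, one per input sequence.
#' @export
featurize_sequences <- function(seqs, L = 112L, rules = pair_rules(),
                                sigma = 1, weights = c(AU = 2, GC = 3, GU = 0.8),
                                normalize = TRUE, crop = c("head", "center")) {
  crop <- match.arg(crop)
  lapply(seqs, function(s) {
    s <- unclass(as_rna_sequence(s))
    n <- nchar(s)
    if (n > L) {
      start <- if (crop == "head") 1L else (n - L) %/% 2L + 1L
      s <- substr(s, start, start + L - 1L)
      n <- L
    }
    pad <- L - n
    if (pad > 0L) s <- paste0(s, strrep("N", pad))
    st <- build_feature_stack(s, rules, sigma, weights, normalize)
    if (pad > 0L) {
      st[(n + 1L):L, , ] <- 0
      st[, (n + 1L):L, ] <- 0
    }
    st
  })
}

#' Write / read a feature-set container
#'
#' Serializes a set of feature stacks with their record identifiers,
#' channel registry and featurization parameters as a single container
#' file (RDS, the package's serialization format).
#'
#' @param stacks List of `feature_stack` objects.
#' @param ids Character record identifiers, one per stack.
#' @param path Output file.
#' @return `write_feature_set` returns `path` invisibly; `read_feature_set`
#'   returns a list with elements `features`, `ids`, `registry`, `params`.
#' @export
write_feature_set <- function(stacks, ids, path) {
  stopifnot(length(stacks) == length(ids))
  obj <- list(features = lapply(stacks, unclass),
              ids = as.character(ids),
              registry = feature_registry(),
              params = attr(stacks[[1]], "params"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  readRDS(path)
}
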