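#' Overlapping k-mer tokenization
#'
#' Merges every window of k consecutive bases into one token and brackets
#' the stream with `[CLS]` and `[SEP]`, so a length-L sequence yields
#' exactly `L - k + 3` tokens.
#'
#' @param seq An [rna_sequence()] or raw base string.
#' @param k k-mer size (default 3).
#' @return Object of class `"token_sequence"`: list with `tokens`
#'   (character vector) and `k`.
#' @examples
#' tokenize_kmers("ACGUA", k = 3)$tokens  # [CLS] ACG CGU GUA [SEP]
#' @export
tokenize_kmers <- function(seq, k = 3L) {
  seq <- unclass(as_rna_sequence(seq))
  L <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (L < k) stop("sequence length ", L, " is shorter than k = ", k)
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  structure(list(tokens = c("[CLS]", kmers, "[SEP]"), k = k),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence>", length(x$tokens), "tokens (k =", x$k, ")\n")
  invisible(x)
}

special_tokens <- function() c("[PAD]", "[UNK]", "[CLS]", "[SEP]")

#' Deterministic k-mer vocabulary
#'
#' Enumerates all `|alphabet|^k` k-mers in lexicographic order, preceded by
#' the special tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`.  Ids are 1-based
#' and stable across runs.
#'
#' @param k k-mer size.
#' @param alphabet Base alphabet (default `A,C,G,U`).
#' @return Named integer vector mapping token to id.
#' @export
build_vocab <- function(k = 3L, alphabet = c("A", "C", "G", "U")) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  alphabet <- sort(alphabet)
  grids <- rev(lapply(seq_len(k), function(i) alphabet))
  kmers <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  toks <- c(special_tokens(), kmers)
  setNames(seq_along(toks), toks)
}

#' Encode a token sequence to vocabulary ids
#'
#' Tokens absent from the vocabulary map to the `[UNK]` id.
#'
#' @param tokens A `token_sequence` or character vector of tokens.
#' @param vocab A vocabulary from [build_vocab()].
#' @return Integer id vector.
#' @export
encode_tokens <- function(tokens, vocab) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- vocab[["[UNK]"]]
  as.integer(ids)
}

#' Reconstruct a sequence from its k-mer tokens
#'
#' Inverse of [tokenize_kmers()] for unambiguous input: the first k-mer
#' contributes its k bases and every following k-mer its last base.
#'
#' @param tokens A `token_sequence` or character vector (specials allowed).
#' @return Character scalar sequence.
#' @export
decode_kmers <- function(tokens) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  km <- tokens[!tokens %in% special_tokens()]
  if (length(km) == 0L) stop("no k-mer tokens to decode")
  paste0(km[1], paste(substring(km[-1], nchar(km[-1])), collapse = ""))
}

#' Write / read a plain-text vocabulary
#'
#' One token per line; the id of a token is its line number.
#'
#' @param vocab Named integer vector from [build_vocab()].
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(names(sort(vocab)), path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  toks <- readLines(path)
  setNames(seq_along(toks), toks)
}
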