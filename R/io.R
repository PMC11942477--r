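#' Read and write FASTA
#'
#' Thin wrappers around Biostrings.  Sequences are normalized with
#' [rna_sequence()] on reading (case folding, T to U); records keep their
#' file order.
#'
#' @param path FASTA file.
#' @return `read_fasta` returns a named character vector of normalized
#'   sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) stop("FASTA file contains an empty record")
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vapply(seqs, function(s) unclass(rna_sequence(s)), character(1))
  setNames(out, ids)
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(vapply(seqs, function(s)
    unclass(as_rna_sequence(s)), character(1)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a dot-bracket structure string
#'
#' Matches `(` with `)` by stack discipline.  Pseudoknot bracket alphabets
#' (`[`, `{`, `<` and letters) are rejected: the pairing model underlying
#' the feature stack is nested-only, so pseudoknotted ground truth is
#' refused rather than silently flattened.
#'
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Binary symmetric L x L pair matrix.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(ch %in% c("[", "]", "{", "}", "<", ">") | grepl("[A-Za-z]", ch)))
    stop("pseudoknot bracket symbols are not supported")
  if (!all(ch %in% c(".", "(", ")")))
    stop("unsupported symbol in dot-bracket string")
  L <- length(ch)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(L)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(j, i))
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pairs_to_matrix(pairs, L)
}

#' Render pairs as a dot-bracket string
#'
#' @param pairs Two-column matrix of 1-based pair positions (i < j), or a
#'   binary pair matrix.
#' @param L Sequence length (required when `pairs` is a two-column matrix).
#' @return Dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, L = NULL) {
  if (is.matrix(pairs) && !is.null(L) && ncol(pairs) == 2L) {
    pm <- pairs
  } else {
    L <- nrow(pairs)
    pm <- matrix_to_pairs(pairs)
  }
  ch <- rep(".", L)
  if (nrow(pm) > 0) {
    ch[pm[, 1]] <- "("
    ch[pm[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Convert between pair lists and pair matrices
#'
#' `pairs_to_matrix` builds the binary symmetric L x L contact matrix of a
#' set of (i, j) pairs (1-based, i < j enforced by sorting); both are
#' mutually inverse at threshold 0.5 on binary matrices.
#'
#' @param pairs Two-column integer matrix of pair positions.
#' @param L Sequence length.
#' @return An L x L binary matrix.
#' @export
pairs_to_matrix <- function(pairs, L) {
  m <- matrix(0, L, L)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (any(pairs < 1 | pairs > L)) stop("pair index out of range 1..", L)
    i <- pmin(pairs[, 1], pairs[, 2])
    j <- pmax(pairs[, 1], pairs[, 2])
    if (any(i == j)) stop("a position cannot pair with itself")
    m[cbind(i, j)] <- 1
    m[cbind(j, i)] <- 1
  }
  m
}

#' @param m Numeric L x L matrix (probabilities or binary).
#' @param threshold Pairs are entries whose symmetrized value exceeds this.
#' @rdname pairs_to_matrix
#' @export
matrix_to_pairs <- function(m, threshold = 0.5) {
  sym <- (m + t(m)) / 2
  idx <- which(sym > threshold & upper.tri(sym), arr.ind = TRUE)
  unname(cbind(idx[, 1], idx[, 2]))
}

#' Read a CT structure file
#'
#' Canonical 6-column CT: a header line whose first field is the sequence
#' length, then one line per position with columns
#' `index base prev next pair index`.  Positions are 1-based; a pair column
#' of 0 means unpaired.  Non-reciprocal pairing is an error.
#'
#' @param path CT file.
#' @return List with `id`, `seq` (normalized) and `pairs` (L x L matrix).
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(L) || L < 1) stop("malformed CT header")
  if (length(lines) - 1L != L) stop("CT body has ", length(lines) - 1L,
                                    " lines but header declares ", L)
  body <- do.call(rbind, strsplit(trimws(lines[-1]), "\\s+"))
  if (ncol(body) < 6L) stop("CT lines must have 6 columns")
  idx <- as.integer(body[, 1])
  if (!identical(idx, seq_len(L))) stop("CT position indices are not 1..L")
  partner <- as.integer(body[, 5])
  if (any(is.na(partner)) || any(partner < 0) || any(partner > L))
    stop("CT partner index out of range")
  check_reciprocal(partner)
  seq <- rna_sequence(paste(body[, 2], collapse = ""))
  list(id = paste(hdr[-1], collapse = " "), seq = seq,
       pairs = partner_to_matrix(partner))
}

#' Read a BPSEQ structure file
#'
#' Three columns per line: `position base partner` (1-based; partner 0 is
#' unpaired).  Non-reciprocal pairing is an error.
#'
#' @param path BPSEQ file.
#' @return List with `seq` (normalized) and `pairs` (L x L matrix).
#' @export
read_bpseq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  body <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  if (ncol(body) != 3L) stop("BPSEQ lines must have 3 columns")
  L <- nrow(body)
  idx <- as.integer(body[, 1])
  if (!identical(idx, seq_len(L))) stop("BPSEQ position indices are not 1..L")
  partner <- as.integer(body[, 3])
  if (any(is.na(partner)) || any(partner < 0) || any(partner > L))
    stop("BPSEQ partner index out of range")
  check_reciprocal(partner)
  list(seq = rna_sequence(paste(body[, 2], collapse = "")),
       pairs = partner_to_matrix(partner))
}

check_reciprocal <- function(partner) {
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > 0 && (j == i || partner[j] != i))
      stop("non-reciprocal pairing at position ", i)
  }
  invisible(TRUE)
}

partner_to_matrix <- function(partner) {
  L <- length(partner)
  paired <- which(partner > 0 & partner > seq_len(L))
  pairs_to_matrix(cbind(paired, partner[paired]), L)
}

#' Read / write 2-column label tables
#'
#' Tab-separated `id<TAB>label` with no header.
#'
#' @param path TSV file.
#' @return Data frame with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(df) != 2L) stop("label file must have exactly 2 columns")
  setNames(df, c("id", "label"))
}

#' @param labels Data frame with columns `id`, `label`.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  write.table(labels[, c("id", "label")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read structures from a dot-bracket sidecar file
#'
#' One dot-bracket line per FASTA record, in record order.
#'
#' @param path Text file of dot-bracket lines.
#' @return List of pair matrices.
#' @export
read_dotbracket_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_dotbracket)
}

#' @param structures List of pair matrices or dot-bracket strings.
#' @rdname read_dotbracket_file
#' @export
write_dotbracket_file <- function(structures, path) {
  lines <- vapply(structures, function(s) {
    if (is.character(s)) s else pairs_to_dotbracket(s)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
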