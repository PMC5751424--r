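#' DNA sequence sets
#'
#' A `seq_set` is the package's in-memory representation of a multi-FASTA
#' dataset: a named character vector of uppercase DNA sequences over the
#' alphabet `{A, C, G, T, N}`.  `N` marks masked or ambiguous positions; any
#' window containing an `N` is excluded from motif search and scanning.  All
#' start coordinates handled by the package are 0-based, and intervals are
#' half-open (BED convention); conversion to 1-based happens only at
#' presentation boundaries (e.g. the `--one-based` switch of the command-line
#' interface).
#'
#' @param x A named character vector of DNA sequences (lowercase allowed,
#'   uppercased on construction), or an existing `seq_set`.
#' @param ids Optional character vector of sequence identifiers; defaults to
#'   `names(x)`.
#'
#' @return A `seq_set` object (named character vector).
#' @examples
#' s <- as_seq_set(c(seq1 = "ACGTACGT", seq2 = "ttttACGT"))
#' seq_lengths(s)
#' @export
as_seq_set <- function(x, ids = NULL) {
  if (inherits(x, "seq_set") && is.null(ids)) return(x)
  x <- stats::setNames(as.character(x), names(x))
  if (!is.null(ids)) names(x) <- ids
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("every sequence needs a non-empty id", call. = FALSE)
  }
  x <- toupper(x)
  validate_seq_set(structure(x, class = "seq_set"))
}

validate_seq_set <- function(x) {
  ids <- names(x)
  if (length(x) < 1L) stop("sequence set is empty", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(x))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(x)], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("illegal characters (outside A/C/G/T/N) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname as_seq_set
#' @export
seq_lengths <- function(x) {
  nchar(unclass(as_seq_set(x)))
}

#' @export
print.seq_set <- function(x, ...) {
  L <- seq_lengths(x)
  cat(sprintf("<seq_set> %d sequence(s), lengths %d..%d\n",
              length(x), min(L), max(L)))
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s (%d nt) %s%s\n", names(x)[i], nchar(s),
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i, ...) {
  structure(NextMethod(), class = "seq_set")
}

# integer encoding A=1 C=2 G=3 T=4, NA for N; used by every scoring routine
.encode_chars <- function(s) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  code
}

.encode_set <- function(seqs) {
  seqs <- as_seq_set(seqs)
  enc <- lapply(unclass(seqs), .encode_chars)
  lens <- lengths(enc)
  list(enc = enc,
       flat = unlist(enc, use.names = FALSE),
       offs = cumsum(c(0L, lens[-length(lens)])),  # flat index of char j of seq i = offs[i] + j
       lens = lens,
       ids = names(seqs),
       n = length(enc))
}

# logical vector over 0-based offsets 0..L-w: TRUE if the window is N-free
.valid_windows <- function(enc_i, w) {
  L <- length(enc_i)
  if (L < w) return(logical(0))
  nas <- cumsum(c(0L, is.na(enc_i)))
  v <- L - w + 1L
  (nas[(w + 1L):(L + 1L)] - nas[1L:v]) == 0L
}

.revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1L)))
}
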