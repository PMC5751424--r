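#' Read a multi-FASTA file into a sequence set
#'
#' Sequences are uppercased on input.  Only `A`, `C`, `G`, `T` and `N` are
#' accepted; anything else (including IUPAC ambiguity codes other than `N`)
#' raises an error naming the offending record, as does an empty file or a
#' duplicated identifier.  FASTA headers are truncated at the first
#' whitespace, the usual convention for sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A [as_seq_set()] object, records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  as_seq_set(as.character(raw), ids = ids)
}

#' Write a sequence set to a FASTA file
#'
#' @param seqs A sequence set.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_set(seqs)
  xs <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

.site_cols <- c("seq_id", "start", "end", "strand", "score", "p_value")

#' Site tables
#'
#' A site table records motif occurrences (annotated or predicted): one row
#' per site with BED-like 0-based half-open coordinates.  Columns are
#' `seq_id`, `start`, `end` (= start + width), `strand` (`+`/`-`), `score`
#' and `p_value` (either may be `NA` for annotations).
#'
#' @param seq_id Character vector of sequence identifiers.
#' @param start Integer 0-based start offsets.
#' @param width Motif width (scalar; constant within one table).
#' @param strand `"+"` or `"-"` per site.
#' @param score Numeric score per site (`NA` allowed).
#' @param p_value Numeric p-value per site (`NA` allowed).
#' @return A `data.frame` with the six site-table columns.
#' @export
site_table <- function(seq_id = character(), start = integer(), width = 1L,
                       strand = "+", score = NA_real_, p_value = NA_real_) {
  n <- length(seq_id)
  width <- as.integer(width)
  if (width < 1L) stop("width must be positive", call. = FALSE)
  out <- data.frame(seq_id = as.character(seq_id),
                    start = as.integer(start),
                    end = as.integer(start) + width,
                    strand = rep_len(as.character(strand), n),
                    score = rep_len(as.numeric(score), n),
                    p_value = rep_len(as.numeric(p_value), n),
                    stringsAsFactors = FALSE)
  validate_site_table(out)
}

validate_site_table <- function(sites, seqs = NULL) {
  if (!all(.site_cols %in% names(sites))) {
    stop("site table must have columns ", paste(.site_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites)) {
    wds <- sites$end - sites$start
    if (any(wds <= 0L)) stop("site width must be positive", call. = FALSE)
    if (length(unique(wds)) > 1L) {
      stop("site width must be constant within one table", call. = FALSE)
    }
    if (any(sites$start < 0L)) stop("negative site start", call. = FALSE)
    if (!all(sites$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
    if (!is.null(seqs)) {
      seqs <- as_seq_set(seqs)
      L <- seq_lengths(seqs)[match(sites$seq_id, names(seqs))]
      if (anyNA(L)) {
        stop("site refers to unknown sequence id(s): ",
             paste(unique(sites$seq_id[is.na(L)]), collapse = ", "),
             call. = FALSE)
      }
      if (any(sites$end > L)) stop("site extends past sequence end",
                                   call. = FALSE)
    }
  }
  sites[.site_cols]
}

#' Read and write site tables
#'
#' Sites are stored as a tab-separated table with a header line and BED-like
#' 0-based half-open coordinates; [read_sites()] and [write_sites()] are exact
#' inverses.  `one_based = TRUE` converts 1-based starts (common in curated
#' binding-site annotations) to the package's internal 0-based convention on
#' input.
#'
#' @param sites A site table ([site_table()]).
#' @param path File path.
#' @param one_based For [read_sites()]: interpret the `start` column as
#'   1-based inclusive and shift down by one.
#' @return [read_sites()] returns a site table; [write_sites()] returns
#'   `path` invisibly.
#' @export
write_sites <- function(sites, path) {
  sites <- validate_site_table(sites)
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path, one_based = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(seq_id = "character"))
  if (nrow(tab) && one_based) {
    tab$start <- tab$start - 1L
    tab$end <- tab$end - 1L
  }
  validate_site_table(tab)
}

#' Write a motif model to disk
#'
#' `format = "meme"` writes the MEME minimal motif format (version header,
#' alphabet, background frequencies, and a `letter-probability matrix` with
#' one row per motif column); `format = "tsv"` writes the frequency matrix as
#' a plain tab-separated table with rows A, C, G, T.  Probabilities are
#' printed to 6 decimals.
#'
#' @param model A [build_model()] motif model with normalized frequencies.
#' @param path Output path.
#' @param format `"meme"` or `"tsv"`.
#' @param name Motif name used in the MEME header.
#' @return `path`, invisibly.
#' @export
write_motif_model <- function(model, path, format = c("meme", "tsv"),
                              name = "motif1") {
  format <- match.arg(format)
  stopifnot(inherits(model, "motif_model"))
  if (any(abs(colSums(model$theta) - 1) > 1e-6)) {
    stop("model frequencies are not normalized; rebuild with a pseudocount",
         call. = FALSE)
  }
  if (format == "tsv") {
    tab <- as.data.frame(round(model$theta, 6L))
    names(tab) <- paste0("pos", seq_len(model$width))
    utils::write.table(cbind(base = c("A", "C", "G", "T"), tab), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  bg <- sprintf("%.6f", model$background)
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %s C %s G %s T %s", bg[1], bg[2], bg[3], bg[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model$width, model$n_support)), con)
  for (j in seq_len(model$width)) {
    writeLines(paste(sprintf("%.6f", model$theta[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a motif model written in MEME minimal format
#'
#' @param path Path to a MEME minimal motif file (one motif).
#' @return A `motif_model` with `theta`, `background`, `width` and
#'   `n_support` restored; counts are not stored in the format and are
#'   returned as `theta * n_support`.
#' @export
read_motif_model <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  background <- rep(0.25, 4)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    background <- as.numeric(toks[seq(2L, 8L, by = 2L)])
  }
  hdr_i <- grep("^letter-probability matrix:", lines)
  if (!length(hdr_i)) stop("no letter-probability matrix in ", path,
                           call. = FALSE)
  hdr <- lines[hdr_i[1L]]
  w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
  nsites <- suppressWarnings(
    as.integer(sub(".*\\bnsites=\\s*(\\d+).*", "\\1", hdr)))
  if (is.na(nsites)) nsites <- 1L
  rows <- lines[(hdr_i[1L] + 1L):(hdr_i[1L] + w)]
  theta <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4L)))
  new_motif_model(counts = t(theta) * nsites, theta = t(theta),
                  background = background, pseudocount = NA_real_,
                  n_support = nsites)
}
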