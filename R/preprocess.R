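#' Low-complexity masking of a sequence set (DUST-style)
#'
#' Slides a window (default 64 nt) along each sequence and computes the
#' classical DUST triplet statistic: with `c_t` the count of each of the 64
#' trinucleotides inside the window, the score is
#' `sum_t c_t * (c_t - 1) / 2 / (len - 3)`.  Every position covered by a
#' window whose score exceeds `threshold` (default 2.0, the classical DUST
#' cutoff) is masked by replacing it with `N`.  Triplets containing `N` are
#' skipped, which makes the operation idempotent.  Masking is soft: sequence
#' lengths and coordinates are unchanged, so downstream site coordinates
#' remain valid against the original FASTA.
#'
#' @param seqs A sequence set.
#' @param window Sliding window length in nt (>= 3; clamped with a warning if
#'   longer than the shortest sequence).
#' @param threshold Mask windows whose normalized triplet score exceeds this.
#' @return A `mask_result`: `masked_set` (the masked sequences), `intervals`
#'   (per-sequence data frames of disjoint 0-based half-open masked
#'   intervals) and `fraction_masked`.
#' @examples
#' r <- dust_mask(as_seq_set(c(a = paste(rep("A", 64), collapse = ""))))
#' r$fraction_masked  # homopolymer: fully masked
#' @export
dust_mask <- function(seqs, window = 64L, threshold = 2.0) {
  seqs <- as_seq_set(seqs)
  if (window < 3L) stop("DUST window must be >= 3", call. = FALSE)
  lens <- seq_lengths(seqs)
  if (window > min(lens)) {
    warning("DUST window clamped to shortest sequence length (",
            min(lens), ")")
  }
  masked <- character(length(seqs))
  intervals <- vector("list", length(seqs))
  names(intervals) <- names(seqs)
  total <- 0L
  for (i in seq_along(seqs)) {
    s <- unclass(seqs)[[i]]
    win <- min(window, lens[i])
    flag <- .dust_flag(.encode_chars(s), win, threshold)
    intervals[[i]] <- .runs_to_intervals(flag)
    if (any(flag)) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      chars[flag] <- "N"
      masked[i] <- paste(chars, collapse = "")
      total <- total + sum(flag)
    } else {
      masked[i] <- s
    }
  }
  structure(list(masked_set = as_seq_set(masked, ids = names(seqs)),
                 intervals = intervals,
                 fraction_masked = total / sum(lens)),
            class = "mask_result")
}

# logical mask over positions: TRUE where covered by a high-scoring window.
# Incremental triplet bookkeeping: one add + one drop per slide.
.dust_flag <- function(enc, window, threshold) {
  L <- length(enc)
  flag <- logical(L)
  if (L < 3L || window < 3L) return(flag)
  # triplet code in 1..64 at position p (1-based, p <= L-2); NA with any N
  tri <- enc[1:(L - 2L)] * 16L + enc[2:(L - 1L)] * 4L + enc[3:L] - 20L
  ntri_win <- window - 2L
  counts <- integer(64L)
  pairs <- 0  # sum c*(c-1)/2 over triplet counts
  denom <- window - 3L
  if (denom < 1L) denom <- 1L
  n_start <- L - window + 1L
  if (n_start < 1L) n_start <- 1L
  # initialize first window
  for (p in seq_len(min(ntri_win, length(tri)))) {
    t <- tri[p]
    if (!is.na(t)) { pairs <- pairs + counts[t]; counts[t] <- counts[t] + 1L }
  }
  for (st in seq_len(n_start)) {
    if (pairs / denom > threshold) flag[st:(min(st + window - 1L, L))] <- TRUE
    # slide: drop triplet at st, add triplet at st + ntri_win
    t_out <- tri[st]
    if (!is.na(t_out)) { counts[t_out] <- counts[t_out] - 1L; pairs <- pairs - counts[t_out] }
    p_in <- st + ntri_win
    if (p_in <= length(tri)) {
      t_in <- tri[p_in]
      if (!is.na(t_in)) { pairs <- pairs + counts[t_in]; counts[t_in] <- counts[t_in] + 1L }
    }
  }
  flag
}

# logical vector -> data.frame of 0-based half-open (start, end) runs of TRUE
.runs_to_intervals <- function(flag) {
  if (!any(flag)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Mark low-complexity start positions invalid via the complexity ratio
#'
#' Fallback filter for when DUST-style masking is disabled: every width-`w`
#' window whose [complexity_ratio()] falls below `min_cs` is masked (replaced
#' by `N`), removing it from the pool of valid motif start positions.  A
#' homopolymer window (`AAAAAA`, ratio about 0.0154) is masked at the default
#' threshold; an ordinary mixed window (`ATACGT`, ratio 45) is kept.
#'
#' @param seqs A sequence set.
#' @param w Window (motif) width.
#' @param min_cs Minimum admissible complexity ratio; `0` masks nothing.
#' @return A `mask_result` (same shape as [dust_mask()]).
#' @export
complexity_filter <- function(seqs, w, min_cs = 1) {
  seqs <- as_seq_set(seqs)
  stopifnot(w > 0)
  masked <- character(length(seqs))
  intervals <- vector("list", length(seqs))
  names(intervals) <- names(seqs)
  lens <- seq_lengths(seqs)
  total <- 0L
  for (i in seq_along(seqs)) {
    s <- unclass(seqs)[[i]]
    enc <- .encode_chars(s)
    L <- lens[i]
    flag <- logical(L)
    if (min_cs > 0 && L >= w) {
      ok <- .valid_windows(enc, w)
      for (o in which(ok)) {  # o is 1-based start
        word_idx <- enc[o:(o + w - 1L)]
        tab <- tabulate(word_idx, nbins = 4L)
        ratio <- factorial(w) / prod(tab[word_idx])
        if (ratio < min_cs) flag[o:(o + w - 1L)] <- TRUE
      }
    }
    intervals[[i]] <- .runs_to_intervals(flag)
    if (any(flag)) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      chars[flag] <- "N"
      masked[i] <- paste(chars, collapse = "")
      total <- total + sum(flag)
    } else masked[i] <- s
  }
  structure(list(masked_set = as_seq_set(masked, ids = names(seqs)),
                 intervals = intervals,
                 fraction_masked = total / sum(lens)),
            class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("<mask_result> %.1f%% of residues masked across %d sequence(s)\n",
              100 * x$fraction_masked, length(x$masked_set)))
  invisible(x)
}
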