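#' Generate a planted-motif dataset with known ground truth
#'
#' Emulates the standard planted (l, d) motif benchmark: background
#' sequences drawn i.i.d. from an order-0 nucleotide model, each receiving
#' one or more motif instances at recorded, non-overlapping, uniformly
#' chosen positions.  Instances are either the consensus with exactly
#' `mutations_per_site` substitutions at random positions (each substituted
#' to a different base), or — if `freq_matrix` is given — an independent
#' draw from a 4 x `width` generating frequency matrix.
#'
#' Defaults are the package's standard challenge regime for a ChIP-seq-like
#' promoter set: 20 sequences of 200 nt with an 11-mer planted at 2
#' substitutions per instance over a uniform background.
#'
#' @param n_sequences Number of sequences.
#' @param length Sequence length `L`.
#' @param width Motif width `w` (`w <= L`).
#' @param consensus Optional consensus string of length `width`; drawn at
#'   random from the background if `NULL` (and `freq_matrix` is `NULL`).
#' @param freq_matrix Optional 4 x `width` column-stochastic generating
#'   matrix (rows A, C, G, T); overrides consensus/mutation planting.
#' @param mutations_per_site Substitutions per planted instance
#'   (`< width`).
#' @param background Length-4 background probabilities (A, C, G, T).
#' @param instances_per_sequence Planted instances per sequence (>= 1; they
#'   must fit without overlap).
#' @param seed Optional RNG seed.
#' @return A list: `seqs` (the sequence set), `truth` (a [site_table()] of
#'   planted positions) and `consensus` (the generating consensus, or `NA`
#'   for frequency-matrix planting).
#' @export
generate_planted <- function(n_sequences = 20L, length = 200L, width = 11L,
                             consensus = NULL, freq_matrix = NULL,
                             mutations_per_site = 2L,
                             background = c(0.25, 0.25, 0.25, 0.25),
                             instances_per_sequence = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  w <- as.integer(width)
  n <- as.integer(n_sequences)
  d <- as.integer(mutations_per_site)
  k <- as.integer(instances_per_sequence)
  stopifnot(w <= L, d < w, k >= 1L, n >= 1L)
  if (k * w > L) stop("instances do not fit in the sequence length",
                      call. = FALSE)
  background <- background / sum(background)
  bases <- c("A", "C", "G", "T")
  if (is.null(freq_matrix)) {
    if (is.null(consensus)) {
      consensus <- paste(sample(bases, w, replace = TRUE, prob = background),
                         collapse = "")
    }
    consensus <- toupper(consensus)
    stopifnot(nchar(consensus) == w)
    cons_idx <- .encode_chars(consensus)
    if (anyNA(cons_idx)) stop("consensus must be over A/C/G/T", call. = FALSE)
  } else {
    freq_matrix <- as.matrix(freq_matrix)
    stopifnot(nrow(freq_matrix) == 4L, ncol(freq_matrix) == w,
              all(abs(colSums(freq_matrix) - 1) < 1e-6))
    consensus <- NA_character_
  }
  ids <- sprintf("seq%d", seq_len(n))
  seqs <- character(n)
  truth_id <- character(0)
  truth_start <- integer(0)
  for (i in seq_len(n)) {
    chars <- sample(bases, L, replace = TRUE, prob = background)
    starts <- .place_nonoverlapping(L, w, k)
    for (st in starts) {  # st is 0-based
      if (is.null(freq_matrix)) {
        inst <- cons_idx
        if (d > 0L) {
          pos <- sample.int(w, d)
          for (p in pos) inst[p] <- sample(setdiff(1:4, inst[p]), 1L)
        }
      } else {
        inst <- vapply(seq_len(w),
                       function(j) sample.int(4L, 1L, prob = freq_matrix[, j]),
                       integer(1L))
      }
      chars[(st + 1L):(st + w)] <- bases[inst]
    }
    seqs[i] <- paste(chars, collapse = "")
    truth_id <- c(truth_id, rep(ids[i], k))
    truth_start <- c(truth_start, starts)
  }
  list(seqs = as_seq_set(seqs, ids = ids),
       truth = site_table(seq_id = truth_id, start = truth_start, width = w),
       consensus = consensus)
}

# k non-overlapping uniform 0-based starts for width-w windows in length L
.place_nonoverlapping <- function(L, w, k, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    starts <- sort(sample.int(L - w + 1L, k) - 1L)
    if (k == 1L || all(diff(starts) >= w)) return(starts)
  }
  stop("could not place ", k, " non-overlapping instances", call. = FALSE)
}

#' Inject low-complexity runs into a dataset
#'
#' Overwrites a target fraction of the residues outside the ground-truth
#' motif windows with homopolymer or short-period (1-3 nt unit) repeat runs,
#' emulating the spurious low-complexity stretches that preprocessing is
#' meant to remove.  Runs never overlap the truth windows or each other.
#'
#' @param seqs A sequence set.
#' @param low_complexity_fraction Target fraction of residues to overwrite,
#'   in `[0, 1)`.
#' @param truth Optional [site_table()] of protected windows.
#' @param run_length Length of each inserted run (default 16).
#' @param seed Optional RNG seed.
#' @return A list: `seqs` (degraded set) and `intervals` (per-sequence data
#'   frames of inserted 0-based half-open run intervals).
#' @export
degrade_low_complexity <- function(seqs, low_complexity_fraction,
                                   truth = NULL, run_length = 16L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(low_complexity_fraction >= 0, low_complexity_fraction < 1)
  seqs <- as_seq_set(seqs)
  intervals <- lapply(seq_along(seqs),
                      function(i) data.frame(start = integer(),
                                             end = integer()))
  names(intervals) <- names(seqs)
  if (low_complexity_fraction == 0) {
    return(list(seqs = seqs, intervals = intervals))
  }
  bases <- c("A", "C", "G", "T")
  out <- unclass(seqs)
  lens <- seq_lengths(seqs)
  target <- low_complexity_fraction * sum(lens)
  inserted <- 0L
  tries <- 0L
  while (inserted < target && tries < 10000L) {
    tries <- tries + 1L
    i <- sample.int(length(seqs), 1L)
    L <- lens[i]
    if (L < run_length) next
    st <- sample.int(L - run_length + 1L, 1L) - 1L  # 0-based
    blocked <- intervals[[i]]
    if (!is.null(truth)) {
      tr <- truth[truth$seq_id == names(seqs)[i], , drop = FALSE]
      blocked <- rbind(blocked, tr[, c("start", "end")])
    }
    if (nrow(blocked) &&
        any(st < blocked$end & st + run_length > blocked$start)) next
    # homopolymers dominate real spurious stretches (and are what a
    # triplet-window masker is built to catch); longer periods are rarer
    period <- sample.int(3L, 1L, prob = c(0.5, 0.3, 0.2))
    unit <- sample(bases, period, replace = TRUE)
    run <- rep_len(unit, run_length)
    chars <- strsplit(out[[i]], "", fixed = TRUE)[[1L]]
    chars[(st + 1L):(st + run_length)] <- run
    out[[i]] <- paste(chars, collapse = "")
    intervals[[i]] <- rbind(intervals[[i]],
                            data.frame(start = st, end = st + run_length))
    inserted <- inserted + run_length
  }
  intervals <- lapply(intervals, function(d) d[order(d$start), , drop = FALSE])
  list(seqs = as_seq_set(out, ids = names(seqs)), intervals = intervals)
}
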