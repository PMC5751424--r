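# Internal fitness evaluator.
#
# Precomputes an integer encoding of the dataset so that one fitness
# evaluation is a handful of vectorized operations: window extraction is a
# single subscript into the concatenated encoding, per-column counts are one
# tabulate() call, and the complexity term is computed for all rows at once.
# Everything downstream of construction (GA, VNS, scanning) goes through one
# of these.

.make_evaluator <- function(seqs, w, weight_v = 0.8, pseudocount = 1,
                            background = "empirical") {
  seqs <- as_seq_set(seqs)
  es <- .encode_set(seqs)
  n <- es$n
  w <- as.integer(w)
  if (any(es$lens < w)) {
    stop("motif width ", w, " exceeds length of sequence(s): ",
         paste(es$ids[es$lens < w], collapse = ", "), call. = FALSE)
  }
  bg <- .resolve_background(background, seqs)
  log2bg <- log2(bg)
  valid <- lapply(es$enc, .valid_windows, w = w)
  lfact_w <- lfactorial(w)
  jrep <- rep.int(seq_len(w), n)                  # within-window positions
  col_off <- 4L * rep(seq_len(w) - 1L, times = n) # counts bin offsets
  row_off <- 4L * rep(seq_len(n) - 1L, each = w)  # per-word bin offsets
  log4 <- log(4)

  # 0-based starts -> w x n matrix of letter codes (error on N / bounds)
  windows <- function(starts) {
    if (length(starts) != n) stop("need one start per sequence", call. = FALSE)
    if (any(starts < 0L) || any(starts > es$lens - w)) {
      stop("start offset out of bounds", call. = FALSE)
    }
    E <- matrix(es$flat[rep.int(es$offs + starts, rep.int(w, n)) + jrep],
                nrow = w)
    if (anyNA(E)) stop("window contains N (masked/ambiguous) characters",
                       call. = FALSE)
    E
  }

  counts_of <- function(E) {
    matrix(tabulate(as.integer(E) + col_off, nbins = 4L * w), nrow = 4L)
  }

  # complexity score: sum over words of log4( w! / prod_j count(word[j]) )
  cs_of <- function(E) {
    wc <- tabulate(as.integer(E) + row_off, nbins = 4L * n)  # 4 x n letter counts
    # wc index of letter E[j,i] within word i is E[j,i] + 4*(i-1) = E + row_off
    lookup <- wc[as.integer(E) + row_off]
    (n * lfact_w - sum(log(lookup))) / log4
  }

  ic_of <- function(counts) {
    theta <- (counts + pseudocount) / (n + 4 * pseudocount)
    sum(theta * (log2(theta) - log2bg))
  }

  fit <- function(starts) {
    E <- windows(starts)
    ic <- ic_of(counts_of(E))
    if (weight_v == 1) return(ic)
    weight_v * ic + (1 - weight_v) * cs_of(E)
  }

  breakdown <- function(starts) {
    E <- windows(starts)
    ic <- ic_of(counts_of(E))
    cs <- cs_of(E)
    structure(list(ic = ic, cs = cs,
                   fi = weight_v * ic + (1 - weight_v) * cs,
                   weight_v = weight_v),
              class = "fitness_breakdown")
  }

  model_of <- function(starts) {
    counts <- counts_of(windows(starts))
    theta <- (counts + pseudocount) / (n + 4 * pseudocount)
    new_motif_model(counts = counts, theta = theta, background = bg,
                    pseudocount = pseudocount, n_support = n)
  }

  # log-odds matrix from an arbitrary stack of w-mers (used in construction,
  # where the model comes from a partial path rather than a full alignment)
  logodds_from_words <- function(word_mat) {
    m <- ncol(word_mat)
    cnt <- matrix(tabulate(as.integer(word_mat) +
                             4L * rep(seq_len(w) - 1L, times = m),
                           nbins = 4L * w), nrow = 4L)
    theta <- (cnt + pseudocount) / (m + 4 * pseudocount)
    log2(theta) - log2bg
  }

  # scores of every window of sequence i under a 4 x w log-odds matrix;
  # NA at offsets whose window contains N
  scan_scores <- function(lo, i) {
    enc_i <- es$enc[[i]]
    v <- es$lens[i] - w + 1L
    if (v < 1L) return(numeric(0))
    s <- numeric(v)
    for (j in seq_len(w)) s <- s + lo[, j][enc_i[j:(j + v - 1L)]]
    s
  }

  list(seqs = seqs, es = es, n = n, w = w, bg = bg, valid = valid,
       weight_v = weight_v, pseudocount = pseudocount,
       windows = windows, fit = fit, breakdown = breakdown,
       model_of = model_of, logodds_from_words = logodds_from_words,
       scan_scores = scan_scores)
}

# random valid start in sequence i, or NA if none
.random_valid_start <- function(ev, i) {
  ok <- which(ev$valid[[i]])
  if (!length(ok)) return(NA_integer_)
  ok[sample.int(length(ok), 1L)] - 1L
}
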