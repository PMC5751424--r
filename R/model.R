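#' @keywords internal
new_motif_model <- function(counts, theta, background, pseudocount,
                            n_support) {
  dimnames(counts) <- dimnames(theta) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(width = ncol(theta), counts = counts, theta = theta,
                 background = as.numeric(background),
                 pseudocount = pseudocount, n_support = n_support),
            class = "motif_model")
}

#' Build a position-specific score matrix from an alignment of start positions
#'
#' The vector of start offsets (one per sequence, 0-based) selects one `w`-mer
#' per sequence — a multiple local sequence alignment.  Per-column letter
#' counts are converted to relative frequencies with additive smoothing:
#' `theta[i, j] = (counts[i, j] + pseudocount) / (n + 4 * pseudocount)` where
#' `n` is the number of aligned `w`-mers.  The background is a length-4
#' probability vector; by default the empirical mononucleotide frequencies of
#' the dataset (`background = "uniform"` forces 0.25 each).
#'
#' @param seqs A sequence set.
#' @param starts Integer vector of 0-based start offsets, one per sequence.
#' @param w Motif width.
#' @param pseudocount Additive smoothing constant (default 1).
#' @param background `"empirical"`, `"uniform"`, or a numeric length-4
#'   probability vector in A, C, G, T order.
#' @return A `motif_model`: `counts` and `theta` are 4 x `w` matrices (rows
#'   A, C, G, T), plus `background`, `pseudocount` and `n_support`.
#' @examples
#' s <- as_seq_set(c(a = "GTCTGTGGTTT", b = "GTCTGAGGTTT"))
#' m <- build_model(s, c(0, 0), 11)
#' m$theta[, 1]  # G gets (2 + 1) / (2 + 4) = 0.5
#' @export
build_model <- function(seqs, starts, w, pseudocount = 1,
                        background = "empirical") {
  seqs <- as_seq_set(seqs)
  ev <- .make_evaluator(seqs, w, pseudocount = pseudocount,
                        background = background)
  ev$model_of(as.integer(starts))
}

.resolve_background <- function(background, seqs = NULL) {
  if (is.numeric(background)) {
    stopifnot(length(background) == 4L, all(background > 0))
    return(background / sum(background))
  }
  background <- match.arg(background, c("empirical", "uniform"))
  if (background == "uniform" || is.null(seqs)) return(rep(0.25, 4))
  counts <- tabulate(unlist(lapply(unclass(as_seq_set(seqs)), .encode_chars),
                            use.names = FALSE), nbins = 4L)
  if (any(counts == 0L)) counts <- counts + 1L  # degenerate composition guard
  counts / sum(counts)
}

#' Information content of a motif model
#'
#' Sum over matrix cells of `theta * log2(theta / background)`: the total
#' Kullback-Leibler divergence, in bits, of the motif columns from the
#' background distribution.  Non-negative for any model whose columns are
#' probability distributions.
#'
#' @param model A `motif_model` with strictly positive `theta`.
#' @return Information content in bits.
#' @export
information_content <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  th <- model$theta
  if (any(th <= 0)) {
    stop("theta has zero entries; rebuild the model with pseudocount > 0",
         call. = FALSE)
  }
  sum(th * log2(th / model$background))
}

#' Complexity ratio of a DNA word
#'
#' The pre-logarithm complexity of a `w`-mer: `w!` divided by the product,
#' position by position, of the count of that position's letter within the
#' word.  Maximal (`w!`) when all letters are distinct, minimal for a
#' homopolymer.  For example `AAAAAA` gives `720 / 6^6 = 720/46656`, about
#' 0.0154, and `ATACGT` gives `720 / (2*2*2*1*1*2) = 45`.
#'
#' @param word A string over A/C/G/T (case-insensitive).
#' @return The complexity ratio, a positive number.
#' @export
complexity_ratio <- function(word) {
  word <- toupper(word)
  if (!nzchar(word)) stop("empty word", call. = FALSE)
  idx <- .encode_chars(word)
  if (anyNA(idx)) stop("word must be over A/C/G/T: ", word, call. = FALSE)
  tab <- tabulate(idx, nbins = 4L)
  factorial(length(idx)) / prod(tab[idx])
}

#' Complexity score of a start-position alignment
#'
#' Sum over the selected `w`-mers of `log4(complexity_ratio(w-mer))` (log
#' base 4 for the nucleotide alphabet).  Higher means more complex; strongly
#' negative for alignments stacked on low-complexity sequence.  An empty
#' selection scores 0.
#'
#' @inheritParams build_model
#' @return The complexity score (dimensionless).
#' @export
complexity_score <- function(seqs, starts, w) {
  seqs <- as_seq_set(seqs)
  starts <- as.integer(starts)
  if (length(starts) == 0L) return(0)
  words <- substring(unclass(seqs)[seq_along(starts)], starts + 1L,
                     starts + w)
  sum(vapply(words, function(x) log(complexity_ratio(x), base = 4),
             numeric(1L)))
}

#' Bi-objective fitness of a start-position alignment
#'
#' The scalar objective optimized by the discovery loop: a weighted sum of
#' information content and complexity score,
#' `fi = weight_v * IC + (1 - weight_v) * CS`.  The default weight 0.8
#' emphasizes information content; `weight_v = 1` collapses to a
#' mono-objective information-content search (appropriate when low-complexity
#' sequence has already been masked in preprocessing).
#'
#' @inheritParams build_model
#' @param weight_v Weight on information content, in `[0, 1]`.
#' @return A `fitness_breakdown` list with components `ic`, `cs`, `fi` and
#'   `weight_v`.
#' @export
motif_fitness <- function(seqs, starts, w, weight_v = 0.8, pseudocount = 1,
                          background = "empirical") {
  stopifnot(weight_v >= 0, weight_v <= 1)
  ev <- .make_evaluator(as_seq_set(seqs), w, weight_v = weight_v,
                        pseudocount = pseudocount, background = background)
  ev$breakdown(as.integer(starts))
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat(sprintf("fitness fi = %.4f  (ic = %.4f bits, cs = %.4f, weight_v = %g)\n",
              x$fi, x$ic, x$cs, x$weight_v))
  invisible(x)
}

#' Log-odds score of a single window under a motif model
#'
#' `sum_j log2(theta[word[j], j] / background[word[j]])` — the standard PSSM
#' log-likelihood-ratio score of a `w`-mer against the background model.
#'
#' @param model A `motif_model`.
#' @param word A string of length `model$width` over A/C/G/T.
#' @return The log2 odds score (can be `-Inf` if `theta` has zeros).
#' @export
window_score <- function(model, word) {
  stopifnot(inherits(model, "motif_model"))
  idx <- .encode_chars(toupper(word))
  if (length(idx) != model$width) {
    stop("word length ", length(idx), " != model width ", model$width,
         call. = FALSE)
  }
  if (anyNA(idx)) stop("word must be N-free", call. = FALSE)
  sum(log2(model$theta[cbind(idx, seq_along(idx))] / model$background[idx]))
}

#' Symmetrize a motif model with its reverse complement
#'
#' Averages the frequency matrix with its reverse complement (columns
#' reversed, A<->T and C<->G swapped); the background is likewise averaged
#' with its complement.  The result is a fixed point of the
#' reverse-complement transform, which is the natural model for palindromic
#' binding sites scored on both strands.
#'
#' @param model A `motif_model`.
#' @return A `motif_model` invariant under its own reverse-complement
#'   transform.
#' @export
revcomp_symmetrize <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  new_motif_model(counts = (model$counts + rc(model$counts)) / 2,
                  theta = (model$theta + rc(model$theta)) / 2,
                  background = (model$background + rev(model$background)) / 2,
                  pseudocount = model$pseudocount,
                  n_support = model$n_support)
}

# reverse-complemented model for minus-strand scanning (no averaging)
.revcomp_model <- function(model) {
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  new_motif_model(counts = rc(model$counts), theta = rc(model$theta),
                  background = rev(model$background),
                  pseudocount = model$pseudocount,
                  n_support = model$n_support)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, %d supporting site(s), pseudocount %s\n",
              x$width, x$n_support, format(x$pseudocount)))
  cons <- paste(c("A", "C", "G", "T")[apply(x$theta, 2L, which.max)],
                collapse = "")
  cat("  consensus:", cons, "\n")
  invisible(x)
}

#' Scoring configuration
#'
#' Bundles the parameters that define the fitness landscape: the information
#' content weight, pseudocount, background model, and whether reverse
#' complement windows participate in scanning.
#'
#' @inheritParams motif_fitness
#' @param revcomp Score/scan reverse-complement windows as well (minus
#'   strand).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(weight_v = 0.8, pseudocount = 1,
                           background = "empirical", revcomp = FALSE) {
  stopifnot(weight_v >= 0, weight_v <= 1, pseudocount >= 0)
  structure(list(weight_v = weight_v, pseudocount = pseudocount,
                 background = background, revcomp = revcomp),
            class = "scoring_config")
}
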