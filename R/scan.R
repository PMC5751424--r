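#' Score every window of a dataset under a motif model
#'
#' Computes the log-odds score of each valid (N-free) width-`w` window, at
#' every offset `0 .. L_i - w` of every sequence (stride-1 sliding windows).
#' With `revcomp = TRUE` each window is additionally scored under the
#' reverse-complemented model and reported on the minus strand.
#'
#' @param seqs A sequence set.
#' @param model A `motif_model`.
#' @param revcomp Also score the minus strand.
#' @return A data frame with columns `seq_index`, `seq_id`, `offset`
#'   (0-based), `strand` and `score`; one row per valid window (sequences
#'   shorter than the motif contribute none, with a warning).
#' @export
score_all_windows <- function(seqs, model, revcomp = FALSE) {
  seqs <- as_seq_set(seqs)
  stopifnot(inherits(model, "motif_model"))
  w <- model$width
  es <- .encode_set(seqs)
  if (any(es$lens < w)) {
    warning("sequence(s) shorter than the motif yield no windows: ",
            paste(es$ids[es$lens < w], collapse = ", "))
  }
  lo <- log2(model$theta) - log2(model$background)
  los <- list(`+` = lo)
  if (revcomp) {
    mrc <- .revcomp_model(model)
    los$`-` <- log2(mrc$theta) - log2(mrc$background)
  }
  out <- vector("list", length(los) * es$n)
  k <- 0L
  for (strand in names(los)) {
    for (i in seq_len(es$n)) {
      if (es$lens[i] < w) next
      v <- es$lens[i] - w + 1L
      s <- numeric(v)
      enc_i <- es$enc[[i]]
      lom <- los[[strand]]
      for (j in seq_len(w)) s <- s + lom[, j][enc_i[j:(j + v - 1L)]]
      ok <- which(!is.na(s))
      if (!length(ok)) next
      k <- k + 1L
      out[[k]] <- data.frame(seq_index = i, seq_id = es$ids[i],
                             offset = ok - 1L, strand = strand,
                             score = s[ok], stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(seq_index = integer(), seq_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Fit the Gaussian null model for window scores
#'
#' The scanner assumes window scores are approximately Gaussian.  With
#' `source = "empirical"` (default) the mean and standard deviation
#' (denominator `n - 1`) are estimated from the observed window-score
#' population; `source = "analytic"` instead derives them from the model:
#' per-column mean and variance of the log-odds score under the background
#' distribution, summed across columns (windows are independent columns
#' under the null).
#'
#' @param scores Numeric vector of raw window scores (empirical source), or
#'   a data frame from [score_all_windows()].
#' @param source `"empirical"` or `"analytic"`.
#' @param model Required when `source = "analytic"`.
#' @return A `scan_model` list: `mu`, `sigma`, `source`.
#' @export
fit_scan_model <- function(scores, source = c("empirical", "analytic"),
                           model = NULL) {
  source <- match.arg(source)
  if (source == "analytic") {
    stopifnot(inherits(model, "motif_model"))
    lo <- log2(model$theta) - log2(model$background)
    bg <- model$background
    mu_j <- colSums(bg * lo)
    var_j <- colSums(bg * lo^2) - mu_j^2
    return(structure(list(mu = sum(mu_j), sigma = sqrt(sum(var_j)),
                          source = "analytic"), class = "scan_model"))
  }
  if (is.data.frame(scores)) scores <- scores$score
  scores <- as.numeric(scores)
  if (length(unique(scores)) < 2L) {
    stop("need at least 2 distinct window scores to estimate the score ",
         "distribution; the model may be degenerate (try a larger dataset ",
         "or pseudocount)", call. = FALSE)
  }
  structure(list(mu = mean(scores), sigma = stats::sd(scores),
                 source = "empirical"), class = "scan_model")
}

#' z-score and upper-tail p-value of raw window scores
#'
#' Standardizes `x` by the scan model (`z = (x - mu) / sigma`) and converts
#' to the upper-tail Gaussian probability `p = 1 - Phi(z)`: small p-values
#' flag windows scoring far above the bulk of the score distribution.
#'
#' @param x Numeric vector of raw scores.
#' @param sm A `scan_model` from [fit_scan_model()].
#' @return A data frame with columns `z` and `p`.
#' @export
site_pvalue <- function(x, sm) {
  stopifnot(inherits(sm, "scan_model"), sm$sigma > 0)
  z <- (x - sm$mu) / sm$sigma
  data.frame(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Call motif occurrences by significance scanning
#'
#' Scores every window ([score_all_windows()]), standardizes against the
#' scan model, and reports windows with upper-tail p-value at most `alpha`
#' (default `1e-4`).  By default overlapping calls within a sequence are
#' greedily pruned, keeping the most significant of any overlapping set.  No
#' multiple-testing correction is applied; `alpha` is a per-window
#' threshold.
#'
#' @inheritParams score_all_windows
#' @param sm A `scan_model`; fitted empirically from the scores if `NULL`.
#' @param alpha Per-window significance level in `(0, 1]`.
#' @param prune_overlaps Greedily keep only the best of overlapping calls.
#' @return A site table ([site_table()]) sorted by sequence and offset.
#' @export
call_sites <- function(seqs, model, sm = NULL, alpha = 1e-4,
                       revcomp = FALSE, prune_overlaps = TRUE) {
  stopifnot(alpha > 0, alpha <= 1)
  seqs <- as_seq_set(seqs)
  scores <- score_all_windows(seqs, model, revcomp = revcomp)
  if (!nrow(scores)) {
    return(site_table(width = model$width))
  }
  if (is.null(sm)) sm <- fit_scan_model(scores$score)
  zp <- site_pvalue(scores$score, sm)
  hits <- cbind(scores, zp)[zp$p <= alpha, , drop = FALSE]
  w <- model$width
  if (prune_overlaps && nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    for (id in unique(hits$seq_id)) {
      rows <- which(hits$seq_id == id)
      rows <- rows[order(hits$p[rows], hits$offset[rows])]
      taken_start <- integer(0)
      for (r in rows) {
        o <- hits$offset[r]
        if (!length(taken_start) || all(abs(taken_start - o) >= w)) {
          keep[r] <- TRUE
          taken_start <- c(taken_start, o)
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$seq_index, hits$offset), , drop = FALSE]
  site_table(seq_id = hits$seq_id, start = hits$offset, width = w,
             strand = hits$strand, score = hits$score, p_value = hits$p)
}
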