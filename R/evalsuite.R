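#' Match predicted against annotated start positions with a tolerance window
#'
#' A predicted start on a sequence matches an annotated start on the same
#' sequence if they differ by at most `tolerance` positions (default 2, so
#' for an annotated position 60 exactly the predictions 58..62 count as
#' correct).  Matching is one-to-one and greedy in ascending distance, so one
#' annotation can absorb at most one prediction.  Unmatched predictions are
#' false positives (including predictions on sequences absent from the
#' annotation, with a warning); unmatched annotations are false negatives.
#'
#' @param predicted,annotated Site tables ([site_table()]); only `seq_id`
#'   and `start` are used.
#' @param tolerance Maximum absolute start-position deviation (>= 0).
#' @return An `eval_result` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`.
#' @export
match_positions <- function(predicted, annotated, tolerance = 2L) {
  stopifnot(tolerance >= 0L)
  pred_extra <- setdiff(unique(predicted$seq_id), unique(annotated$seq_id))
  if (length(pred_extra)) {
    warning("predictions on sequence(s) absent from the annotation ",
            "(counted as false positives): ",
            paste(pred_extra, collapse = ", "))
  }
  tp <- 0L
  for (id in unique(c(predicted$seq_id, annotated$seq_id))) {
    p <- predicted$start[predicted$seq_id == id]
    a <- annotated$start[annotated$seq_id == id]
    if (!length(p) || !length(a)) next
    pairs <- expand.grid(pi = seq_along(p), ai = seq_along(a))
    pairs$d <- abs(p[pairs$pi] - a[pairs$ai])
    pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$pi, pairs$ai), , drop = FALSE]
    used_p <- logical(length(p))
    used_a <- logical(length(a))
    for (r in seq_len(nrow(pairs))) {
      if (!used_p[pairs$pi[r]] && !used_a[pairs$ai[r]]) {
        used_p[pairs$pi[r]] <- TRUE
        used_a[pairs$ai[r]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(predicted) - tp
  fn <- nrow(annotated) - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, fscore = fscore),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  fn %d | precision %.3f  recall %.3f  f-score %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Summarize repeated evaluation runs
#'
#' Per-metric sample mean and standard deviation (denominator `n - 1`) over
#' a list of evaluation results, the usual report for repeated stochastic
#' runs on one dataset.  A single run reports sd 0 with `n = 1` flagging
#' that the deviation is undefined.
#'
#' @param results List of `eval_result` objects ([match_positions()]).
#' @return Data frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
summarize_runs <- function(results) {
  stopifnot(length(results) >= 1L)
  metrics <- c("precision", "recall", "fscore")
  vals <- vapply(results, function(r) unlist(r[metrics]), numeric(3L))
  vals <- matrix(vals, nrow = 3L, dimnames = list(metrics, NULL))
  n <- length(results)
  data.frame(metric = metrics,
             mean = apply(vals, 1L, mean),
             sd = if (n > 1L) apply(vals, 1L, stats::sd) else rep(0, 3L),
             n = n, row.names = NULL)
}

#' Pairwise dominance ranking of predictors by f-score
#'
#' For every ordered pair of predictors and every dataset, the predictor
#' with the strictly greater f-score takes one win and the other one loss;
#' ties contribute nothing.  The rank score is `wins - losses`, which sums
#' to zero over predictors.
#'
#' @param fscores Numeric matrix, rows = predictors (rownames required),
#'   columns = datasets; no missing cells.
#' @return Data frame with columns `predictor`, `wins`, `losses`, `total`,
#'   sorted by `total` descending.
#' @export
dominance_rank <- function(fscores) {
  fscores <- as.matrix(fscores)
  if (anyNA(fscores)) stop("missing f-score cells", call. = FALSE)
  if (nrow(fscores) < 2L) stop("need at least 2 predictors", call. = FALSE)
  if (is.null(rownames(fscores))) {
    rownames(fscores) <- paste0("predictor", seq_len(nrow(fscores)))
  }
  np <- nrow(fscores)
  wins <- losses <- integer(np)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j) next
      wins[i] <- wins[i] + sum(fscores[i, ] > fscores[j, ])
      losses[i] <- losses[i] + sum(fscores[i, ] < fscores[j, ])
    }
  }
  out <- data.frame(predictor = rownames(fscores), wins = wins,
                    losses = losses, total = wins - losses)
  out[order(-out$total, out$predictor), , drop = FALSE]
}

#' Compare two predictors' repeated f-scores by hypothesis test
#'
#' Optional statistical report: tests paired f-score samples for a location
#' difference.  Normality of the paired differences is checked with a
#' Shapiro-Wilk test; if not rejected at `alpha`, a paired t test is used,
#' otherwise a paired Wilcoxon signed-rank test.  Delegates entirely to the
#' standard tests in \pkg{stats}.
#'
#' @param a,b Numeric vectors of f-scores from repeated runs (paired, equal
#'   length).
#' @param alpha Significance level (default 0.05).
#' @return A list: `test` (`"t"` or `"wilcoxon"`), `p_value`,
#'   `significant`, `shapiro_p`.
#' @export
compare_fscores <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- a - b
  shapiro_p <- if (length(unique(d)) > 1L) stats::shapiro.test(d)$p.value else 0
  if (shapiro_p > alpha) {
    ht <- stats::t.test(a, b, paired = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE))
    test <- "wilcoxon"
  }
  list(test = test, p_value = ht$p.value,
       significant = ht$p.value < alpha, shapiro_p = shapiro_p)
}
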