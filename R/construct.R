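#' Number of valid motif start positions in a sequence
#'
#' A width-`w` window can start at offsets `0 .. L - w`, giving
#' `L - w + 1` valid positions (before any masking).
#'
#' @param seq_length Sequence length `L`.
#' @param w Motif width.
#' @return `seq_length - w + 1`.
#' @examples
#' valid_positions(180, 11)  # 170
#' valid_positions(30, 5)    # 26
#' @export
valid_positions <- function(seq_length, w) {
  if (any(w <= 0L)) stop("w must be positive", call. = FALSE)
  if (any(w > seq_length)) {
    stop("motif width exceeds sequence length", call. = FALSE)
  }
  as.integer(seq_length - w + 1L)
}

#' GRASP construction parameters
#'
#' Controls the semi-greedy construction of the initial population.  At each
#' level a uniform draw `n` decides between a greedy step (`n <= q`: take the
#' best-scoring position, branching on ties) and a randomized step (rank the
#' candidates, keep the top `rcl_size` in a restricted candidate list, pick
#' one uniformly).  `q = 1` is fully greedy; `q = 0` with `rcl_size` equal to
#' the number of valid positions is fully random.
#'
#' @param q Probability of a greedy step, in `[0, 1]` (default 0.9).
#' @param rcl_size Restricted-candidate-list size (default 5).
#' @param tie_epsilon Scores within `tie_epsilon` of the best are treated as
#'   tied in a greedy step.  `NULL` (default) uses a relative band of 10% of
#'   the magnitude of the best score; `0` requires exact ties.
#' @param max_branches Cap on retained tied branches per tree (default 5).
#' @return A `grasp_config` list.
#' @export
grasp_config <- function(q = 0.9, rcl_size = 5L, tie_epsilon = NULL,
                         max_branches = 5L) {
  stopifnot(q >= 0, q <= 1, rcl_size >= 1L, max_branches >= 1L)
  if (!is.null(tie_epsilon)) stopifnot(tie_epsilon >= 0)
  structure(list(q = q, rcl_size = as.integer(rcl_size),
                 tie_epsilon = tie_epsilon,
                 max_branches = as.integer(max_branches)),
            class = "grasp_config")
}

#' Grow one GRASP solution tree from a root start position
#'
#' The root fixes the motif start in the first sequence; levels `2..N` choose
#' a start in each subsequent sequence.  Candidate positions at a level are
#' scored by their window log-odds under the model built (with the configured
#' pseudocount and background) from the `w`-mers on the best root-to-frontier
#' path so far.  Greedy steps branch on ties (scores within the tie band);
#' randomized steps extend every retained path with one uniformly chosen
#' member of the restricted candidate list.  The frontier is capped at
#' `cfg$max_branches` paths, keeping the best cumulative construction scores.
#'
#' Uses the session RNG; seed upstream (e.g. in
#' [build_initial_population()] or [run_discovery()]) for reproducibility.
#'
#' @param seqs A sequence set (at least 2 sequences).
#' @param root_start 0-based valid start offset in the first sequence.
#' @param w Motif width.
#' @param cfg A [grasp_config()].
#' @param scoring A [scoring_config()].
#' @return A `solution_tree`: retained root-to-leaf paths (`paths`, a list of
#'   0-based start vectors), their cumulative construction scores (`scores`),
#'   and `failed = TRUE` if some level had no valid position.
#' @export
grow_tree <- function(seqs, root_start, w, cfg = grasp_config(),
                      scoring = scoring_config()) {
  ev <- .make_evaluator(as_seq_set(seqs), w, weight_v = scoring$weight_v,
                        pseudocount = scoring$pseudocount,
                        background = scoring$background)
  .grow_tree_ev(ev, as.integer(root_start), cfg)
}

.grow_tree_ev <- function(ev, root_start, cfg) {
  n <- ev$n
  w <- ev$w
  if (n < 2L) stop("need at least 2 sequences to grow a tree", call. = FALSE)
  if (root_start < 0L || root_start > ev$es$lens[1L] - w ||
      !ev$valid[[1L]][root_start + 1L]) {
    stop("root_start is not a valid start in sequence 1", call. = FALSE)
  }
  paths <- matrix(root_start, nrow = 1L)  # rows = paths, cols = levels so far
  cum <- 0
  for (lev in 2L:n) {
    best <- .lex_best(paths, cum)
    lo <- ev$logodds_from_words(.path_words(ev, paths[best, ]))
    s <- ev$scan_scores(lo, lev)
    s[!ev$valid[[lev]]] <- NA_real_
    cand <- which(!is.na(s))  # 1-based offsets
    if (!length(cand)) {
      return(structure(list(paths = .rows_as_list(paths), scores = cum,
                            n_seq = n, width = w, failed = TRUE,
                            failed_level = lev),
                       class = "solution_tree"))
    }
    if (stats::runif(1L) <= cfg$q) {
      smax <- max(s, na.rm = TRUE)
      eps <- if (is.null(cfg$tie_epsilon)) 0.1 * abs(smax) else cfg$tie_epsilon
      tied <- cand[s[cand] >= smax - eps]
      tied <- tied[order(-s[tied], tied)]
      if (length(tied) > cfg$max_branches) tied <- tied[seq_len(cfg$max_branches)]
      # extend every path with every tied offset, then cap the frontier
      k <- length(tied)
      newp <- cbind(paths[rep(seq_len(nrow(paths)), each = k), , drop = FALSE],
                    rep(tied - 1L, times = nrow(paths)))
      newc <- rep(cum, each = k) + rep(s[tied], times = length(cum))
      if (nrow(newp) > cfg$max_branches) {
        keep <- .top_paths(newp, newc, cfg$max_branches)
        newp <- newp[keep, , drop = FALSE]
        newc <- newc[keep]
      }
      paths <- newp
      cum <- newc
    } else {
      rcl <- cand[order(-s[cand], cand)]
      rcl <- rcl[seq_len(min(cfg$rcl_size, length(rcl)))]
      pick <- rcl[sample.int(length(rcl), 1L)]
      paths <- cbind(paths, pick - 1L)
      cum <- cum + s[pick]
    }
  }
  structure(list(paths = .rows_as_list(paths), scores = cum, n_seq = n,
                 width = w, failed = FALSE),
            class = "solution_tree")
}

.path_words <- function(ev, starts) {
  k <- length(starts)
  idx <- rep.int(ev$es$offs[seq_len(k)] + starts, rep.int(ev$w, k)) +
    rep.int(seq_len(ev$w), k)
  matrix(ev$es$flat[idx], nrow = ev$w)
}

.rows_as_list <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

# index of the best-scoring row; ties to lexicographically smallest starts
.lex_best <- function(paths, cum) {
  top <- which(cum == max(cum))
  if (length(top) == 1L) return(top)
  ord <- do.call(order, c(as.data.frame(paths[top, , drop = FALSE]),
                          list(method = "radix")))
  top[ord[1L]]
}

.top_paths <- function(paths, cum, k) {
  ord <- do.call(order, c(list(-cum), as.data.frame(paths),
                          list(method = "radix")))
  ord[seq_len(k)]
}

#' Extract the best root-to-leaf path of a solution tree
#'
#' Returns the retained path with the maximum summed construction score,
#' breaking ties toward the lexicographically smallest start offsets.
#'
#' @param tree A `solution_tree` from [grow_tree()].
#' @return Integer vector of 0-based start offsets, one per sequence, with
#'   the construction score as attribute `"construction_score"`.
#' @export
best_path <- function(tree) {
  stopifnot(inherits(tree, "solution_tree"))
  if (isTRUE(tree$failed)) {
    stop("tree construction failed at level ", tree$failed_level,
         call. = FALSE)
  }
  m <- do.call(rbind, tree$paths)
  b <- .lex_best(m, tree$scores)
  structure(as.integer(m[b, ]), construction_score = tree$scores[b])
}

#' Build the GRASP initial population
#'
#' Grows one solution tree per valid (unmasked, N-free) start position of the
#' first sequence — optionally subsampled uniformly to `max_pop` roots — and
#' extracts each tree's best path as one individual.  Individuals carry their
#' fitness ([motif_fitness()]) as attribute `"fitness"`.  Trees whose
#' construction fails (a level with no valid position) are dropped with a
#' message; it is an error for all constructions to fail.
#'
#' @inheritParams grow_tree
#' @param max_pop Optional cap on the number of roots attempted.
#' @param seed Optional RNG seed for reproducible construction.
#' @return List of individuals (integer start vectors with attributes
#'   `"fitness"` and `"construction_score"`).
#' @export
build_initial_population <- function(seqs, w, cfg = grasp_config(),
                                     scoring = scoring_config(),
                                     max_pop = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- .make_evaluator(as_seq_set(seqs), w, weight_v = scoring$weight_v,
                        pseudocount = scoring$pseudocount,
                        background = scoring$background)
  .initial_population_ev(ev, cfg, max_pop)
}

.initial_population_ev <- function(ev, cfg, max_pop = NULL) {
  roots <- which(ev$valid[[1L]]) - 1L
  if (!length(roots)) stop("no valid root positions in sequence 1",
                           call. = FALSE)
  if (!is.null(max_pop) && length(roots) > max_pop) {
    roots <- sort(sample(roots, max_pop))
  }
  pop <- vector("list", length(roots))
  ok <- logical(length(roots))
  for (r in seq_along(roots)) {
    tree <- .grow_tree_ev(ev, roots[r], cfg)
    if (isTRUE(tree$failed)) next
    ind <- best_path(tree)
    attr(ind, "fitness") <- ev$breakdown(as.integer(ind))
    pop[[r]] <- ind
    ok[r] <- TRUE
  }
  if (!any(ok)) stop("construction failed for every root", call. = FALSE)
  if (!all(ok)) {
    message(sum(!ok), " of ", length(roots), " tree constructions failed")
  }
  pop[ok]
}
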