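#' Evolutionary loop parameters
#'
#' @param generations Maximum number of generations (default 100).
#' @param crossover_rate Fraction of the population recombined each
#'   generation (default 0.8).
#' @param vns_max_neighborhood Largest VNS neighborhood index `k_max`
#'   (default 3): neighborhood `k` shakes `k` coordinates by shifts up to
#'   `k`.
#' @param vns_max_iters Maximum shake/descent cycles per VNS call
#'   (default 10).
#' @param stall_generations Stop early after this many generations without
#'   improvement of the best fitness (default 20).
#' @param pop_size Population cap; defaults to `min(v1, 200)` where `v1` is
#'   the number of valid roots in sequence 1.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(generations = 100L, crossover_rate = 0.8,
                             vns_max_neighborhood = 3L, vns_max_iters = 10L,
                             stall_generations = 20L, pop_size = 200L) {
  stopifnot(generations >= 0L, crossover_rate >= 0, crossover_rate <= 1,
            vns_max_neighborhood >= 1L, vns_max_iters >= 1L,
            stall_generations >= 1L, pop_size >= 2L)
  structure(list(generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 vns_max_neighborhood = as.integer(vns_max_neighborhood),
                 vns_max_iters = as.integer(vns_max_iters),
                 stall_generations = as.integer(stall_generations),
                 pop_size = as.integer(pop_size)),
            class = "evolution_config")
}

#' Uniform crossover of two start-position individuals
#'
#' Each coordinate of child 1 is drawn from one parent uniformly at random;
#' child 2 takes the complementary choice, so
#' `{c1[i], c2[i]} = {p1[i], p2[i]}` at every coordinate.
#'
#' @param p1,p2 Integer start vectors over the same dataset and width.
#' @return `list(c1, c2)` of integer start vectors (fitness not attached).
#' @export
recombine <- function(p1, p2) {
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  stopifnot(length(p1) == length(p2))
  take1 <- stats::runif(length(p1)) < 0.5
  list(ifelse(take1, p1, p2), ifelse(take1, p2, p1))
}

#' Variable neighborhood search on one individual
#'
#' Shift-based VNS for start-position encodings.  Neighborhood `k` "shakes"
#' `k` randomly chosen coordinates by a uniform shift in `±(1..k)` (clamped
#' to valid, unmasked starts), then runs best-improvement local search over
#' single-coordinate `±1` shifts until no move improves the fitness.  On
#' improvement the neighborhood resets to `k = 1`, otherwise it grows; the
#' search stops past `vns_max_neighborhood` or after `vns_max_iters` cycles.
#' The returned individual never has lower fitness than the input.
#'
#' @param x Integer start vector (0-based).
#' @param seqs,w,scoring Dataset, motif width and [scoring_config()].
#' @param cfg An [evolution_config()] (VNS fields are used).
#' @return The improved start vector with attribute `"fitness"`.
#' @export
vns_search <- function(x, seqs, w, scoring = scoring_config(),
                       cfg = evolution_config()) {
  ev <- .make_evaluator(as_seq_set(seqs), w, weight_v = scoring$weight_v,
                        pseudocount = scoring$pseudocount,
                        background = scoring$background)
  x <- as.integer(x)
  out <- .vns_ev(ev, x, ev$fit(x), cfg)
  res <- out$starts
  attr(res, "fitness") <- ev$breakdown(res)
  res
}

.vns_ev <- function(ev, starts, fi, cfg) {
  best <- starts
  best_fi <- fi
  ls <- .local_search_ev(ev, best, best_fi)
  if (ls$fi > best_fi) { best <- ls$starts; best_fi <- ls$fi }
  k <- 1L
  iters <- 0L
  while (k <= cfg$vns_max_neighborhood && iters < cfg$vns_max_iters) {
    iters <- iters + 1L
    cand <- .shake_ev(ev, best, k)
    ls <- .local_search_ev(ev, cand, ev$fit(cand))
    if (ls$fi > best_fi + 1e-12) {
      best <- ls$starts
      best_fi <- ls$fi
      k <- 1L
    } else {
      k <- k + 1L
    }
  }
  list(starts = best, fi = best_fi)
}

# perturb k random coordinates by a shift in ±(1..k); invalid landings keep
# the original coordinate
.shake_ev <- function(ev, starts, k) {
  n <- ev$n
  coords <- sample.int(n, min(k, n))
  for (i in coords) {
    shift <- sample(c(-seq_len(k), seq_len(k)), 1L)
    cand <- starts[i] + shift
    vmax <- ev$es$lens[i] - ev$w
    if (cand >= 0L && cand <= vmax && ev$valid[[i]][cand + 1L]) {
      starts[i] <- cand
    }
  }
  starts
}

# best-improvement descent over single-coordinate ±1 shifts
.local_search_ev <- function(ev, starts, fi, max_sweeps = 100L) {
  n <- ev$n
  for (sweep in seq_len(max_sweeps)) {
    best_delta <- 0
    best_move <- NULL
    for (i in seq_len(n)) {
      vmax <- ev$es$lens[i] - ev$w
      for (d in c(-1L, 1L)) {
        cand <- starts[i] + d
        if (cand < 0L || cand > vmax || !ev$valid[[i]][cand + 1L]) next
        trial <- starts
        trial[i] <- cand
        f <- ev$fit(trial)
        if (f - fi > best_delta + 1e-12) {
          best_delta <- f - fi
          best_move <- trial
          best_f <- f
        }
      }
    }
    if (is.null(best_move)) break
    starts <- best_move
    fi <- best_f
  }
  list(starts = starts, fi = fi)
}

#' Conditional VNS mutation of a pair of children
#'
#' Let `p* = max(F(p1), F(p2))`.  A child whose fitness is below `p*` is
#' replaced by [vns_search()] applied to it; a child at least as fit as `p*`
#' passes through untouched.
#'
#' @param c1,c2 Child start vectors (from [recombine()]).
#' @param p1,p2 Parent start vectors.
#' @inheritParams vns_search
#' @return `list(c1, c2)` after conditional mutation, each with attribute
#'   `"fitness"`.
#' @export
mutate_children <- function(c1, c2, p1, p2, seqs, w,
                            scoring = scoring_config(),
                            cfg = evolution_config()) {
  ev <- .make_evaluator(as_seq_set(seqs), w, weight_v = scoring$weight_v,
                        pseudocount = scoring$pseudocount,
                        background = scoring$background)
  p_star <- max(ev$fit(as.integer(p1)), ev$fit(as.integer(p2)))
  out <- lapply(list(as.integer(c1), as.integer(c2)), function(ch) {
    fi <- ev$fit(ch)
    if (fi < p_star) {
      res <- .vns_ev(ev, ch, fi, cfg)
      ch <- res$starts
    }
    attr(ch, "fitness") <- ev$breakdown(ch)
    ch
  })
  out
}

#' Elitist selection over the union of parent and child populations
#'
#' Joins `P` and `Q`, stable-sorts by fitness (descending; ties keep
#' insertion order, parents before children), and truncates to `|P|`.
#'
#' @param P,Q Lists of individuals carrying attribute `"fitness"` (a
#'   [motif_fitness()] breakdown) or, for plain vectors, `fitnesses` must be
#'   supplied.
#' @param fitnesses Optional numeric vector of fitness values for
#'   `c(P, Q)`, overriding the attributes.
#' @return The next population: a list of `length(P)` individuals, sorted by
#'   fitness descending.
#' @export
select_next <- function(P, Q, fitnesses = NULL) {
  R <- c(P, Q)
  if (is.null(fitnesses)) {
    fitnesses <- vapply(R, function(x) attr(x, "fitness")$fi, numeric(1L))
  }
  stopifnot(length(fitnesses) == length(R))
  ord <- order(-fitnesses, seq_along(R), method = "radix")
  R[ord[seq_len(min(length(P), length(R)))]]
}

#' Run the full memetic motif discovery
#'
#' The complete pattern-discovery loop: GRASP initial population
#' ([build_initial_population()]), then per generation a random non-self
#' pairing of a `crossover_rate` fraction of the population, uniform
#' crossover ([recombine()]), conditional VNS mutation of the children
#' against the better parent, and elitist truncation selection over parents
#' plus children.  Stops after `generations` generations or once the best
#' fitness has stalled for `stall_generations`.  Elitism guarantees the
#' best-fitness history is non-decreasing.
#'
#' @param seqs A sequence set (at least 2 sequences).
#' @param w Motif width.
#' @param grasp_cfg A [grasp_config()].
#' @param evo_cfg An [evolution_config()].
#' @param scoring A [scoring_config()].
#' @param max_pop Cap on constructed roots; defaults to
#'   `evo_cfg$pop_size`.
#' @param seed Optional RNG seed; fixes the whole run.
#' @return A `motif_discovery` list: `best` (start vector with attribute
#'   `"fitness"`), `model` (the [build_model()] of the best alignment),
#'   `history` (data frame: generation, best_fi, mean_fi) and `width`.
#' @export
run_discovery <- function(seqs, w, grasp_cfg = grasp_config(),
                          evo_cfg = evolution_config(),
                          scoring = scoring_config(), max_pop = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- as_seq_set(seqs)
  if (length(seqs) < 2L) {
    stop("motif discovery needs at least 2 sequences", call. = FALSE)
  }
  ev <- .make_evaluator(seqs, w, weight_v = scoring$weight_v,
                        pseudocount = scoring$pseudocount,
                        background = scoring$background)
  if (is.null(max_pop)) max_pop <- evo_cfg$pop_size
  pop <- .initial_population_ev(ev, grasp_cfg, max_pop = max_pop)
  fis <- vapply(pop, function(x) attr(x, "fitness")$fi, numeric(1L))

  best_i <- which.max(fis)
  best_ever <- pop[[best_i]]
  best_fi <- fis[best_i]
  history <- data.frame(generation = 0L, best_fi = best_fi,
                        mean_fi = mean(fis))
  stall <- 0L
  npop <- length(pop)
  gen <- 0L
  while (gen < evo_cfg$generations && stall < evo_cfg$stall_generations) {
    gen <- gen + 1L
    Q <- list()
    qfi <- numeric(0)
    n_cross <- floor(evo_cfg$crossover_rate * npop / 2) * 2
    if (n_cross >= 2L && npop >= 2L) {
      picked <- sample.int(npop, n_cross)
      for (p in seq_len(n_cross / 2L)) {
        i1 <- picked[2L * p - 1L]
        i2 <- picked[2L * p]
        ch <- .recombine_int(pop[[i1]], pop[[i2]])
        p_star <- max(fis[i1], fis[i2])
        for (ch1 in ch) {
          f <- ev$fit(ch1)
          if (f < p_star) {
            res <- .vns_ev(ev, ch1, f, evo_cfg)
            ch1 <- res$starts
            f <- res$fi
          }
          Q[[length(Q) + 1L]] <- ch1
          qfi <- c(qfi, f)
        }
      }
    }
    allfi <- c(fis, qfi)
    ord <- order(-allfi, seq_along(allfi), method = "radix")[seq_len(npop)]
    pop <- c(pop, Q)[ord]
    fis <- allfi[ord]
    if (fis[1L] > best_fi + 1e-12) {
      best_fi <- fis[1L]
      best_ever <- pop[[1L]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history <- rbind(history,
                     data.frame(generation = gen, best_fi = best_fi,
                                mean_fi = mean(fis)))
  }
  best <- as.integer(best_ever)
  attr(best, "fitness") <- ev$breakdown(best)
  structure(list(best = best, model = ev$model_of(best), history = history,
                 width = as.integer(w)),
            class = "motif_discovery")
}

.recombine_int <- function(p1, p2) {
  take1 <- stats::runif(length(p1)) < 0.5
  list(as.integer(ifelse(take1, p1, p2)),
       as.integer(ifelse(take1, p2, p1)))
}

#' @export
print.motif_discovery <- function(x, ...) {
  fb <- attr(x$best, "fitness")
  cat(sprintf("<motif_discovery> width %d, best fitness %.4f after %d generation(s)\n",
              x$width, fb$fi, max(x$history$generation)))
  print(x$model)
  invisible(x)
}
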