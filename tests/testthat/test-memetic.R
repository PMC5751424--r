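test_that("uniform crossover children stay inside the parental coordinates", {
  set.seed(1)
  p1 <- c(3L, 7L, 1L, 9L)
  p2 <- c(5L, 2L, 8L, 0L)
  for (i in 1:20) {
    ch <- recombine(p1, p2)
    for (j in seq_along(p1)) {
      expect_setequal(c(ch[[1]][j], ch[[2]][j]), c(p1[j], p2[j]))
    }
  }
  # identical parents reproduce themselves
  same <- recombine(p1, p1)
  expect_identical(same[[1]], p1)
  expect_identical(same[[2]], p1)
  # single-coordinate individuals: children are copies of the parents
  one <- recombine(4L, 6L)
  expect_setequal(c(one[[1]], one[[2]]), c(4L, 6L))
})

test_that("VNS never degrades fitness and repairs a displaced coordinate", {
  sim <- generate_planted(n_sequences = 6, length = 40, width = 6,
                          mutations_per_site = 0, seed = 21)
  scoring <- scoring_config(weight_v = 1, background = "uniform")
  planted <- sim$truth$start
  planted_fi <- motif_fitness(sim$seqs, planted, 6L, weight_v = 1,
                              background = "uniform")$fi

  displaced <- planted
  displaced[3] <- planted[3] + 1L
  set.seed(2)
  repaired <- vns_search(displaced, sim$seqs, 6L, scoring = scoring)
  expect_equal(attr(repaired, "fitness")$fi, planted_fi, tolerance = 1e-9)

  # monotone contract on arbitrary inputs and seeds
  for (seed in 1:5) {
    set.seed(seed)
    x <- vapply(seq_lengths(sim$seqs) - 6L,
                function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    f0 <- motif_fitness(sim$seqs, x, 6L, weight_v = 1,
                        background = "uniform")$fi
    out <- vns_search(x, sim$seqs, 6L, scoring = scoring)
    expect_gte(attr(out, "fitness")$fi, f0 - 1e-12)
  }
})

test_that("children are mutated only when worse than the better parent", {
  sim <- generate_planted(n_sequences = 4, length = 30, width = 5,
                          mutations_per_site = 0, seed = 31)
  scoring <- scoring_config(weight_v = 1, background = "uniform")
  planted <- sim$truth$start
  set.seed(3)
  bad <- vapply(seq_lengths(sim$seqs) - 5L,
                function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
  fi <- function(x) motif_fitness(sim$seqs, x, 5L, weight_v = 1,
                                  background = "uniform")$fi
  # child at least as fit as p*: passes through untouched
  out <- mutate_children(planted, bad, bad, bad, sim$seqs, 5L, scoring)
  expect_identical(as.integer(out[[1]]), as.integer(planted))
  # child worse than p*: replaced by a VNS result at least as fit
  expect_gte(attr(out[[2]], "fitness")$fi, fi(bad) - 1e-12)
  out2 <- mutate_children(bad, bad, planted, bad, sim$seqs, 5L, scoring)
  expect_gte(attr(out2[[1]], "fitness")$fi, fi(bad) - 1e-12)
})

test_that("elitist selection equals the naive sort-and-slice oracle", {
  mk <- function(starts, fi) {
    x <- as.integer(starts)
    attr(x, "fitness") <- list(fi = fi)
    x
  }
  P <- list(mk(c(1, 1), 0.5), mk(c(2, 2), 2.0), mk(c(3, 3), 1.0))
  Q <- list(mk(c(4, 4), 3.0), mk(c(5, 5), 0.1), mk(c(6, 6), 2.0))
  nxt <- select_next(P, Q)
  expect_length(nxt, 3L)
  fis <- vapply(nxt, function(x) attr(x, "fitness")$fi, numeric(1))
  expect_identical(fis, c(3.0, 2.0, 2.0))
  # stable: the parent 2.0 precedes the child 2.0
  expect_identical(as.integer(nxt[[2]]), c(2L, 2L))
  expect_identical(as.integer(nxt[[3]]), c(6L, 6L))

  # Q empty: P sorted
  expect_identical(vapply(select_next(P, list()),
                          function(x) attr(x, "fitness")$fi, numeric(1)),
                   c(2.0, 1.0, 0.5))
  # dominant Q displaces P entirely
  Qd <- list(mk(c(7, 7), 10), mk(c(8, 8), 11), mk(c(9, 9), 12))
  expect_true(all(vapply(select_next(P, Qd),
                         function(x) attr(x, "fitness")$fi, numeric(1)) >= 10))
})

test_that("discovery is deterministic under a seed and history never decreases", {
  sim <- generate_planted(n_sequences = 5, length = 40, width = 6,
                          mutations_per_site = 1, seed = 41)
  cfg <- evolution_config(generations = 8, stall_generations = 5)
  d1 <- run_discovery(sim$seqs, 6L, evo_cfg = cfg, seed = 7)
  d2 <- run_discovery(sim$seqs, 6L, evo_cfg = cfg, seed = 7)
  expect_identical(as.integer(d1$best), as.integer(d2$best))
  expect_identical(d1$history, d2$history)
  expect_true(all(diff(d1$history$best_fi) >= -1e-12))

  # generations = 0 returns the best of the initial population
  d0 <- run_discovery(sim$seqs, 6L,
                      evo_cfg = evolution_config(generations = 0),
                      seed = 7)
  pop <- build_initial_population(sim$seqs, 6L, max_pop = 200L, seed = 7)
  best0 <- max(vapply(pop, function(x) attr(x, "fitness")$fi, numeric(1)))
  expect_equal(attr(d0$best, "fitness")$fi, best0, tolerance = 1e-9)
})
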