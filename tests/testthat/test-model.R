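test_that("pseudocount smoothing gives the documented single-site frequencies", {
  s <- as_seq_set(c(a = "GTCTGTGGTTT"))
  m <- build_model(s, 0L, 11L, pseudocount = 1, background = "uniform")
  # one supporting site: present letter (1+1)/(1+4) = 0.4, absent (0+1)/5 = 0.2
  expect_equal(unname(m$theta[, 1]), c(0.2, 0.2, 0.4, 0.2))
  expect_equal(colSums(m$theta), rep(1, 11), tolerance = 1e-9,
               ignore_attr = TRUE)

  # two identical sites, no smoothing: consensus letters get probability 1
  s2 <- as_seq_set(c(a = "ACGT", b = "ACGT"))
  m2 <- build_model(s2, c(0L, 0L), 4L, pseudocount = 0,
                    background = "uniform")
  expect_equal(unname(diag(m2$theta[c(1, 2, 3, 4), ])), rep(1, 4))
  expect_true(any(m2$theta == 0))
})

test_that("build_model rejects out-of-bounds starts and N windows", {
  s <- as_seq_set(c(a = "ACGTNACGT", b = "ACGTACGTA"))
  expect_error(build_model(s, c(6L, 0L), 4L), "out of bounds")
  expect_error(build_model(s, c(2L, 0L), 4L), "contains N")
})

test_that("information content matches a naive double-loop oracle", {
  bg <- c(0.3, 0.2, 0.3, 0.2)
  set.seed(42)
  counts <- matrix(rpois(20, 5), nrow = 4)
  theta <- sweep(counts + 1, 2, colSums(counts + 1), "/")
  m <- memotif:::new_motif_model(counts, theta, bg, 1, 10L)
  expect_equal(information_content(m), oracle_ic(theta, bg),
               tolerance = 1e-12)

  # uniform model over uniform background carries no information
  u <- memotif:::new_motif_model(matrix(1, 4, 5), matrix(0.25, 4, 5),
                                 rep(0.25, 4), 1, 4L)
  expect_equal(information_content(u), 0)

  # an (almost) deterministic column contributes log2(1/0.25) = 2 bits
  d <- memotif:::new_motif_model(matrix(c(4, 0, 0, 0), 4, 1),
                                 matrix(c(1, 1e-300, 1e-300, 1e-300), 4, 1),
                                 rep(0.25, 4), 0, 4L)
  expect_equal(information_content(d), 2, tolerance = 1e-9)

  z <- memotif:::new_motif_model(matrix(0, 4, 1),
                                 matrix(c(1, 0, 0, 0), 4, 1),
                                 rep(0.25, 4), 0, 1L)
  expect_error(information_content(z), "pseudocount")
})

test_that("complexity ratio reproduces the worked homopolymer and mixed words", {
  expect_equal(complexity_ratio("AAAAAA"), 720 / 46656)
  expect_equal(round(complexity_ratio("AAAAAA"), 4), 0.0154)
  expect_equal(complexity_ratio("ATACGT"), 45)
  expect_equal(complexity_ratio("ACGT"), 24)  # all distinct: 4!/1
  expect_error(complexity_ratio(""), "empty")
  expect_error(complexity_ratio("ACGN"), "A/C/G/T")
})

test_that("complexity ratio equals the definitional oracle on random words", {
  set.seed(7)
  for (i in 1:25) {
    word <- random_dna(sample(3:12, 1))
    expect_equal(complexity_ratio(word), oracle_complexity_ratio(word))
  }
})

test_that("complexity ratio is maximal for distinct letters, minimal for homopolymers", {
  for (w in 2:4) {
    distinct <- paste(c("A", "C", "G", "T")[1:w], collapse = "")
    expect_equal(complexity_ratio(distinct), factorial(w))
    homo <- strrep("A", w)
    set.seed(w)
    others <- replicate(20, complexity_ratio(random_dna(w)))
    expect_true(all(others >= complexity_ratio(homo)))
  }
})

test_that("complexity score sums log4 ratios over the selected words", {
  two_a <- as_seq_set(c(a = "AAAAAA", b = "AAAAAA"))
  expect_equal(complexity_score(two_a, c(0L, 0L), 6L),
               2 * log(720 / 46656, base = 4))
  two_m <- as_seq_set(c(a = "ATACGT", b = "ATACGT"))
  expect_equal(complexity_score(two_m, c(0L, 0L), 6L), 2 * log(45, base = 4))
  expect_equal(complexity_score(two_m, integer(0), 6L), 0)
})

test_that("fitness is the stated affine combination and degenerates correctly", {
  s <- example_pair()
  starts <- c(0L, 0L)
  ic <- information_content(build_model(s, starts, 11L,
                                        background = "uniform"))
  cs <- complexity_score(s, starts, 11L)
  for (v in c(0, 0.25, 0.8, 1)) {
    fb <- motif_fitness(s, starts, 11L, weight_v = v,
                        background = "uniform")
    expect_equal(fb$fi, v * ic + (1 - v) * cs, tolerance = 1e-9)
    expect_equal(fb$fi, fb$weight_v * fb$ic + (1 - fb$weight_v) * fb$cs)
  }
  expect_equal(motif_fitness(s, starts, 11L, weight_v = 1,
                             background = "uniform")$fi, ic)
  expect_equal(motif_fitness(s, starts, 11L, weight_v = 0,
                             background = "uniform")$fi, cs)
})

test_that("window scores match the naive oracle and rank the consensus first", {
  set.seed(9)
  counts <- matrix(rpois(16, 3), nrow = 4)
  theta <- sweep(counts + 1, 2, colSums(counts + 1), "/")
  bg <- c(0.2, 0.3, 0.2, 0.3)
  m <- memotif:::new_motif_model(counts, theta, bg, 1, 8L)
  for (i in 1:10) {
    word <- random_dna(4)
    expect_equal(window_score(m, word),
                 oracle_window_score(theta, bg, word))
  }

  # uniform model, uniform background: every word scores 0
  u <- memotif:::new_motif_model(matrix(1, 4, 3), matrix(0.25, 4, 3),
                                 rep(0.25, 4), 1, 4L)
  expect_equal(window_score(u, "ACG"), 0)

  # consensus of a pseudocount-0 single-site model beats all 4^w words
  site <- "GTCA"
  ms <- build_model(as_seq_set(c(a = site)), 0L, 4L, pseudocount = 0,
                    background = "uniform")
  all_words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                     paste, collapse = "")
  scores <- vapply(all_words, function(x) window_score(ms, x), numeric(1))
  expect_identical(names(which.max(scores)), "GTCA")

  expect_error(window_score(ms, "GTC"), "length")
  expect_error(window_score(ms, "GTNA"), "N-free")
})

test_that("reverse-complement symmetrization is an involution fixed point", {
  s <- as_seq_set(c(a = "GTCTGTGGTTT", b = "AATTGGCCATG"))
  m <- build_model(s, c(0L, 0L), 11L)
  sym <- revcomp_symmetrize(m)
  rc <- function(x) x[4:1, rev(seq_len(ncol(x)))]
  expect_equal(sym$theta, rc(sym$theta), ignore_attr = TRUE)
  expect_equal(revcomp_symmetrize(sym)$theta, sym$theta, tolerance = 1e-12)
  expect_equal(colSums(sym$theta), rep(1, 11), tolerance = 1e-9,
               ignore_attr = TRUE)

  # ACGT is its own reverse complement: single-site model already symmetric
  mp <- build_model(as_seq_set(c(a = "ACGT")), 0L, 4L,
                    background = "uniform")
  expect_equal(revcomp_symmetrize(mp)$theta, mp$theta, tolerance = 1e-12)
})
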