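test_that("every valid window is scored, and scores match recomputation", {
  s <- as_seq_set(c(one = random_dna(180, seed = 51)))
  m <- build_model(example_pair(), c(0L, 0L), 11L, background = "uniform")
  sw <- score_all_windows(s, m)
  expect_identical(nrow(sw), 170L)  # L - w + 1 sliding windows
  expect_identical(sw$offset, 0:169)
  # brute-force recomputation of a sample of windows
  for (r in c(1L, 57L, 170L)) {
    word <- substr(unclass(s)[[1]], sw$offset[r] + 1, sw$offset[r] + 11)
    expect_equal(sw$score[r], window_score(m, word), tolerance = 1e-9)
  }

  # windows containing N are skipped; short sequences warn and yield none
  sn <- as_seq_set(c(a = "ACGTNACGTACGTA", b = "ACGTACGTACGTAC"))
  m4 <- build_model(sn["b"], 0L, 4L, background = "uniform")
  sw2 <- score_all_windows(sn, m4)
  expect_identical(sum(sw2$seq_index == 1L), 11L - 4L)  # 4 N windows lost
  expect_warning(score_all_windows(as_seq_set(c(tiny = "ACG", b = "ACGTA")),
                                   m4),
                 "shorter than the motif")
})

test_that("empirical z-scores are standardized and p-values behave", {
  scores <- c(0, 2)
  sm <- fit_scan_model(scores)
  expect_equal(sm$mu, 1)
  expect_equal(sm$sigma, sqrt(2))

  set.seed(13)
  xs <- rnorm(5000, mean = 3, sd = 1.7)
  sm2 <- fit_scan_model(xs)
  zp <- site_pvalue(xs, sm2)
  expect_equal(mean(zp$z), 0, tolerance = 1e-6)
  expect_equal(sd(zp$z), 1, tolerance = 1e-6)
  expect_equal(sm2$mu, 3, tolerance = 3 * 1.7 / sqrt(5000))

  # center of the distribution: z = 0, p = 0.5
  center <- site_pvalue(sm2$mu, sm2)
  expect_equal(center$z, 0)
  expect_equal(center$p, 0.5)
  # the conventional stringent cutoff: z = 3.719 is p ~ 1e-4
  expect_equal(site_pvalue(sm2$mu + 3.719016 * sm2$sigma, sm2)$p, 1e-4,
               tolerance = 1e-4)
  # monotone decreasing in the raw score
  expect_true(all(diff(site_pvalue(sort(xs), sm2)$p) <= 0))

  expect_error(fit_scan_model(rep(1, 10)), "distinct")
})

test_that("the analytic null matches the empirical null on background data", {
  set.seed(23)
  m <- build_model(example_pair(), c(3L, 17L), 8L, background = "uniform")
  bgseq <- as_seq_set(c(bg = random_dna(20000)))
  emp <- fit_scan_model(score_all_windows(bgseq, m)$score)
  ana <- fit_scan_model(NULL, source = "analytic", model = m)
  expect_equal(ana$mu, emp$mu, tolerance = 0.05 * abs(emp$mu) + 0.05)
  expect_equal(ana$sigma, emp$sigma, tolerance = 0.05 * emp$sigma)
})

test_that("alpha = 1 reports every valid window before pruning", {
  s <- as_seq_set(c(a = random_dna(60, seed = 61),
                    b = random_dna(60, seed = 62)))
  m <- build_model(s, c(0L, 0L), 6L, background = "uniform")
  sites <- call_sites(s, m, alpha = 1, prune_overlaps = FALSE)
  expect_identical(nrow(sites), 2L * (60L - 6L + 1L))
  # a vanishing alpha calls nothing
  expect_identical(nrow(call_sites(s, m, alpha = 1e-300)), 0L)
})

test_that("site calls are invariant under affine raw-score transforms", {
  s <- as_seq_set(c(a = random_dna(120, seed = 71),
                    b = random_dna(120, seed = 72)))
  m <- build_model(s, c(5L, 9L), 7L, background = "uniform")
  sw <- score_all_windows(s, m)
  sm <- fit_scan_model(sw$score)
  zp <- site_pvalue(sw$score, sm)
  affine <- 3.7 * sw$score - 11.2
  sm_a <- fit_scan_model(affine)
  zp_a <- site_pvalue(affine, sm_a)
  expect_equal(zp_a$z, zp$z, tolerance = 1e-9)
  expect_equal(zp_a$p, zp$p, tolerance = 1e-12)
})

test_that("two planted instances per sequence are both recovered", {
  sim <- generate_planted(n_sequences = 10, length = 300, width = 8,
                          mutations_per_site = 0,
                          instances_per_sequence = 2, seed = 81)
  # model estimated from one instance per sequence; scanning must still
  # recover the second occurrence in each
  model <- build_model(sim$seqs, sim$truth$start[seq(1, 20, by = 2)], 8L)
  sites <- call_sites(sim$seqs, model, alpha = 1e-4)
  per_seq <- table(sites$seq_id)
  expect_gte(mean(per_seq >= 2), 0.8)
  r <- match_positions(sites, sim$truth, tolerance = 2)
  expect_gte(r$recall, 0.8)
})

test_that("minus-strand scanning scores the reverse complement model", {
  s <- as_seq_set(c(a = "AAATCCCCAAAAA"))
  m <- build_model(as_seq_set(c(x = "GGGGA")), 0L, 5L,
                   background = "uniform")
  sw <- score_all_windows(s, m, revcomp = TRUE)
  minus <- sw[sw$strand == "-", ]
  # TCCCC at offset 3 is the reverse complement of the model consensus
  best <- minus[which.max(minus$score), ]
  expect_identical(best$offset, 3L)
})
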