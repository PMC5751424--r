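# Shared fixtures and independent oracles, built in code.

# Two 180-nt promoter-like sequences whose first 11-mers share the pattern
# GTCTGTGG... ; used as the standard worked example throughout the tests.
example_pair <- function() {
  s1 <- paste0("GTCTGTGGTTTtttccgtaaacccaacacaaacaaaccctccgcc",
               "gtgaaacggtggcccccgatcaagtggggtctatgaagttatgtg",
               "agcggagcgtaatatagcgtatacaactagatcaccttgtgcagt",
               "gtgattccgccctctcctggctctctctcgtcgtgggcatatgtt")
  s2 <- paste0("gtctgtggtgtacttgcataaccggatcttcaaccatctcgagga",
               "cggtgtgtgtggtttttccgattagagggttaggtgtcagtggtt",
               "tgctttctaattgatttacgatatatggatcctggacacacacac",
               "tgtaatacttggtggatgccccggatgttaaggatggcgcacatt")
  as_seq_set(c(seq1 = s1, seq2 = s2))
}

# deterministic pseudo-random DNA (independent of the package generator)
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-cell information content oracle
oracle_ic <- function(theta, bg) {
  total <- 0
  for (i in 1:4) for (j in seq_len(ncol(theta))) {
    total <- total + theta[i, j] * log2(theta[i, j] / bg[i])
  }
  total
}

# naive per-position log-odds window score oracle
oracle_window_score <- function(theta, bg, word) {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  s <- 0
  for (j in seq_along(idx)) s <- s + log2(theta[idx[j], j] / bg[idx[j]])
  s
}

# brute-force complexity ratio: w! / product over positions of the count of
# that position's letter (direct transliteration of the definition)
oracle_complexity_ratio <- function(word) {
  chars <- strsplit(word, "")[[1]]
  denom <- 1
  for (ch in chars) denom <- denom * sum(chars == ch)
  factorial(length(chars)) / denom
}

# exhaustive search over all start-position alignments (tiny instances only)
oracle_exhaustive_best <- function(seqs, w, weight_v = 0.8,
                                   pseudocount = 1,
                                   background = "empirical") {
  lens <- seq_lengths(seqs)
  grids <- lapply(lens, function(L) 0:(L - w))
  grid <- expand.grid(grids)
  best_fi <- -Inf
  best_starts <- NULL
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    fb <- motif_fitness(seqs, st, w, weight_v = weight_v,
                        pseudocount = pseudocount, background = background)
    if (fb$fi > best_fi) {
      best_fi <- fb$fi
      best_starts <- st
    }
  }
  list(starts = best_starts, fi = best_fi)
}

# DUST triplet score of a window, computed the slow way
oracle_dust_score <- function(window_chars) {
  n <- length(window_chars)
  tris <- vapply(seq_len(n - 2),
                 function(p) paste(window_chars[p:(p + 2)], collapse = ""),
                 character(1))
  cnt <- table(tris)
  sum(cnt * (cnt - 1) / 2) / (n - 3)
}
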