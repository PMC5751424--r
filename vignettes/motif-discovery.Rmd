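---
title: "Memetic motif discovery: model, search and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memetic motif discovery: model, search and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memotif)
```

# The problem

Given *N* DNA sequences assumed to share a binding site for the same
transcription factor, and a motif width *w*, the package searches for the
start-offset vector — one offset per sequence, the one-occurrence-per-sequence
(OOPS) formulation — whose stacked *w*-mers form the strongest
position-specific score matrix (PSSM).  The search space has
$\prod_i (L_i - w + 1)$ alignments and the problem is NP-hard, so the package
uses a memetic metaheuristic: constructive multi-start (GRASP), a genetic
algorithm, and variable neighborhood search (VNS) as the mutation operator.

All coordinates in this package are **0-based with half-open intervals** (the
BED convention), both in memory and on disk.  Curated binding-site
annotations are often 1-based; `read_sites(one_based = TRUE)` and the CLI's
`--one-based` switch convert on input.

# The scoring model

From an alignment, per-column letter counts are smoothed into relative
frequencies

$$\Theta_{ij} = \frac{c_{ij} + a}{N + 4a},$$

with pseudocount $a = 1$ by default (a Laplace prior; it also guarantees the
strictly positive matrix that the information content requires).  The
background $\Theta_0$ is by default the empirical mononucleotide composition
of the input — appropriate for promoter sets with biased GC content — or
uniform 0.25 per base on request, the right null for synthetic data.

Two objectives are computed from the model:

* **Information content** (bits),
  $\mathrm{IC} = \sum_i \sum_j \Theta_{ij} \log_2 (\Theta_{ij}/\Theta_{0i})$,
  the total Kullback–Leibler divergence of the motif columns from the
  background; non-negative whenever the columns are proper distributions.
* **Complexity score**.  Each selected *w*-mer has a *complexity ratio*
  $w! \,/\, \prod_{j} n_{\mathrm{word}[j]}$ — the factorial of the width over
  the position-wise product of per-letter counts within the word.  The ratio
  is $w!$ for all-distinct letters and minimal for homopolymers
  (`AAAAAA` $\to 720/46656 \approx 0.0154$; `ATACGT` $\to 720/16 = 45$).
  The score sums $\log_4$ of the ratios over the alignment, penalizing
  low-complexity stacks.

The scalar fitness is the weighted sum
$F = v\,\mathrm{IC} + (1 - v)\,\mathrm{CS}$, default $v = 0.8$.

## Why the default pipeline is mono-objective

The complexity term exists to keep the search away from homopolymeric and
repeat-rich alignments.  The default pipeline already removes those by
masking (below), and the two terms scale differently: IC is bounded by
$2w$ bits regardless of *N*, while CS is a sum over the *N* selected words
(each up to $\log_4 w!$), so at realistic dataset sizes (say $N = 20$) a
0.2-weighted CS term numerically dominates a 0.8-weighted IC term and the
fitness stops ranking conserved alignments first.  Accordingly
`run_pipeline()` uses $v = 1$ (pure information content) when masking is on,
and the bi-objective $v = 0.8$ only when the user disables masking — in which
case CS is what protects the search from spurious optima.  `motif_fitness()`
itself defaults to $v = 0.8$, and the fitness is affine in $v$, which the
test suite asserts.

# Preprocessing

`dust_mask()` re-implements triplet-statistic masking: over a sliding window
(default 64 nt), the score is $\sum_t c_t (c_t - 1)/2$ over the 64 triplet
counts, normalized by (window length − 3); positions covered by a window
scoring above 2.0 (the classical cutoff, exposed as a flag) are replaced by
`N`.  Masking is *soft* — lengths are unchanged, so downstream coordinates
remain valid against the original FASTA — and idempotent, because triplets
containing `N` are skipped.  Any window containing `N` is excluded from
valid start positions everywhere in the package; that is also how ambiguous
input bases are handled.

`complexity_filter()` is the fallback for pipelines without DUST-style
masking: windows whose complexity ratio falls below `min_cs` (default 1) are
masked out of the start-position pool.

# Construction (GRASP)

One solution tree is grown per valid start offset of the first sequence;
its root fixes $x_1$ and level $k$ chooses $x_k$.  Candidates at a level are
scored by their window log-odds under the model built from the *w*-mers of
the best partial path — the construction score function is a design choice
(the constructive step only requires *some* ranking); this one keeps each
level at $O(Lw)$ and reuses the package's single scoring path.  Per level a
uniform draw $n$ against the greediness $q$ (default 0.9) selects:

* **greedy** ($n \le q$): the best-scoring position is taken, and every
  position whose score is within a tie band joins as an extra branch.  Exact
  floating-point ties are rare, so the default band is relative, 10% of the
  magnitude of the best score (`tie_epsilon = 0` restores exact ties).  The
  frontier is capped at 5 retained paths — branched trees are overwhelmingly
  pruned back by the cumulative-score cap, which keeps the worst case away
  from $O(L^N)$.
* **randomized** (otherwise): candidates are ranked, the top
  `rcl_size = 5` form the restricted candidate list, and one is chosen
  uniformly.

$q = 1$ makes construction fully greedy; $q = 0$ with `rcl_size` equal to
the number of valid positions makes it uniformly random — both degeneracies
are asserted in the tests (the latter by a $\chi^2$ check over $10^4$
draws).  `best_path()` extracts the maximum-cumulative-score root-to-leaf
path, ties broken toward lexicographically smallest offsets so results are
deterministic under a seed.

The initial population takes one individual per root (all roots by default,
capped at 200; an optional `max_pop` subsamples roots uniformly at random).
Construction once, at startup only — the evolutionary loop never re-runs it.

# The evolutionary loop

Parameters the source method leaves open are set to canonical GA values,
all tunable: uniform per-coordinate crossover on a random non-self pairing
of 80% of the population; population size $\min(v_1, 200)$; at most 100
generations with early stop after 20 stalled generations.

Mutation is conditional local search: with $p^\* = \max(F(p_1), F(p_2))$, a
child with $F < p^\*$ is replaced by `vns_search(child)`; children at least
as fit pass through untouched.  The VNS move set is shift-based —
neighborhood $k$ perturbs $k$ random coordinates by shifts up to $\pm k$
(clamped to valid starts), followed by best-improvement descent over
single-coordinate $\pm 1$ shifts; improvement resets $k \to 1$.  Shifts are
the natural neighborhood for start-position encodings, and the
accept-only-improvements rule guarantees VNS never degrades fitness.

Selection is elitist: parents and children are pooled, stable-sorted by
fitness (ties keep insertion order), and truncated to the parent-population
size.  Since parents stay in the pool, the best fitness per generation is
non-decreasing — asserted as an invariant.

On instances small enough to enumerate ($9^3$ alignments), the loop reaches
the exhaustive optimum in at least 95% of 50 seeded runs; on the standard
challenge regime it recovers planted motifs end to end (both in the
acceptance tests, sizes below).

# Scanning

The final model scores every width-*w* window of every sequence (stride-1;
disjoint splitting would miss nearly all sites).  Scores are log₂ odds
(model over background) — any affine transform of the raw score yields
identical calls, because standardization removes location and scale.  The
score population is summarized by its sample mean and standard deviation
(denominator $n-1$); windows are reported when the upper-tail Gaussian
probability of their z-score is at most $\alpha$ (default $10^{-4}$).  The
upper tail is the only convention consistent with "most significant =
highest scoring".  An analytic null (per-column mean and variance of the
log-odds under the background, summed) is available as
`fit_scan_model(source = "analytic")`; the empirical route is the default
because it needs no independence assumption across columns of real
sequence.  No multiple-testing correction is applied — $\alpha$ is a
per-window threshold, and the tests document that secondary sites in a
sequence are recovered.  Overlapping calls are greedily pruned to the most
significant representative by default (disable with
`prune_overlaps = FALSE`).  With `revcomp = TRUE`, windows are also scored
under the reverse-complemented model and reported on the minus strand, and
`revcomp_symmetrize()` provides the palindrome-symmetric model average.

# Evaluation protocol

`match_positions()` scores predictions against annotations with a ±2
start-position tolerance (for an annotated position 60, exactly 58–62
match).  Matching is greedy in ascending distance and **one-to-one** — the
annotation side is not told how to absorb multiple near predictions, and
one-to-one is the choice that keeps $tp \le$ number of annotations, so
recall cannot be inflated by stacked predictions.  Precision, recall and
f-score follow, with the 0/0 conventions stated in the documentation.
`summarize_runs()` reports per-metric mean and sd over repeated runs;
`dominance_rank()` implements pairwise wins-minus-losses ranking (zero-sum
by construction); `compare_fscores()` is an optional report that delegates
to Shapiro–Wilk, paired t and Wilcoxon tests from `stats`.

# Synthetic data

`generate_planted()` emulates the planted-$(l, d)$ benchmark: i.i.d.
order-0 background (uniform by default), one or more non-overlapping
instances per sequence at uniform recorded positions, instances either the
consensus with exactly *d* substitutions or draws from a generating
frequency matrix.  Defaults — 20 sequences × 200 nt, $w = 11$, $d = 2$, one
instance per sequence — are the package's standard challenge regime: the
scale of a small curated promoter set and a planted-motif difficulty that
is hard but solvable, the community-standard middle ground.
`degrade_low_complexity()` injects homopolymer-biased short-period runs
(never over the truth windows) for testing the preprocessing stage.

What the generator does *not* emulate: positional bias of sites within
promoters, higher-order background structure, correlated columns, missing
sites (non-OOPS sequences), and overlapping/cooperative motifs.  Passing the
planted-recovery gates therefore demonstrates the optimizer and scanner work
as specified, not that real ChIP-seq performance is reproduced.

# Numerical choices and problem sizes

* Fitness comparisons use a $10^{-12}$ strict-improvement margin; selection
  and tie-breaks are otherwise deterministic, so a run is fully reproducible
  from its seed (the CLI echoes seed and parameters into every output
  directory).
* Degenerate inputs: sequences shorter than *w* contribute no windows
  (warning); a level with no valid position fails that tree (logged,
  skipped); an all-identical score population is a hard error in
  `fit_scan_model()`; zero-`theta` models are rejected by
  `information_content()` with a pointer to pseudocounts.
* The acceptance-level checks run at deliberately scaled sizes chosen to
  exercise the claims well inside a laptop budget: exhaustive-oracle
  agreement at $N=3, L=12, w=4$ over 50 seeds, and planted recovery at the
  challenge regime over 10 seeds with 40 generations, stall 10 — early
  stopping typically ends these runs near generation 10.

# Known limitations

* OOPS only: no ZOOPS/TCM site-count models; sequences without a true site
  still contribute one (spurious) alignment row.
* Order-0 background only; no dinucleotide or flexible-length models.
* Gaussian tail p-values are an approximation to the true PSSM score
  distribution; no exact DP p-value computation.
* Phase shifts: the optimizer can converge to the planted alignment offset
  by ±1 column (still within the evaluation tolerance, but it dilutes one
  model column and weakens scan z-scores on unlucky seeds).
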