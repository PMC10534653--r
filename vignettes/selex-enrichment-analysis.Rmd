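---
title: "Methods: SELEX round enrichment analysis with aptaselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SELEX round enrichment analysis with aptaselex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`aptaselex` analyses per-round sequencing data from SELEX aptamer
selections. The unit of analysis is the *pool*: a map from distinct
variable-region sequences to read counts for one selection round. The
pipeline converts raw FASTQ into pools, groups pools into clusters, summarises
each round, links clusters across rounds into lineages, and ranks final-round
candidates. A selection simulator provides synthetic experiments with known
ground truth for validation. This vignette records the methodological choices
and their rationale.

# Library geometry

A library member is `arm5 + variable + arm3`. The default geometry is a 40-nt
randomized region between constant arms of 18 and 19 nt — a 77-nt amplicon at
the transcript level. The packaged default arm sequences are fixed arbitrary
sequences of those lengths: they define a concrete, reproducible geometry
without pretending to be any particular experiment's primers, and real
analyses should pass their own arms to `library_spec()`. Arms given as RNA
(with U) are converted to the DNA view.

# Read preparation

`load_round()` applies three filters in a fixed order:

1. **Mean quality** (default threshold 28): a read passes when the arithmetic
   mean of its Phred scores is ≥ the threshold. The per-read mean (rather
   than a windowed rule) is the simplest reading of an "average quality"
   cutoff; the boundary is inclusive, so a mean of exactly 28 passes.
2. **Arm trimming**: each constant arm is located as the best ungapped
   placement scanned over ±2 nt of positional slack, tolerating up to
   2 substitutions (both configurable via `prep_params()`). The slack absorbs
   single indels, which is what produces variable regions of 39 or 41 nt.
   Failure to place an arm is a *rejection with a reason*, not an error.
3. **Length/alphabet**: the enclosed variable region must be 39–41 nt of pure
   A/C/G/T.

The order quality → trim → length is a package convention chosen so that each
rejected read has exactly one attributable reason and
`input = survivors + Σ rejections` holds identically. Reads whose variable
region contains N are rejected — downstream clustering and alignment assume a
clean alphabet — but the fraction of raw reads containing any N is still
reported (`n_read_fraction`) so that ambiguity is visible before filtering.

# Clustering

`greedy_cluster()` reimplements the CD-HIT-style step as an internal,
deterministic algorithm:

* **Identity metric**: matched bases in a banded global alignment divided by
  the length of the *shorter* sequence (the CD-HIT denominator). The band is
  the main diagonal widened by the length difference plus 2 nt of slack —
  exact for pools whose lengths differ by at most 2, which the 39–41 window
  guarantees — and gaps and mismatches carry no cost in the match count.
* **Ordering**: candidates are visited by read count descending, ties broken
  lexicographically. Abundance ordering (not CD-HIT's length ordering) makes
  the representative of every cluster its most abundant member, which is what
  "seed sequence" means here; lengths are nearly constant so length ordering
  would be arbitrary anyway.
* **Rule**: each sequence joins the first existing cluster (in founding
  order) whose representative is within the threshold (default 0.90), else it
  founds a new cluster. Sequences are clustered as unique strings weighted by
  counts; clustering read-by-read would give the same partition at linear
  extra cost.

Thresholds are compared in integer space (`matches ≥ ⌈t·minlen⌉`) so that
0.90 of 40 means exactly 36 matched bases, immune to floating-point drift.

Two rigorous shortcuts accelerate the scan without changing its result: an
equal-length pair whose *ungapped* match count already reaches the threshold
joins immediately (the ungapped alignment is one of the banded alignments, so
it is a lower bound), and a pair whose *longest common subsequence* falls
below the required match count is rejected (any alignment's matches form a
common subsequence, so the LCS — computed bit-parallel — is an upper bound).
`brute_force_cluster()` executes the same rule from a full all-pairs identity
matrix with none of these shortcuts and is used in the tests as the oracle.

# Round statistics

* **Unique vs enriched**: clusters with ≤ 50 total reads are "unique",
  larger ones "enriched"; fractions are read-weighted (class read sum over
  round reads). The inclusive boundary (50 is unique) follows the
  figure-legend convention "50 sequences or fewer".
* **Bins**: cluster totals fall into the six printed bands
  (≤10, 11–100, 101–1000, 1001–5000, 5001–10,000, >10,000), read-weighted.
* **Nucleotide profile**: count-weighted base frequencies at variable
  positions 1–40. 39-mers contribute N at position 40; 41-mers are truncated
  to 40. The padding rule is a declared package convention — a fixed-width
  profile with an explicit N category needs *some* rule for off-length reads,
  and right-padding/truncation keeps every row summing to 1.
* **Diversity**: for relative abundances $p_1..p_R$, richness $R$, Shannon
  $H = -\sum p_i \ln p_i$ (natural log), inverse Simpson
  $S^{-1} = 1/\sum p_i^2$. Computed over distinct *sequences* by default
  ("different sequences observed"); `diversity_level = "cluster"` switches to
  cluster abundances, since either reading is defensible and both are one
  call.

# Cluster tracking

Lineages ("UC" + integer, assigned at first appearance) follow clusters
forward in time:

* **Scoring**: Needleman–Wunsch global alignment with affine gaps; a gap of
  length $L$ costs $open + L \cdot extend$. The defaults (match +1,
  mismatch −1, open 2, extend 2) are a package choice exposed in
  `tracking_config()`: under them two 40-mers clear the score threshold of 30
  when they differ at about five or fewer positions, consistent in spirit
  with the 90 % clustering identity. The threshold is strict on the loss
  side: best score < 30 means lost, exactly 30 carries forward.
* **Forward chaining**: a representative maps only to the *next* round; a
  lineage lost at round $k$ never resumes — a later similar sequence founds a
  new lineage. This matches the interpretation that an unmatched
  representative is "lost" rather than dormant.
* **Collision handling**: live lineages are processed in descending current
  RPM and each claims its best-scoring unclaimed cluster; a cluster absorbs
  at most one lineage. This keeps trajectories disjoint and the result
  deterministic (ties on score break by higher cluster count, then
  lexicographic representative; all orderings have explicit tie-breaks).
* **Network**: nodes are rounds sized by cluster richness; the edge between
  two rounds counts lineages present in both — the same alignment criterion
  as tracking, for internal consistency, rather than exact string equality.

An exact representative match short-circuits the alignment scan: with a
positive match score and non-negative penalties, the verbatim target is the
unique score maximum. When mismatch penalties are non-positive, targets that
cannot reach the threshold (score ≤ match × LCS) are skipped; both shortcuts
leave the matched/lost decision and the identity of any match unchanged.

# Candidate ranking

Final-round clusters are ranked by RPM (ties: total count, then
representative). For each candidate the report carries the RPM gap to the
next rank (the last gap is the last RPM itself) and the seed dominance
`representative_count / total_count`. The default report depth is 100, with
10 as the conventional shortlist; both are parameters. Representatives export
as FASTA for external multiple-alignment or structure tools — those analyses
are deliberately out of scope.

# qPCR quantification

`fit_standard_curve()` is ordinary least squares of Ct on log10 quantity over
a dilution series (canonically 10-fold steps from $10^2$ to $10^{-3}$ ng).
`interpolate_quantity()` inverts the line and flags values outside the fitted
range as extrapolated, with a $10^{-8}$ relative tolerance so boundary
standards do not flag through rounding. `ddct_fold_change()` implements
$2^{-\Delta\Delta Ct}$ with the PCR efficiency fixed at 2 — the calibrator
itself therefore gets a fold change of exactly 1; efficiency-corrected
variants are out of scope. Relative enrichment is the plain ratio of
tissue-normalized quantities; the same operation with input-cDNA units
expresses relative binding.

# The simulator and what it does (not) emulate

`simulate_selex()` models one round as: binomial survival of each read with
its sequence's capture probability, multiplication by an amplification factor
with per-sequence lognormal noise (mean 1, coefficient of variation
`amp_noise_cv`), and multinomial resampling to the sequencing depth. FASTQ
emission adds independent per-base substitution errors, per-base Gaussian
Phred qualities, and optionally single-base indels inside the variable
region. All randomness flows through R's RNG, so a seed makes the entire
experiment — including the FASTQ bytes — reproducible.

Default scenario (the conditions the validation suite uses): 7 rounds, a
10,000-member library sequenced at 100,000 reads per round, one spiked
sequence with capture probability 0.5 against a background of 0.05 (a 10×
per-round advantage), amplification factor 10 with cv 0.3, substitution rate
0.001/base, 0.5 % of reads carrying one indel, mean quality 32. Property
tests that average over many replicate simulations use smaller pools
(hundreds of members, thousands of reads) so that fifty-replicate means stay
cheap; the conclusions they check are scale-free.

Two generator choices deserve emphasis:

* **Amplified input** (`initial_copies`, default 100): the synthesized
  library enters round 1 with every member in many copies, as real selections
  do (~10¹³ molecules). With single copies, survival of any individual
  sequence through round 1 would be a Bernoulli coin flip and no analysis
  could recover a spiked sequence reliably.
* **Indels exist** (`indel_rate` > 0 by default): observed SELEX length
  spreads (39–41 nt around a 40-nt design) imply indel-bearing reads, and the
  length filter needs exercising; `emit_fastq()` itself defaults to
  substitutions only.

What the simulator does **not** emulate: PCR chimeras, cross-binding to
carrier tissue, reverse-transcription biases, quality degradation along the
read, and — most consequentially — *library diversity far exceeding
sequencing depth*. A desk-scale library (10⁴ members at 10⁵ reads/round) is
exhaustively oversampled: consecutive early rounds share nearly all their
clusters, so the common-cluster network's early edges are the heaviest and
thin out as the pool converges. Real selections sample ~10¹³-diverse pools at
~10⁵ reads, so early-round samples are nearly disjoint and shared-cluster
edges *grow* toward the convergence plateau. Passing simulation tests
therefore validates the accounting, the algorithms and the enrichment
dynamics, but the direction of the network-edge trend is regime-dependent
and the oversampled regime inverts it.

# Numerical and degenerate-input conventions

* Pools order sequences by count descending, ties lexicographic; every
  downstream ordering (cluster founding, UC assignment, ranking) states its
  tie-break, so reruns are bit-identical.
* Empty inputs are values, not crashes: an empty FASTQ gives an empty pool
  with a zeroed report; an empty cluster list classifies with a warning and
  zero fractions; an empty final round ranks to an empty list with a warning.
  A selection round in which nothing survives raises an explicit
  "selection collapse" error rather than returning an empty pool.
* `brute_force_cluster()` refuses pools above 500 unique sequences — it is a
  quadratic validation oracle, not a production path.
* Alignment scores are doubles throughout; identity decisions are integral as
  described above.

# Known limitations

* Identity is exact only within the ±2 alignment band; pools with length
  spreads beyond the 39–41 window would need a wider band (a
  `band` argument exposes this).
* Tracking maps strictly forward round-to-round; selections with skipped or
  failed sequencing rounds should be tracked on the rounds that exist.
* The qPCR module fixes amplification efficiency at 2 and does not estimate
  it from the dilution series.
* Paired-end merging is not implemented; inputs are single-end or pre-merged
  reads covering the full amplicon.
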