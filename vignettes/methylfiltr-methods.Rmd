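---
title: "Models and methods behind methylfiltr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylfiltr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylfiltr)
```

# The problem

Methylation filtration (MF) builds a shotgun library in a bacterial strain
that degrades methylated DNA. In plant genomes, repeats are heavily
methylated and genes are not, so MF clones over-represent the
hypomethylated, gene-rich genome fraction. Two quantities summarise how
well this worked:

* **Filter power (FP)** — the probability that a filtered read sampled gene
  sequence divided by the same probability for an unfiltered control read.
* **Effective sampled genome size** `G_f = G / FP` — the portion of a
  genome of size `G` that the filtered library can actually reach.

methylfiltr implements the two classical estimators of these quantities
together with the marker-mining stages such surveys run downstream
(microsatellites, SNPs from assembly pileups, gene-space coverage, and
rule-based gene classification), plus a synthetic-data generator so every
estimator is exercised against a known truth.

# Filter-power estimation

## Direct estimator

`direct_filter_power(h_f, n_f, h_u, n_u)` is the plug-in ratio
`(h_f/n_f) / (h_u/n_u)`. A delta-method standard error for the
binomial-proportion ratio is attached:
`se(FP) = FP * sqrt((1-p_f)/(n_f p_f) + (1-p_u)/(n_u p_u))`. The ratio is
undefined when the unfiltered hit count is zero; this is an error, not an
infinity.

## Mixed-assembly Lander–Waterman inversion

In Lander–Waterman theory, reads laid on a genome at start density
`lambda` with effective length `sigma = L - T` (a join needs a detectable
overlap of at least `T` bp) form `N * exp(-lambda * sigma)` islands in
expectation. In a *mixed* assembly, filtered reads fall only inside the
hypomethylated space `G_f`, unfiltered reads everywhere, so the density is

* `lambda_in = n_f/G_f + n_u/G` inside the hypomethylated space, and
* `lambda_out = n_u/G` outside,

and `expected_islands_mixed()` evaluates the expectation piecewise:

`E = lambda_in G_f exp(-lambda_in sigma) + lambda_out (G - G_f) exp(-lambda_out sigma)`.

Fragmentation of the hypomethylated space into many blocks does not change
this expectation (it is additive over blocks at fixed density), which is
why a single contiguous `G_f` is an adequate model. The formula is
validated against a Monte-Carlo placement oracle
(`mc_island_counts()`), not against any closed-form reference.

`infer_filtered_size()` inverts the expectation for `G_f` given an
observed island count: a 1000-point grid over `(0, G]` locates sign
changes, each bracketing interval is bisected (tolerance `1e-9 * G`; the
round-trip contract of 0.5% demands much better than a coarse
`1e-3 * G`). If several roots exist, the one whose FP is closest to the
direct estimate (when given) is reported and all roots are retained. An
observed count outside the attainable range yields a `no_solution` flag.
The analysis refuses to report below 0.1x coverage of the inferred
filtered space — under that coverage the island count barely constrains
`G_f`.

Reported megabase values round half *away* from zero
(`round_half_away()`): `1800/3.2 = 562.5` reports as 563, matching the
convention of the survey literature this package follows. Ti/Tv display
values are *truncated* to two decimals, again following that convention.

# Island clustering

An island is a maximal set of reads connected by pairwise overlaps of at
least `T` bp. For placed intervals with `start_i <= start_j` the
intersection is `min(end_i, end_j) - start_j`, so an edge exists iff
`start_j <= end_i - T` and read `j` is at least `T` long. Single-linkage
components are therefore exactly the overlap components of the shrunken
intervals `[start, end - T]`, which a left-to-right sweep computes
exactly; reads shorter than `T` are always singletons. (A naive sweep on
the *unshrunken* intervals is wrong when a long read spans past short
ones; the test suite checks the implementation against an all-pairs
union-find oracle.) No sequence alignment is performed: in simulation
mode the truth placements are used, otherwise a supplied overlap table.

# Microsatellite mining

## The run model

A microsatellite is a tandem run of a 2–4 bp unit with minimum copy
numbers 6/5/4 (di/tri/tetra) and "one imperfection per 10 repeat units"
allowed. methylfiltr makes that rule concrete as a grammar:

* a run is a sequence of unit copies, beginning and ending with a
  *perfect* copy;
* an imperfection is a *substituted copy* (one mismatch), a *deleted copy*
  (unit minus one base) or one *inserted base* between copies (at most one
  insertion per junction);
* a run of `n` units may carry at most `floor(n/10)` imperfections — a
  global budget, not a sliding window, so a run needs at least 10 units
  before its first imperfection is affordable.

`N` matches nothing, mononucleotide runs are never reported, and
sub-periodic motifs (`ATAT` as a tetramer) are handled at their true
period. For each start the longest valid run is kept (ties: more units,
then fewer imperfections); within a unit length, runs contained in a
longer run are suppressed; overlapping runs of *different* unit lengths
are all reported. A trailing partial unit neither counts toward `n_units`
nor extends the reported interval (the run must end on a perfect copy).

## Search and the reachability bound

The finder performs a memoized depth-first search over parse states
`(position, units, imperfections, insertion-pending)`. Exhaustive search
of imperfection chains is exponential near repeat-rich sequence, so two
*provably lossless* prunes are applied; both follow from the budget
arithmetic. For a state with deficit `d = 10*imps - units > 0`:

* if the parse finishes with no further imperfection, the remaining units
  are consecutive perfect copies of the motif starting at the current
  position — checkable against a precomputed tandem profile;
* otherwise, with `e >= 1` future imperfections, at least `d + 9e` future
  *perfect* copies are needed (each future imperfect unit raises the
  requirement by 9) sitting in at most `e + 1` blocks; hence the largest
  downstream perfect tandem block has at least `min(ceil((d+9)/2), 9)`
  copies, and counting self-matching positions gives
  `d <= E/k - 7` where `E` is the number of positions `q` ahead with
  `s[q] == s[q+k]`.

A start-level corollary (any valid run either opens with the minimum
number of perfect copies or contains a 5-copy perfect tandem block)
prunes candidate starts vectorially, which is what makes scanning random
DNA fast. The same bounds are embedded in the test oracle, whose search
is otherwise an independent exhaustive recursion; an additional test
compares both against a bound-free naive recursion on short strings.

## Canonical motif classes

`canonical_motif()` maps a unit to the lexicographically smallest string
among its rotations and the rotations of its reverse complement, so `GA`,
`AG`, `CT`, `TC` all report as `AG`. Brute-force orbit enumeration over
all aperiodic units gives 4 dinucleotide, 10 trinucleotide and 33
tetranucleotide classes. Class percentages are computed over all SSRs of
all unit lengths combined.

# SNP calling

A pileup column yields a SNP iff at least two distinct nucleotide alleles
each have support from `>= 2` separate reads and the column depth does not
exceed the high-coverage cutoff. Gaps and `N` count toward depth but
never toward allele support. The cutoff is the absolute value 30 by
default, matching the convention that columns deeper than that sit in
repetitive or collapsed regions; `max_depth = "auto"` instead uses
`mean + 2*sd` of the depth distribution. Columns with three or more
supported alleles are emitted once, flagged `multiallelic`, with the two
best-supported alleles (ties broken alphabetically) so that totals remain
auditable. Transitions are `C/T` and `G/A`; SNP density is
`SNPs / (positions with depth in [4, 30]) * 100` (both bounds inclusive).

# Gene-space coverage and classifiers

`iterative_subtract()` implements in-silico subtractive hybridisation:
align queries to targets, mask the single globally best passing hit's
target interval with `N`, repeat until no hit passes `1e-20`. The global
best is (lowest e-value, highest score, longest target interval,
lexicographic ids) — deterministic; `per_target = TRUE` masks the best
hit of every target per iteration instead. Only the aligned interval is
masked, not the whole target, so the masked fraction equals the interval
union of the hits used. Masked positions cannot anchor new hits (N
matches nothing in the bundled scoring), so every iteration masks fresh
sequence and termination is guaranteed. The bundled aligner is
`Biostrings::pairwiseAlignment` with unit scores and the pseudo e-value
`m*n*2^(-score)` — deterministic and monotone in score but **not**
BLAST-compatible; production runs should supply external tabular hits.
Queries are assumed repeat-masked upstream.

The rule-based classifiers are direct encodings of their field
conventions: EST tagging at e-value `<= 1e-20` (inclusive); gene-model QC
(keep iff `length >= 300` and (`AED < 0.1` or rescued by a database hit
`<= 1e-20`)); R-gene classes by domain signature with precedence
TIR-NBS-LRR (3) > CC-NBS-LRR (2) > LRR-TM-kinase (5) > LRR-TM (4) >
kinase+Pto (1) > uncategorized (6); and miRNA precursor matches (perfect:
full-length span at `>= 95%` identity; partial candidate: `>= 85%`
identity and score `>= 100`, promoted to partial only by an external
secondary-structure hook — the bundled default confirms nothing and
leaves candidates marked unconfirmed). TM and Pto are *input* labels:
the upstream evidence standard (e.g. transmembrane prediction) is the
caller's responsibility.

# The synthetic world

`simulate_genome()` partitions a single random chromosome into gene,
repeat and spacer segments hitting the requested bp fractions exactly
(gene and repeat interval lengths average ~2 kb and ~15 kb), then marks
repeat intervals as methylated until the requested fraction of repeat bp
is covered. Defaults (`gene_fraction = 0.25`, `repeat_fraction = 0.6`,
`methylated_repeat_fraction = 0.97`) give a hypomethylated fraction of
about 1/2.4, the regime the estimators are designed for. Long methylated
blocks are deliberate: read-level rejection shaves `read_len - 1` start
positions off the hypomethylated space per methylated block, so many
short blocks would bias the direct FP estimator upward by several
percent, while with ~40 long blocks the bias is ~1%, well inside the
sampling noise of a 10^4-read library.

`simulate_library()` models filtration as a genome-space restriction at
read level: candidates overlapping a methylated interval are rejected and
resampled, except that each escapes with probability `leak_prob`
(default 0.05 — the filtering strain's leak rate is not a published
number; this is a modeling choice). Read lengths are uniform on 60–140 bp,
a tenfold scale-down of a 0.6–1.4 kb size-selection window. No quality
scores, indels, paired ends or cloning artifacts are simulated, so green
tests establish correctness of the estimators under the stated model, not
robustness to real sequencing noise. `inject_variants()` plants biallelic
sites with a controllable transition/transversion weighting (a target
Ti/Tv of `r` is planted with weights `r : 1`), and `build_pileups()`
realises gap-free reads over contig windows at Poisson depth with
per-read allele sampling and optional uniform substitution error.

All generators draw from per-operation streams derived from one top-level
seed by fixed offsets, so adding a generator does not perturb the others,
and identical `(seed, params)` give byte-identical outputs.

# Numerical and design choices

* Coordinates are 0-based half-open internally; +1 shifts happen exactly
  once, at serialization (GFF3/VCF/ACE are 1-based on disk).
* Reported Mb: round half away from zero. Ti/Tv display: truncate to 2
  decimals. Percentages in summary tables: integer, half away from zero;
  SSR class percentages: 2 decimals.
* The ACE dialect is a documented subset (`AS`/`CO`/`AF`/`RD`, pads `*`,
  `QA`/`BQ` ignored); anything else is rejected loudly rather than
  guessed, and truncated files are errors, never partial parses.
* The island count defaults to *all* islands; the table convention that
  drops sub-50 bp singletons is available via `exclude_short`.
* Depth bounds are read inclusively (`[4, 30]`), and the EST-tagging and
  gene-model rescue thresholds are inclusive ("not more than").

# Known limitations

* The bundled aligner is quadratic-time and intended for fixtures and
  small coverage studies; large runs should import tabular hits from a
  real aligner.
* The SSR imperfection budget is global per run; tools that enforce a
  sliding window or score-based extension (e.g. Sputnik itself) can call
  slightly different boundaries on heavily imperfect tracts.
* The Lander–Waterman inversion assumes uniform sampling within each
  space and fixed read length; variable read length enters only through
  the mean.
* Multi-chromosome genomes are modelled as concatenations with interval
  bookkeeping; no inter-chromosome structure is simulated.
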