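---
title: "Discovering anchor-TF cofactors from motif modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering anchor-TF cofactors from motif modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A transcription factor (TF) rarely regulates alone. When an anchor TF --
HIF1A in the motivating application -- is ChIP-sequenced across several cell
lines, the sequences under its binding peaks carry not only its own motif but
the motifs of the TFs it cooperates with. `cofactorScope` implements the
downstream analysis that turns per-cell-line *motif modules* (sets of motifs
that significantly co-occur in peak sequences, as produced by a de novo
module-discovery tool) into a ranked, validated list of candidate cofactors:

1. match predicted motifs against a known-motif library (JASPAR-style) to
   name candidate cofactor TFs;
2. validate predictions by cross-cell-line conservation of motifs and motif
   pairs, against a random-motif-module resampling null;
3. test whether predicted cofactor pairs are enriched for known
   protein-protein interactions (PPIs) with a hypergeometric tail;
4. rank cofactors and measure recovery of curated cofactor lists;
5. annotate peaks to nearest-TSS target genes and ask whether differences in
   cofactor usage between cell lines predict differences in the enriched GO
   terms of their targets (the divergence regression).

Module discovery itself, read mapping and peak calling are upstream tools and
out of scope; the package consumes their outputs (BED peaks, JASPAR motif
text, a module TSV).

# Motif similarity and E-values

Motif comparison uses ungapped alignment of position weight matrices: motif
*b* slides along motif *a* in both orientations, every overlap of at least
`min(4, width)` columns is scored by the sum of per-column Pearson
correlations of the probability 4-vectors, normalised by `max(w_a, w_b)`.
Normalising by the longer width penalises partial overlaps, so only
full-motif similarity scores near 1; uniform columns contribute zero
correlation, so padding cannot inflate a match.

Scores are converted to E-values against an empirical null: `calibrateNull()`
aligns `nNull` pairs of column-shuffled, within-column-permuted library
motifs and stores the sorted null scores. The E-value of a score is the
library size times the (add-one) fraction of null scores at least as large.
Two practical consequences shaped the design:

* The smallest attainable empirical E-value is `L/(nNull + 1)`. Thresholds
  such as 1e-5 and 1e-8 -- the decision structure this pipeline preserves --
  are below that floor at any feasible `nNull`. The `"tail"` method therefore
  fits a Gaussian to the null scores and, only when a score exceeds every
  null score, substitutes the analytic upper-tail probability (capped so
  E-values remain monotone in the score). The `"empirical"` method is the
  plain formula and is what `motifEvalue()` returns by default; the matching
  and conservation stages default to `"tail"`.
* Because E-values are calibrated rather than borrowed from an external
  motif-comparison tool, threshold semantics are preserved (smaller = more
  similar; `< 1e-5` for naming cofactors, `< 1e-4` relaxed, `< 1e-8` for
  cross-line similarity) but absolute values are not comparable to other
  tools'. Synthetic acceptance therefore scores *recovery of planted truth*,
  not absolute threshold agreement.

Matching (`matchKnown()`) reports up to the top five TFs per motif below the
cutoff, mirroring the behaviour of standard motif-comparison tools; an
unfiltered mode supports paralog diagnostics.

# Conservation and the resampling null

Motif conservation of a cell line is the fraction of its motifs with at least
one similar motif (E < 1e-8) in at least one *other* line. Motif-pair
conservation treats the pairs extracted from each line's modules
(`modulePairs()`: all size-2 subsets, deduplicated) and calls a pair
conserved when another line has a pair similar component-wise in either
orientation. Both statistics share one cached similarity relation
(`crossLineSimilarity()`), so they cannot drift apart.

`randomPairNull()` rebuilds every module as a uniform random draw of the same
size from its line's motifs, recomputes the overall pair-conservation
fraction, and reports both the add-one empirical p-value
`(1 + #{null >= observed})/(R + 1)` and a Gaussian-tail p-value fitted to the
null fractions. The empirical value is honest at small `R` (its floor is
`1/(R+1)`); the Gaussian value mirrors the extreme magnitudes that a
parametric reading of such nulls produces. Both are reported because either
convention is defensible and they answer slightly different questions.

# Pair enrichment

Known TF-TF interactions are split into *direct* (an edge between two TFs)
and *indirect* (two TFs sharing any common interactor -- a length-2 path --
excluding already-direct pairs, so the classes are disjoint and can be tested
separately). With `N` TFs and `M` known pairs in the database, `n` distinct
TFs among the predicted cofactor pairs and `m` predicted pairs known to
interact, the p-value is the hypergeometric upper tail
`phyperTail(m, n(n-1)/2, M, N(N-1)/2)`, authored in log space in this package
and cross-checked in the test suite against both exhaustive enumeration and
the standard distribution function. Treating all `n(n-1)/2` pairs of
predicted TFs as the universe is deliberately conservative when the predicted
pairs are a sparse subset. The per-line tests are combined into one
study-level p-value with Fisher's method (`fisherCombine()`), matching the
study-level question "is planted/real PPI structure detected".

The TF universe `N` is taken from the supplied edge list's TF flags and
recorded in the output, since curated databases differ in how many TFs they
cover.

# Ranking and recovery

A cofactor's score is the mean over cell lines of `-log10` of its best
E-value in the line, times the number of lines in which it appears. The
negative log is base 10 and the cutoff is strict (`score > 15`): a TF at
average E-value exactly 1e-5 in exactly 3 lines scores 15 and is excluded,
because a top cofactor should beat an average E-value of 1e-5 and occur in
more than three of eight lines. A config switch allows weighting by module
count instead of line count, because study descriptions sometimes state the
former; the line-count definition is the default as the only one that makes
the cutoff of 15 interpretable. Recovery against a curated list reports
hits, total, a half-up one-decimal percentage (21/29 prints as 72.4), and
the missed list for paralog diagnostics.

# Peaks, targets and divergence

Peaks shorter than 800 bp (about the median length of a cis-regulatory
region) are extended symmetrically about their midpoint, the extra base going
right on odd deficits, clamped to the chromosome with an inward shift so the
target length survives at chromosome ends. Midpoint-based extension and
midpoint-to-TSS distances are conventions chosen here (summit positions are
not part of the input contract); ties between equidistant genes resolve to
the lexicographically smaller gene id so the assignment is deterministic.
Cross-line peak overlap uses half-open, at-least-1-bp semantics.

GO over-representation of a line's target genes reuses the same
hypergeometric tail, with Benjamini-Hochberg adjustment across tested terms
and an enrichment call at `q < 0.05` (the multiple-testing rule is this
package's choice). The "difference" between two cell lines' cofactor sets or
GO-term sets is the Jaccard distance (symmetric, bounded, robust to set
size; a normalised symmetric difference is available as an alternative).
For every cell line, GO difference is regressed on cofactor difference over
that line's pairs with all other lines -- per-line fits, because per-line
R-squared values are the quantity of interest -- and the mean R-squared over
lines summarises the study. The per-line cofactor sets entering this
analysis are *all* TFs assigned in the line: every predicted motif already
derives from the anchor's peaks. The anchor-module co-occurrence restriction
(`anchorCofactors()`) defines the focused set used for ranking and recovery.

# The synthetic-study generator

`simulateStudy()` builds a complete study with planted truth. Its defaults
are the study conditions every acceptance simulation uses: 8 cell lines, a
60-motif known library, 25 predicted motifs per line of which 70% derive
from a conserved core, 30 modules per line of size 2-5 containing the anchor
motif with probability 0.8, Dirichlet perturbation concentration 50, 15
planted cofactors, PPI background density 0.02, 500 genes and 40 GO terms.

Design choices the generator makes beyond those headline numbers, with the
reasoning:

* **Conserved core pool (28 TFs) with a similarity gradient.** Each line
  draws its core from a pool larger than the draw, with Gaussian preference
  (bandwidth 0.18 on a unit circle) for pool TFs near the line's own
  position. Lines therefore share most but not all cofactors, and *how much*
  two lines share varies smoothly across pairs -- without this, pairwise
  overlap is nearly constant and the divergence regression has no variance
  to explain; with it, the panel behaves like a real mix of related and
  unrelated cell lines.
* **Line-private motifs** fill the remaining 30% from a global queue, so
  they are disjoint across lines whenever the library allows -- they model
  cell-type-specific regulators.
* **Shared module templates.** 70% of a line's modules instantiate one of 40
  global TF-composition templates (restricted to the TFs the line carries,
  padded from the line's own motifs); the rest are line-random. TF complexes
  recurring across cell lines is precisely the biology the conservation
  statistics measure; fully line-random modules would make the "real"
  modules indistinguishable from the resampling null by construction.
* **PPI plants.** Every anchor-cofactor edge is present; cofactor-cofactor
  pairs that co-occur within some realized module gain an edge with
  probability 0.6 (interacting TFs co-bind); background edges are uniform at
  the configured density over 60 TFs plus 60 non-TF proteins (the non-TFs
  provide length-2 paths for the indirect class).
* **Genome and GO plants.** Genes sit in disjoint 8 kb windows on a toy
  two-chromosome genome; each core-pool TF owns 12 program genes annotated
  with its own GO term (one term per TF keeps 28 programs within the
  40-term budget); genes additionally carry Poisson(0.4) noise annotations
  drawn from the remaining background terms, so annotation noise is present
  without corrupting the planted programs themselves.
  A line's peaks cover the program genes of its core TFs (one peak per gene
  window, so peaks never overlap within a line, while shared programs make
  peaks overlap *across* lines) plus 50 background peaks in unused windows.
  Target-gene sets are then roughly half the gene universe, the regime in
  which a q < 0.05 call cleanly separates program terms from noise terms.
* **Determinism.** One global seed fans out to per-component seeds through a
  counter scheme, so adding a component does not shift the streams of
  existing ones; two runs at the same seed are byte-identical on disk.

What the generator does *not* emulate: genomic sequence composition (modules
and occurrence matrices are planted directly, since the analysis starts from
module-discovery output), read-level noise, motif discovery failure modes,
paralog structure within the known library, or GO-term dependency (the
gene-to-term map is flat). Passing the recovery tests therefore shows the
*inference machinery* is sound under the planted model; it does not certify
performance on real ChIP-seq data, where motif discovery quality and
database incompleteness dominate.

# Numerical conventions and degenerate inputs

* All genomic intervals are 0-based half-open on disk (BED, TSS TSV) and
  1-based closed inside `GRanges`; parsers convert at the boundary and
  round-trip exactly.
* Presentation rounding of summary percentages is half-up at one decimal
  (a mean of 88.85 prints as 88.9, matching how such tables are printed);
  full precision is kept in all JSON output.
* Alignment tie-breaks: maximum score, then smaller absolute offset, then
  the + orientation. Uniform (zero-variance) columns score correlation 0.
* `phyperTail` sums in log space; infeasible terms contribute zero;
  `phyperTail(0, ...)` is exactly 1.
* Degenerate cases warn and return the conservative value: zero marginals in
  the co-occurrence test (p = 1), fewer than two predicted TFs in the
  enrichment test (p = 1), a single cell line in pair conservation
  (fraction 0), zero-variance regressors in the divergence fit (line
  excluded from the mean).
* A config flag for dropping motifs confounded by cross-line peak overlap
  exists at the pipeline level but requires module-to-peak provenance that
  the input formats do not carry; it warns and skips, and is documented as
  such.

# Problem sizes

The test-suite and acceptance simulations run the full default study
(8 lines, 60-motif library, 200 predicted motifs, 240 modules, ~1500 peaks)
across ten seeds, with 2000-score E-value calibrations and 199-replicate
resampling nulls; null-calibration property checks use 99-replicate nulls
over 200 repetitions on a 4-line study. These sizes give stable pass/fail
behaviour for every planted-recovery check while a complete run of the suite
stays comfortable on a single CPU.

# Known limitations

* E-values are library-relative; comparing E-values across differently sized
  or differently informative libraries is not meaningful.
* The Gaussian tail used beyond the empirical null resolution is an
  extrapolation; ordering of extreme matches is reliable, their absolute
  E-values are approximate.
* Indirect-pair extraction is quadratic in neighbourhood size and intended
  for TF-scale networks (hundreds of proteins), not proteome-scale graphs.
* The divergence regression inherits the instability of per-line fits over
  `nCellLines - 1` points; with fewer than ~6 lines its per-line R-squared
  values are noisy by construction.
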