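---
title: "Methods: junction-based cap mapping and capture enrichment for NAD-capped RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based cap mapping and capture enrichment for NAD-capped RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadcapr)
```

# Scope

`nadcapr` implements two complementary computational analyses of
non-canonically capped RNA in budding yeast, together with the synthetic-data
machinery needed to validate them end to end:

1. **circNC junction analysis** — nucleotide-precision mapping of
   cap-addition sites from circularized-RNA amplicon sequencing. Decapped
   (5'-monophosphate) RNA is circularized so that the transcript's 5' end is
   ligated to its 3' polyA tail; PCR across the junction and paired-end
   sequencing yield reads in which the polyA tract separates the transcript's
   3' end from its 5' end. Locating the tract and aligning both flanks back
   to the reference transcript reads off the cap-addition site, the 3'-end
   site and a tail-length estimate, read by read.
2. **Capture enrichment analysis** — classification of NAD-capped transcripts
   from gene-level counts of capture libraries versus standard RNA-seq,
   using a negative-binomial enrichment test and the twofold / q &le; 0.01
   decision rule, plus permutation and hypergeometric statistics for
   comparing the resulting gene catalogs.

Upstream read processing tools (quality trimming, pseudo-alignment) and
wet-lab steps are out of scope; counts and amplicon reads are the pipeline
inputs.

# The junction model

A circNC amplicon for a transcript with sequence $T$ (0-based coordinates)
is

$$ A \;=\; T[f \,..\, e] \;\Vert\; \mathrm{A}^{L} \;\Vert\; T[c \,..\, r), $$

where $f$ is the forward-primer start, $e$ the cleavage site (last templated
base), $L$ the polyA tail length, $c$ the cap-addition site and $r$ the
reverse-primer end. Read 1 is the amplicon prefix, read 2 the reverse
complement of its suffix; because UTR lengths vary, the junction can fall on
either mate, so read 1, read 2 and the best-overlap merge are processed as
three separate streams and the merged stream takes precedence in per-gene
summaries when it yields junction-spanning calls.

## PolyA run detection and the 8-A filter

A read is considered junction-spanning material when it contains a run of at
least 8 consecutive `A` (`find_polya_run()`, `filter_polya()`); the longest
maximal run is used, ties going to the leftmost. Reads with unresolved
orientation are also tested in reverse complement and flipped on a hit. The
run semantics are exact (no mismatches inside the run at the filtering
stage); lowering the threshold can only grow the passing set, which the test
suite asserts as a monotonicity property.

## Calling the junction

`call_junction()` splits the read at its polyA run and aligns the post-run
segment against the transcript's 5' region (up to the reverse-primer end)
and the pre-run segment against the 3' region (from the forward-primer
start), using a semi-global affine-gap aligner (`semiglobal_align()`): the
segment is aligned end to end while reference end gaps are free. The cap
site is the reference position aligned to the first base after the run, the
3'-end site the position aligned to the last base before it, and the tail
length the run-interval length.

Two practical complications shape the caller:

* **Templated adenosines at the junction.** If the reference base at the cap
  site is itself `A` (or the 3' flank ends in `A`), those bases are
  indistinguishable from the tail and are absorbed by the maximal run. The
  caller therefore reports the first post-run base as the cap site and emits
  up to 3 alternative upstream positions where the reference continues in
  `A` (`alt_cap_sites`). The simulator records the same homopolymer
  extensions in its truth tables (`cap_site_attr`, `polya_len_attr`), so
  recovery tests can be exact rather than approximate.
* **Substitution errors inside the tail.** A single sequencing error splits
  the A-run in two, and the longest fragment alone would misplace one
  junction boundary. The caller builds a small set of boundary candidates by
  bridging single non-A interruptions (up to 3 per side) and keeps the
  candidate whose flank alignment scores best, ties favouring the unextended
  run. The alignment itself arbitrates: for an error-free read the extra
  genuine bases of the unextended candidate always win, while for a
  tail-internal error the bridged candidate's clean flank wins. This keeps
  error-free calls exact and maintains high exact-recovery rates at the
  study's ~1% amplicon error scale.

Confidence is `high` when both flanks have &ge; 15 aligned bases at &ge; 0.9
identity, `low` when one flank qualifies (the qualifying site is still
reported), `none` otherwise. Classification (`classify_cap_site()`) then
compares the called site to the sense-strand reference base: an `A` is
consistent with the cap being incorporated as the initiating nucleotide
(ab initio), anything else implies post-transcriptional cap addition.

## Alignment parameters

The scoring defaults (match +2, mismatch &minus;3, gap open &minus;5, gap
extension &minus;2 per base; `N` always a mismatch) are ordinary short-read
alignment weights; none are critical, because junction flanks are
near-identical matches to their reference region. The aligner's traceback is
fully deterministic (diagonal preferred, then the query-consuming gap, then
the reference-consuming gap; smallest reference offset at the end), so
repeated runs produce byte-identical reports. The implementation is compiled
(Rcpp) and is checked in the test suite against exhaustive enumeration on
short sequences and against an independent pairwise aligner at read-scale
lengths.

## Report conventions

Internally all coordinates are 0-based half-open; user-facing report columns
are 1-based inclusive. Support fractions in the per-gene report use
junction-spanning reads (confidence `high` or `low`) of the same gene and
treatment as denominator — the most defensible choice given that percentages
could also be quoted against all reads of a library. Predominant sites per
cap class are support-weighted modes over high-confidence calls, and
`same_tss` flags whether the predominant NAD and m7G cap sites coincide.

# The enrichment model

Counts are assumed negative binomial with $\mathrm{Var}(K) = \mu + \alpha
\mu^2$. Samples are normalized by median-of-ratios size factors
(`size_factors()`), the standard differential-expression normalization,
re-implemented here and cross-checked in the tests against the reference
implementation. TPMs are recalculated from the rounded counts
(`recalc_tpm()`).

`nb_enrichment_test()` fits, per gene, a two-group NB log-linear model with
size-factor offsets by Newton iterations (the groups decouple, so each group
mean is a one-dimensional fit) and tests the capture-vs-control coefficient
with a two-sided Wald statistic; `bh_adjust()` applies Benjamini–Hochberg,
and `classify_capped()` applies the decision rule *log2 fold-change &ge; 1
and q &le; 0.01*, both boundaries inclusive. The module is deliberately a
functional stand-in for a full shrinkage-based pipeline: the scientific
content being reproduced is the classification rule, not shrunken effect
estimates, so no fold-change shrinkage is applied and the threshold is
applied to the raw estimate.

## Dispersion pooling

The dispersion default is a single **pooled (common) method-of-moments
estimate** across genes rather than independent per-gene estimates. With
triplicates, per-gene moment estimates of $\alpha$ are extremely noisy, and
plugging them into a normal-reference Wald test is substantially
anticonservative; switching the reference to a $t$ with the within-group
degrees of freedom restores calibration but then BH-adjusted significance at
q &le; 0.01 becomes unreachable at realistic effect sizes, collapsing power.
Pooling across a couple of thousand genes makes the dispersion effectively
known, and the package's null-calibration property (the fraction of null
genes at p &le; 0.05 stays within binomial noise of 0.05) holds at the
simulated study scale. Per-gene estimation remains available via
`dispersion_mode = "per_gene_mom"` for data whose dispersions genuinely vary
across genes, with the caveat above. Genes with fewer than 10 total counts
are filtered before testing; all-zero groups enter the fold-change with a
half-count shift rather than a degenerate maximum-likelihood estimate.

## Abundance comparison

`compare_abundance()` is a one-sided Welch $t$-test on log(TPM + 1),
testing whether one identified transcript set sits at lower abundance than
another — the comparison used to show that removing canonical-capped
background lets a capture method reach low-abundance transcripts.

# Overlap statistics

`permutation_overlap()` keeps both set sizes fixed and redraws the identity
of each set's members independently and uniformly from the universe, 10,000
times by default, reporting the permutation mean and SD of the intersection
and an add-one empirical upper-tail p (never exactly zero).
`hypergeom_overlap()` provides the closed-form counterpart (mean $n_1 n_2 /
N$; hypergeometric variance), which the permutation must match within Monte
Carlo error — an internal consistency check the acceptance tests enforce.
`chi2_independence()` is the Pearson test without continuity correction on
the 2×2 membership table. The randomization universe is a modelling choice
the original analysis leaves open; the package defaults to all genes tested
for enrichment (nonzero total count), and any explicit universe can be
supplied.

# The synthetic-data generator

The generator exists so that every stage has ground truth:

* `simulate_transcriptome()` draws uniform-random sequences with UTR/CDS
  segment lengths in configurable ranges, distinct predominant NAD and m7G
  cap sites inside the 5' UTR (the two cap classes were observed to start at
  different positions), cleavage sites at the transcript end, and primer
  intervals giving amplicons of a few hundred bases. Genomic A-homopolymers
  are capped at 6 nt so a planted tail is always the dominant run.
* `simulate_circ_reads()` builds amplicons exactly per the junction model,
  draws tail lengths from a truncated normal (default mean 30, SD 8, minimum
  12 — kept above the 8-A filter; tail-length distributions are not reported
  for the original libraries, so these are plausible defaults, not
  estimates), and applies uniform substitution errors. Truth tables carry
  planted coordinates, junction-edge homopolymer extensions, error counts
  and junction-spanning annotations.
* `simulate_counts()` draws log-normal expression levels, rescales each
  condition to the library depth (so capture libraries show the real
  compositional shift that median-of-ratios must undo), multiplies planted
  genes by $2^{\mathrm{lfc}}$ in the capture condition and samples NB
  counts in biological triplicate. When the planted set is given as a count,
  genes are drawn from those with expected control counts of at least 100,
  since enrichment below the counting-noise floor is unrecoverable by any
  test.
* `simulate_gene_sets()` produces two sets with an exact forced overlap, the
  fixture for the overlap statistics.

What the generator does **not** emulate: PCR duplicates, instrument-specific
quality profiles, indels (substitutions only by default), cross-reactivity
of the capture chemistry (available only as a contamination-fraction style
manipulation of planted sets), and real transcriptome sequence composition.
Passing tests therefore demonstrate algorithmic correctness under the stated
error model, not robustness to every artefact of real libraries.

# Numerical and design choices

* Coordinates 0-based half-open internally, 1-based inclusive in reports.
* Read-pair merging scans every admissible suffix/prefix overlap
  (&ge; 12 nt, mismatch fraction &le; 0.1) and keeps the highest-scoring
  one, ties to the longest; read-1 bases win conflicts since no per-base
  qualities are carried.
* Unique-read ranking breaks count ties lexicographically; its counts
  conserve the number of input reads.
* Dispersion floor $10^{-8}$; Wald p-values floored at the smallest positive
  double; empirical permutation p uses the add-one rule.
* All stochastic functions take explicit seeds and restore the caller's RNG
  state; identical seeds give byte-identical outputs, which the suite
  asserts for both pipelines end to end.
* Problem sizes used by the validation suite — 5 transcripts × 1,000 read
  pairs per error rate for junction recovery, 2,000 genes × (3+3) replicates
  × 10–20 seeds for enrichment, 10,000 permutation iterations at set sizes
  268/769 in a universe of 6,000 — were chosen as the smallest scales at
  which the stochastic properties of interest are measurable with
  comfortable margins.

# Known limitations

* The enrichment test is not a drop-in replacement for shrinkage-based
  differential pipelines; with very few genes the pooled dispersion is
  itself noisy, and per-gene mode should be interpreted with its
  anticonservativeness in mind.
* Junction calls assume the supplied transcript model is the correct source;
  cross-mapping between paralogous amplicons is not modelled.
* A cap site on a templated adenosine is reported at the first post-run base
  with ambiguity flags; without orthogonal information the true start within
  the flagged A-tract is undecidable from circNC reads alone.
* The minus-ADPRC background-control libraries of the capture assay are
  accepted as a condition label but only reported descriptively; they do not
  enter the test design.
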