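---
title: "Quantifying read-level DNA methylation heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying read-level DNA methylation heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methentropy)
library(tibble)
```

## The problem

A bulk bisulfite experiment reports, per CpG, the methylated fraction over
all sampled cells. Two very different populations produce the same 50%
figure: a homogeneous population in which every cell is half methylated at
random, and a mixture in which half the cells are fully methylated and half
fully unmethylated. The difference matters wherever subpopulations are
biologically expected — multipotent stem-cell cultures, reprogrammed iPSC
colonies picked from few founder cells, tissues with mixed cell types — and
it is recoverable, because every sequenced fragment is a haplotype-level
observation of one cell's methylation pattern.

`methentropy` works entirely at this read-pattern level. This vignette
explains the model, every tunable constant and why its default is what it
is, the synthetic population used for validation, and the numerical
decisions taken where the design was genuinely open.

## Segments and scores

### Four-CpG windows at sixteen reads

The unit of analysis is a window of **4 consecutive CpGs** (consecutive in
the CpG index of the reference, however far apart in base pairs), scanned
with a slide of one CpG so that windows overlap. A fragment contributes to a
window only if it carries unambiguous calls at *all four* positions — the
pattern space has 2⁴ = 16 outcomes and partially observed patterns cannot be
assigned without imputation, which we refuse. A window is emitted when at
least `min_reads = 16` fragments qualify: sixteen is the smallest depth at
which every one of the 16 patterns could in principle be observed, and it
matches typical whole-genome bisulfite coverage (15–30×). Wider windows
scale badly — five CpGs would need 32 reads — which is why the width is
fixed at 4 by default and configurable rather than adaptive.

The genomic span of a window runs from the first C to one base past the
last C's G (`[cpg1, cpg4 + 2)`), so interval operations see both bases of
the terminal CpG. All internal coordinates are 0-based half-open; the
Bismark input dialect (1-based) is converted on read, and the two strand
cytosines of one CpG are collapsed to a single unit at the forward-strand C
(methylation of CpG is symmetric; a flag disables collapsing for
strand-resolved work).

### Level, entropy, weighted entropy

With pattern counts $n_i$, $N = \sum_i n_i$ reads and $b = 4$ sites:

$$L = \frac{\sum_i n_i\, m_i}{bN}, \qquad
  ME = \frac{1}{b} \sum_{i:\,n_i>0} -\frac{n_i}{N}\log_2 \frac{n_i}{N},
  \qquad
  WME = \frac{1}{b} \sum_{i:\,n_i>0} t_i \left(-\frac{n_i}{N}\log_2
  \frac{n_i}{N}\right)$$

where $m_i$ is the number of methylated sites in pattern $i$ and $t_i$ its
number of adjacent state transitions (0 for MMMM and UUUU, 3 for MUMU). The
$1/b$ normalisation puts $ME$ on $[0, 1]$ for $N \ge 16$: 0 iff a single
pattern is observed, 1 at uniform use of all 16. We define
$0 \log 0 = 0$ and use log base 2 throughout.

Two decisions here were open and are ours:

* **No renormalisation of the transition weights.** $WME$ multiplies each
  Shannon term by $t_i$ inside the sum, without dividing by $\sum_i t_i$.
  This makes a *purely bipolar* segment — only all-M and all-U reads —
  score exactly 0, the extreme the downstream detection is built around; a
  renormalised version would be undefined there (total weight 0).
* **Entropy is a function of the count multiset only.** Pattern identity
  enters $L$ and $WME$ but not $ME$; the test suite checks this invariance
  and verifies all three scores against a string-based brute-force oracle,
  exhaustively over every pattern multiset up to $N = 5$ (and every count
  partition up to $N = 8$ for $ME$).

A useful symmetry used in testing: complementing every call (M↔U) leaves
$ME$, $WME$ and each $t_i$ unchanged and maps $L \mapsto 1 - L$.

## The level-preserving null

Whether an observed pattern distribution is "structured" must be judged
against what random methylation would produce *at the same level and
depth*, since $ME$ is strongly level- and depth-dependent. The null
rearranges the $bN$ binary calls uniformly at random, keeping the
methylated-call count $M$ exactly fixed (we carry the observed integer $M$,
not a re-rounded level), and re-tabulates patterns. Per segment we draw
`n_reps = 1000` replicates and report:

* the **median null entropy** — the entropy a stochastic segment of this
  level/depth would show; and
* the **p-value**: the fraction of replicates with simulated $WME$
  *strictly below* the observed one.

Strictness is deliberate and has a consequence worth stating plainly: ties
are not counted, so any segment whose observed $WME$ sits on the minimum
atom of its null distribution gets $p = 0$ — including every single-pattern
segment. The detection pipeline therefore applies the bipolar-read
preselection *before* the p-value filter; the p-value is meaningful only on
segments that already show both extremes. Where the null distribution is
coarse (levels near 0 or 1), the strict-inequality estimator is granular;
the tie-inclusive count is the classically calibrated quantity, and the
acceptance suite checks calibration (stochastic dominance over uniform) on
that estimator while asserting the strict one is non-significant for the
large majority of null-generated segments.

Each segment owns an RNG stream seeded from the global seed and the segment
key (chromosome + CpG positions, via a 31-bit polynomial hash), so results
are independent of row order and of how work is chunked.

`downsample_reads()` supports the companion depth-normalisation analysis:
keeping `round(fraction · N)` reads without replacement (e.g. 20 of 28,
71.4%) and recomputing entropy quantifies how much of a between-sample
entropy difference is attributable to depth alone.

## Bipolar detection pipeline

Steps, in order, with their constants:

1. **Bipolar preselection**: keep segments with ≥ 1 all-M *and* ≥ 1 all-U
   read.
2. **Null p-values** on those segments (1,000 reps).
3. **Confounder and noise filters**: remove segments overlapping a supplied
   allele-specific-methylation (ASM) catalogue by ≥ 1 bp — imprinted and
   other allelic loci produce the identical read signature from a
   homogeneous population — and segments with $p > 0.05$ ($p = 0.05$
   retained, the removal condition being strictly "greater").
4. **Region merging**: transitive merge of spans overlapping or within 1 bp.
5. **Promoter association**: promoter = 1 kb upstream to 200 bp downstream
   of the TSS, strand-reflected for minus-strand transcripts (TSS taken at
   `txStart`/`txEnd`); transcripts sharing a gene symbol contribute the
   union of their promoters; ≥ 1 bp overlap qualifies; regions inside one
   promoter are merged regardless of gap.
6. **CpG-count filter**: genes whose promoter union holds fewer than 10
   indexed CpGs are dropped — with four-CpG windows, CpG-poor promoters
   cannot be interrogated reliably.

Every step is exposed as its own verb (`select_bipolar()`, `filter_asm()`,
`filter_stochastic()`, `merge_regions()`, `associate_promoters()`,
`filter_low_cpg()`), each tibble-in/tibble-out, and
`run_bipolar_pipeline()` chains them and logs per-step counts, which are
monotonically non-increasing by construction.

Note the package carries **two promoter definitions**, deliberately:
`promoter_1kb` (1 kb upstream only) is the feature class used for
stratified summaries, while the detection pipeline uses the −1000/+200
window. They serve different purposes and are named apart rather than
silently unified.

## Genomic stratification and expression profiles

`build_features()` derives promoter/UTR/exon/intron classes from a
RefSeq-style table, repeat classes from a RepeatMasker-style table, and CpG
islands with **shores** (2 kb flanks minus islands) and **shelves** (2–4 kb
flanks minus islands and shores), overlapping islands merged first and all
bands clipped against neighbouring islands, so island/shore/shelf never
overlap. Segments join *every* class they overlap by ≥ 1 bp (classes are
not exclusive; a segment is counted once per class), and unmatched segments
are labelled `intergenic`.

`classify_level()` uses strict thresholds: hypermethylated above 0.8,
hypomethylated below 0.2 — boundary values are intermediate.

For expression, genes are ranked into five equal-sized quintiles (5 =
highest; zero-expression genes fall to quintile 1; ties broken by stable
input order, sizes differing by at most one). `tss_profile()` averages
segment level and entropy in 100 bp bins of midpoint position relative to
the TSS, strand-oriented (upstream negative), over a ±3 kb span. Midpoint
assignment was chosen over overlap-weighting for transparency — a segment
lands in exactly one bin — and empty bins are reported as absent, never as
zero. The ±3 kb span and 100 bp bin width are configurable.

## The synthetic population

Real methylomes at this scale require cluster resources and archive
downloads, so validation runs on a generator whose defaults *are* the study
conditions, fixed once:

* **50 loci × 13 CpGs** (25 bp spacing) = 10 overlapping four-CpG windows
  per locus, 500 windows total; loci 3 kb apart so each sits in exactly one
  gene's promoter (one plus-strand gene per locus, TSS 100 bp past the
  locus, so the −1000/+200 promoter holds all 13 CpGs — comfortably over
  the 10-CpG filter).
* **Depth**: Poisson with mean 20 fragments per window, emulating the
  16–30× range of real data; windows below 16 reads are dropped by the
  scanner exactly as in real data (~16% at this depth).
* **Two equal subpopulations**; locus labels 20 cell-subset-specific
  (probability 1 in one subpopulation, 0 in the other), 10 uniform-hypo
  (per-CpG probability 0.02), 10 uniform-hyper (0.98), 5 allele-specific
  (each fragment draws one of two opposite-state alleles at 50/50), 5
  stochastic-intermediate (every call a fair coin).
* **Noise**: every call flips with probability 0.01, a realistic aggregate
  of bisulfite conversion failure and sequencing error; the flip is
  symmetric (non-conversion asymmetry is a documented extension, off by
  default).
* All randomness flows from the single spec seed; generated files embed the
  seed in a header comment.

Fragments span exactly one window, so window depth maps directly to the
depth parameter and windows are independent. This is the one structural
simplification versus real fragments (75 bp paired-end reads can span more
than four CpGs); the overlapping-window scanner is exercised separately by
toy fixtures with longer fragments.

What passing on this population demonstrates — and what it does not: the
generator plants clean two-state mixtures, so recovering ≥ 95% of planted
cell-subset-specific genes with zero calls from uniform loci validates the
*machinery* (segmentation, scores, null, filters, promoter logic), not
robustness to partial subpopulation fractions, three-way mixtures, sparse
or uneven CpG spacing, or mapping artefacts, none of which the generator
emulates. ASM loci are statistically indistinguishable from
cell-subset-specific loci by construction — that is precisely why the
pipeline requires an external ASM catalogue, and the generator's truth
regions double as one in tests.

Expected values on this population are closed-form where it matters: a
50/50 two-state locus at depth $N$ has $ME = H_2(k/N)/4$ with
$k \sim \mathrm{Bin}(N, 1/2)$, mean just below the 0.25 ceiling, and the
test suite compares against that expression rather than a round number.

## Numerical choices and degenerate inputs

* Entropy terms use `ifelse(p > 0, -p log2 p, 0)`; no epsilon smoothing.
* P-value comparisons subtract 1e-12 before the strict `<` to absorb
  floating-point noise in ties.
* $N = 0$ segments are an error (`level`/`entropy` undefined), not NA.
* Mate pairs sharing a read id are one fragment; concordant duplicate calls
  at a CpG collapse to one, discordant calls discard that position for that
  fragment (the conservative option; the alternative — trusting one mate —
  has no principled basis).
* Merging is idempotent and order-independent (inputs are sorted first);
  gaps are measured in half-open coordinates, so spans `[100,140)` and
  `[141,180)` are 1 bp apart and merge at the default gap.
* Expression quintile boundaries use `ceiling(rank · 5 / n)` on
  first-occurrence ranks: deterministic, stable under ties, sizes within 1.

## Problem sizes

The shipped tests run the full stack at the sizes above: exhaustive oracle
comparisons to ~20,000 count vectors, 500-segment/1,000-replicate null
calibration, the 500-window recovery run, and bit-identity of two complete
workflow reruns — about a minute altogether on one core. The acceptance
script (`scripts/acceptance.R`) regenerates the study population and
recomputes every headline quantity in ~12 s.

## Limitations

* Window width is fixed per run; cross-width comparisons need separate runs
  and care with the depth threshold (2^b reads for width $b$).
* The p-value is Monte-Carlo with no multiple-testing correction, matching
  the detection pipeline's design (the bipolar preselection is the primary
  specificity device); FDR control across millions of segments would need
  an analytic null.
* Entropy at depth near the threshold is biased low (fewer reads than
  patterns); comparisons across samples of very different depth should use
  `downsample_reads()`.
* The collapse of CpG strands assumes symmetric methylation; hemimethylated
  DNA (e.g. at replication forks) is invisible by design unless collapsing
  is disabled.
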