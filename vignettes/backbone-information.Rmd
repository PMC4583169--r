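---
title: "Information content of DNA backbone dynamics: models and design choices"
author: "trxlogo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information content of DNA backbone dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxlogo)
```

## The model

A set of `n` center-aligned DNA sequences of common length `L` defines two
positional alphabets. At each base position `i` the symbols are the four
nucleobases; at each phosphate linkage `j` (between bases `j` and `j+1`)
the symbol is the TRX flexibility state of the dinucleotide step. The TRX
scale gives the percentage of time a step's phosphate linkage occupies the
BII backbone conformation in free solution; it runs from 0 (ApT) to 43
(CpG), rises with GC content, and assigns one value per strand-symmetric
dinucleotide class. Ten classes carry nine distinct values — two classes
(CpA/TpG and GpC in the shipped table) share one score — so the linkage
alphabet has exactly `k = 9` states.

Information content at any position is Shannon's

$$IC_i = \log_2 k - H_i, \qquad
  H_i = -\sum_{s=1}^{k} p_{s,i}\,\log_2 p_{s,i},$$

with `p_{s,i}` the relative frequency of symbol `s` among the sequences at
position `i` and `0·log 0 := 0`. Logarithms are base 2 throughout so that
IC is in bits and the caps take their conventional values: 2.0 bits for
bases, `log2(9) ≈ 3.17` bits for linkage states. For display — and for any
comparison of the two alphabets on a common scale — linkage IC is rescaled
linearly so that `log2(9)` maps to 2.0 bits. Because symbol identity is
the *score* rather than the class, a mixture of CpA/TpG and GpC steps at
one linkage is a single state at frequency 1 (IC at cap); an implementation
using ten states would see entropy there, and a regression test pins this
down.

An important consequence of the unequal class sizes is an IC floor:
i.i.d.-uniform DNA does not drive linkage IC to zero but to
`log2(9) − H(class sizes/16) ≈ 0.092` bits. Every "no structure" baseline
in the package is therefore compared against matched random DNA rather
than against zero.

The plot is a standard stacked-letter logo (letter height = frequency ×
column IC, most frequent letter on top) with a gray bar at each linkage:
bar height is the normalized linkage IC and bar fill maps mean TRX
linearly onto a gray ramp, black (0, stiff) to white (43, flexible). Bars
are drawn behind the letters and outlined in black so near-white bars stay
visible.

## Tunable parameters

* `TRXScale(file)` — the scale ships as an editable three-column text
  table (class, member dimers, score) and is validated at load: 10
  strand-symmetric classes, 9 distinct scores, minimum 0, maximum 43,
  exactly one shared-score pair, positive rank correlation with GC
  content. Alternative flexibility tables can be supplied provided they
  satisfy the same structure.
* `logoProfile(..., correction = FALSE)` — optional small-sample
  correction subtracting the classical `(k−1)/(2·ln 2·n)` bias from IC.
  Off by default: the plain `log2(k) − H` definition is what the display
  caps assume, and all internal comparisons contrast regions of equal `n`,
  where the bias cancels.
* `LogoStyle(barStart = 1.5, barIncrement = 1, barWidth = 0.35)` — bar
  geometry in column units, replacing the interactive adjustment console
  of older logo tools with reproducible configuration. Defaults suit
  motifs around 20 bp.
* `compareICRegions(..., useNormalized = TRUE, paired = FALSE)` — the
  base-vs-linkage comparison defaults to a Welch two-sample t-test on the
  normalized scale. Positions (`L`) and linkages (`L−1`) are offset sets
  of different sizes, so the unpaired test is the default; a paired option
  (position `i` with linkage `i`) is available. Whether such comparisons
  should use raw or normalized linkage bits is genuinely open; normalized
  is the default because it puts both alphabets under a common 2.0-bit
  cap, and the raw scale remains one flag away.
* `bonferroniDecisions(p, alpha = 0.05)` — family-wise control at
  `alpha/m`; the per-test level before correction is 0.05 and tests are
  two-sided by default.

## Input dialects and alignment conventions

Three dialects are read: plain text (one pre-aligned sequence per line),
FASTA (whole-record center alignment: every record is trimmed to the
shortest record's span about its own midpoint), and JASPAR-style FASTA
(uppercase motif core, lowercase flanks; records are aligned on motif
centers and flanks trimmed to the largest width available in all records
— trimming, never padding, so no sequence is ever fabricated). For
even-length spans the center is taken left-of-middle, `floor((L+1)/2)`,
consistently in both dialects. Coordinates are 1-based; linkage `j` sits
between bases `j` and `j+1`. Gap characters are stripped before
alignment; any other non-ACGT character becomes `N`, which occupies its
column but is excluded from the frequency counts of that column and of
both adjacent linkages. If uppercase motifs differ in length within one
JASPAR file, the common span is kept with a warning.

## Codon-phase analysis

For a gene set aligned at the start codon (anchor = the A of ATG, codon
position 1), per-linkage IC is bucketed period-3 into four codon-bridging
phases: `x-1` (last base of the preceding codon to position 1), `1-2`,
`2-3` (internal), and `3-z` (position 3 to the next codon). The start
codon is part of the coding region and is included in the buckets. Two
points deserve emphasis:

* In a contiguous reading frame the interior `x-1` and `3-z` linkages are
  the *same physical steps* viewed from adjacent codons; the two phases
  differ only at the window boundaries (the UTR-to-ATG junction belongs
  only to `x-1`). They become genuinely distinct linkages in the
  codon-context scan, where each codon is flanked by random triplets.
* Under uniform usage of the 61 sense codons the code-structure signal is
  subtle and not uniformly ordered: the theoretical raw linkage IC is
  0.125 bits at `1-2`, 0.091 at `2-3` and 0.108 at inter-codon steps
  (against the 0.092 uniform-DNA floor) — the `1-2` step, which joins the
  two bases most determinative of amino-acid identity, is the informative
  one. The aggregate internal-exceeds-external ordering of the phase
  means relies on the fully conserved start codon being part of the
  window, as it is in a start-aligned gene scan. Realistic (non-uniform)
  codon usage strengthens all of these contrasts.

`bootstrapANOVA()` draws `nSets = 100` subsets of `setSize = 10` genes
with replacement (the resampling scheme is a required, logged parameter —
with or without replacement is a genuine choice; with-replacement is the
bootstrap convention), computes per-subset phase means, and runs a one-way
ANOVA across the four phase groups. Because the subsets resample one fixed
gene pool, the replicates are not independent: set means within a phase
share pool-level sampling noise, and in a contiguous frame two of the four
groups share physical linkages. The null distribution of its p-value is
therefore *not* uniform — measured on uniform-base pools of 200 genes ×
300 coding bp the rejection rate at 0.05 is ≈ 0.005 (conservative), while
small pools (tens of genes) push it above 0.1 (anti-conservative). The
statistic is reported exactly as defined because it is the procedure this
package implements, but its p-values should be read as descriptive, not
calibrated; the acceptance suite records this calibration failure
honestly rather than repairing it post hoc.

## Synthetic data generators

`generateTFBS()` emulates a collection of genomic matches to a consensus:
motif base `i` is drawn uniformly from the IUPAC-consistent set with
probability `conservation`, otherwise uniformly from the complementary
bases — a deliberately simple substitution model, sufficient to exercise
the IC mathematics with a single interpretable knob. Flanks are i.i.d.
with a configurable GC fraction (default 0.5); the default flank length
is 7 bp, with 25 bp as the wide-flank preset. `generateCodingSet()` emits
genes as a uniform-composition UTR (default 25 bp) + ATG + codons sampled
i.i.d. from a usage table over the 61 sense codons (uniform by default,
configurable).

What the generators do *not* emulate: phylogenetic correlation between
sites, dinucleotide composition biases of real flanks, positional
heterogeneity of conservation, and codon autocorrelation along real
genes. Passing tests on these fixtures therefore demonstrate the
correctness of the computations and the qualitative code-organization
effects, not the genome-scale magnitudes obtainable only from real
alignment data (the pipeline accepts such data as FASTA when the user
supplies it).

## Numerical choices and degenerate inputs

* `0·log 0 := 0` exactly; entropy sums run over positive frequencies only.
* Frequency-column validation tolerance 1e-9; oracle agreement asserted at
  1e-12; IC+H identity holds to 1e-12.
* Columns or linkages with no N-free observation are flagged through their
  effective counts, carry IC 0, and render as zero height.
* One-way ANOVAs with essentially zero residual variance (e.g. a
  single-gene phase scan, where every linkage IC equals `log2 9`) return
  `NA` rather than an unstable F.
* Letter stacking breaks frequency ties alphabetically, so rendering is
  fully deterministic; SVG output contains no timestamps and identical
  profile + style give byte-identical files.
* Problem sizes used by the verification suite: oracle equivalence on 100
  sets of up to 5 × 6 bases; codon-phase analysis on 200 genes × 100
  codons with a 100 × 10 bootstrap; null calibration on 200 replicates of
  the same geometry; generator recovery at n = 5000 sequences per
  conservation level.

## Known limitations

The TRX scale is dinucleotide-based and deliberately ignores higher-order
(trimer/tetramer) flexibility effects. The numeric per-class scores are
transcribed constants and editable; analyses that depend only on the
class partition (all IC values) are unaffected by score perturbations,
while mean-TRX shading is. Center alignment is purely positional — no
similarity-based alignment is performed anywhere. The bootstrap ANOVA's
calibration caveat above is structural, not an implementation artifact.
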