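---
title: "Strand compositional asymmetry along genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand compositional asymmetry along genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(skewscape)
```

## The statistic

Within one DNA strand, Chargaff's second parity rule says G ≈ C and
A ≈ T. Departures from it are measured by the *GC skew*,
(G − C)/(G + C), and the *AT skew*, (A − T)/(A + T): symmetric
statistics ranging from −1 (all C, resp. all T) to +1 (all G, resp.
all A). In many unicellular fungi the coding strand of genes is
C-biased near the translation start and G-biased near the stop, with
an intermediate level in between — a signature plausibly linked to
transcription-coupled mutation or repair, since the two strands sit
in different environments while RNA polymerase II transits a gene.

Everything in this package is built on counting A, C, G, T in some
set of positions and forming these two ratios. Three conventions are
applied uniformly:

* **Undefined means missing.** When a window contains no G and no C
  the GC skew does not exist; it is reported as `NA`, excluded from
  averages, and never coerced to 0.
* **Ambiguity codes never count.** N and other IUPAC ambiguity codes
  are retained in sequences but enter no numerator or denominator.
* **Pooling means summed counts.** A profile value at an offset or
  bin is the skew of the counts pooled over genes ("total skew per
  position"), not the average of per-gene ratios. At single-base
  offsets the two definitions coincide algebraically; for bins they
  differ, and a mean-of-genes mode is available in
  `binned_metagene(mode = "mean")` for sensitivity analysis.

## Profile representations

`superposed_profile()` aligns all genes at the start or stop codon
and computes the pooled skew per base-pair offset. Offset 0 is the A
of the ATG (start anchor) or the first base after the stop codon
(stop anchor), so the stop codon itself occupies offsets −3..−1. On
any strict-ORF set the G of the ATG gives skew exactly 1 — a built-in
sanity check the test suite and the acceptance analysis both exploit.
Optional post-processing, in fixed order: codon averaging (each
coding-side value replaced by its codon-triplet mean, frame taken
from the anchor) and then a centred moving average of `smooth_bp`
bases. Both default off; when smoothing is wanted, 9 bp is a mild,
visually stable choice.

`binned_metagene()` divides each gene body into `n_bins` bins
(default 40): base *i* (0-based) of a gene of length *L* goes to bin
`floor(i * n_bins / L)`, so every base lands in exactly one bin with
no length bias, and the 200-bp flanks are profiled position-wise.
`sliding_track()` produces a chromosomal skew track (default window
2000 bp, step window/10), exportable as bedGraph.

## The per-gene permutation test

Whether one gene's skew changes 5'→3' is tested against a uniform
mononucleotide shuffle of its CDS. The statistic is
Δ = skew(last 100 bp) − skew(first 100 bp); the null distribution
comes from 1000 shuffles, and the gene is called significant when the
add-one empirical p, (1 + #{Δ_null ≥ Δ_obs})/(1 + n), is ≤ 0.05.
Because the phenomenon under study is an *increase* of skew toward
the 3' end, the default is one-sided; `alternative = "two.sided"`
switches to |Δ|. Each shuffle is realised by drawing 2 × 100 distinct
positions without replacement — a uniform permutation restricted to
the two windows has exactly that law, so this is an algebraic
shortcut, not an approximation. The windows include the ATG and stop
codon by default; `exclude_anchors = TRUE` removes the first and last
codon first, since their composition is fixed by the genetic code.
Shuffles whose Δ is undefined (possible only in degenerate, nearly
G/C-free sequences) are excluded from numerator and denominator
alike.

Mononucleotide shuffling is the minimal null: it preserves overall
composition and nothing else. Codon- or dinucleotide-preserving
shuffles would test sharper hypotheses and are deliberately not
defaults.

## The three-line model

Across a large gene set, the pooled skew along genes is summarised by
a piecewise-linear model with five parameters: the central level *c*;
the skew offset *a* at the ATG (so the model value at the ATG is
*c + a*) decaying linearly over the first *b* bp; and the offset *e*
at the stop, reached linearly over the final *d* bp. It is fitted on
three pooled 750-bp skew series — anchored at the ATG, at the gene
centres, and at the stops. *c* is simply the mean of the central
series. The other four parameters minimise the summed squared error
by exhaustive enumeration over declared grids (defaults: *a*, *e*
from −1 to 1 in steps of 0.01; *b*, *d* from 0 to 750 in steps of
10 bp). Given *c*, the 5' and 3' terms share nothing, so the search
factorises into two independent enumerations — a speed-up that leaves
the optimum unchanged; the naive quadruple loop is retained in the
test suite as the oracle. Ties are broken toward the shortest ramp
(smallest *b*, then *d*), and a zero-length ramp means "no ramp"
(amplitude forced to 0). The error is computed on per-position pooled
skews, not per-gene values, matching how the profiles themselves are
defined.

## Terminal composition biases

Because the skew gradient spans coding sequence, it reshapes protein
N- and C-termini. `terminal_aa_bias()` translates the first 21 codons
and the 20 codons before the stop of every eligible gene, and for
each residue forms the 5'/3' frequency ratio, the mean GC skew of its
codons (uniform weights over synonymous codons by default; usage
weighting optional), and a 2×2 chi-square p-value (this residue vs
all others × 5' vs 3' window, no continuity correction; an expected
count below 5 raises a warning rather than switching tests). A
per-residue 2×2 table, rather than one global residues × windows
test, is used so each residue gets its own p-value. The initiator
methionine is fixed by the code, not chosen; `drop_initial_met`
excludes codon 1 from the Met count. Both the standard nuclear code
and the alternative yeast nuclear code (CTG → Ser, relevant for
*Candida albicans* and relatives) are available; the standard code is
the default, and fourfold-degenerate codon families are derived from
whichever table is active rather than hard-coded.

## The synthetic generator

`generate_genes()` draws gene sets whose coding-strand composition
follows a known three-line GC-skew law plus a constant AT skew: at
each position the target skew *s* maps to
P(G) = gc·(1+s)/2, P(C) = gc·(1−s)/2, and analogously for A/T.
Defaults describe a strongly skewed fungal-like gene set: 2000 genes
of 1500 bp, GC content 0.40, (a, b, c, d, e) = (−0.3, 300, 0.1, 200,
0.2), AT skew +0.10, promoter flank skew −0.3, 3'-flank skew +0.2,
and per-gene, per-position Gaussian skew noise of sd 0.02 emulating
gene-to-gene heterogeneity. The flank values reflect the empirical
pattern that the strongest C-bias sits in promoters and the 3' G-bias
extends into the UTR; the AT skew is positive and weaker than the GC
skew, as observed in real fungal gene sets.

In codon mode (default) the first codon is set to ATG, the last to a
uniformly drawn stop, and in-frame internal stops are resampled from
the local base probabilities until none remain. Two consequences are
worth knowing. First, the anchor codons are deterministic, which
reproduces the trivial +1 skews at the exact start/stop positions
seen in real data. Second, rejecting internal stop codons (which
contain G but never C) depletes G slightly — about 0.03 of skew at
the default composition. For this reason analyses that probe the
three-line *law itself* — notably the parameter-recovery validation —
use `codon_mode = FALSE`, where the realised composition matches the
target exactly; analyses that need strict ORFs (translation windows,
profile anchors) use codon mode. `generate_null_genes()` produces the
fully position-homogeneous i.i.d. control set used for type-I
calibration, and `emit_genome()` writes a gene set onto a contig
(FASTA + GFF3, random strands, configurable spacers) such that
re-extraction reproduces the genes byte-exactly.

What the generator does *not* emulate: codon-usage structure beyond
stop avoidance, intron/exon architecture, neighbour-dependent
substitution processes, chromosomal heterogeneity, and any coupling
between skew and GC content unless induced via the covariate helper.
Passing tests on synthetic data therefore validate the machinery and
its statistical calibration, not biological conclusions about any
particular genome.

## Correlation analyses

`local_skew_correlation()` computes, per gene-body bin, the Pearson
correlation across genes between local GC skew and local AT skew (or
GC content), with pairwise exclusion of undefined bins and `NA`
whenever fewer than three complete pairs or a constant vector remain.
`species_scatter()` correlates overall AT against GC skew across
species tables. `expression_correlation()` correlates per-gene
expression with the GC skew of the first and last 75 CDS bases;
expression is rank-transformed by default because RNA-seq levels are
heavy-tailed (`rank_transform = FALSE` gives raw Pearson), and
p-values come from label permutation rather than the t
approximation. `methylation_association()` runs a one-sided Welch
t-test of whether methylated genes have greater end-window skew than
the remainder — Welch because equal variances are not worth assuming
— plus the level–skew correlation inside the methylated set. End
windows are taken from the CDS ends by default; `use_flanks = TRUE`
in `gene_summaries()` switches to the annotated flanks where UTR
windows are wanted instead.

## Numerical and degenerate-input choices

* Bin assignment uses integer arithmetic (`(i * n_bins) %/% L`), so
  floating-point rounding can never move a boundary base.
* Empirical p-values use the add-one rule and are never exactly 0.
* Grid fits break ties deterministically (shortest ramp first), so
  refitting is reproducible even on pathological flat inputs.
* Genes too short for a requested window (permutation test, terminal
  windows, strict region building) are excluded and counted, never
  silently padded.
* All generator and test randomness flows from explicit seeds; the
  observed statistic of the permutation test never depends on the
  seed, only the null draws do.

## Problem sizes used in validation

The packaged validation suite runs entirely on synthetic data built
at call time: type-I calibration of the shuffle test on 2000 null
genes of 600 bp (GC 0.40, 1000 shuffles, expecting the nominal 5%
rate within a 99% binomial band), three-line parameter recovery on
2000 genes of 1500 bp with noise sd 0.02 across 20 seeds (a, c, e
within ±0.03; b, d within ±20 bp), oracle equivalence on 100-gene
instances with coarse grids, and byte-exact genome round trips for
100 mixed-strand genes. These sizes give comfortable statistical
resolution for every claimed tolerance while keeping a full run in
the low minutes on a single core.

## A worked example

```{r example}
spec <- synthetic_spec(n_genes = 400, length = 900, seed = 42)
genes <- generate_genes(spec)
genes

bm <- binned_metagene(genes, n_bins = 40, flank_bp = 200)
bm

fit <- fit_three_line(build_regions(genes, region_len = 300))
fit

sf <- significant_fraction(genes, end_bp = 100, n_shuffles = 200,
                           seed = 42)
sf
```

The fitted parameters approximate the generator's (the 300-bp region
truncates the full ramp geometry, and codon-mode anchor effects nudge
the boundary estimates), and a large majority of genes carry a
detectable 5'→3' skew increase, as engineered.

```{r plot, fig.width = 6, fig.height = 4}
plot(bm, main = "Synthetic gene set: binned GC-skew metagene")
```

## Known limitations

* Multi-part CDS records are concatenated; exon-junction effects and
  trans-splicing are out of scope, as are fuzzy coordinates.
* The permutation test treats each gene independently; no
  multiple-testing correction is applied because the downstream
  quantity of interest is the *fraction* of significant genes
  compared against a calibrated null rate, not per-gene discovery.
* Per-gene three-line fits are intentionally absent: with one gene's
  worth of counts the five parameters are badly determined, and the
  model is defined on pooled series.
* No cumulative-skew origin-of-replication detection and no
  substitution-process simulation are provided.
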