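---
title: "Methods: phylogeny-guided discovery of variably methylated IAP LTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-guided discovery of variably methylated IAP LTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iapmeth)
```

## Scope and model

`iapmeth` implements a five-stage analysis for locating candidate
metastable epialleles among intracisternal A particle (IAP) long terminal
repeats (LTRs): catalog filtering, phylogeny and clade partition, CoBRA
(combined bisulfite restriction analysis) assay design, gel quantitation,
and clade-level statistics. The guiding model is that metastability —
interindividual variation in LTR methylation among isogenic animals — is a
property of particular diverged subfamilies of the IAPLTR1_Mm family, so
phylogenetic position is an informative prior for screening.

## Catalog stage

RepeatMasker `.out` records are read 1-based inclusive, exactly as
printed, with complementary-strand `C` mapped to `-`; internally all
interval arithmetic stays on those 1-based inclusive coordinates and
conversion to other dialects happens only at I/O boundaries (BED export is
0-based half-open). Subtype filtering keeps records matching a repeat name
(default threshold 330 nt element span) on an allowed chromosome list;
"non-chromosomal" defaults to any sequence name containing `random` or
`Un`, the common unplaced-contig conventions, since no precise definition
exists.

Paired/solo classification marks two same-strand, same-chromosome elements
as the 5' and 3' LTRs of one insertion when their inner gap falls in
[3000, 8000] nt. That window spans the internal bodies of both the
truncated 5.4 kb and the full-length 7.2 kb IAP forms with margin;
annotation jitter of a few hundred nt does not cross its edges. Pairing is
greedy left-to-right with nearest-neighbour preference and smaller-gap
tie-breaks; each element joins at most one pair. Greediness is the
simplest deterministic rule and is exact whenever true insertions are
separated by more than the window, which genomic IAP spacing satisfies
essentially always.

## Alignment and phylogeny

Elements are aligned to the family consensus by consensus-anchored star
alignment: each element is aligned pairwise (global, match +5 /
mismatch −4 — the standard nucleotide matrix with a 65% target identity —
gap open 12, gap extension 3) and the pairwise alignments are merged on
consensus coordinates, insertions opening gap columns padded through all
other rows. Compared to a progressive MSA this is deterministic, order
independent, and linear in the number of elements; it is adequate here
because every member is orthologous to one consensus and indels are rare
within the family. Elements under 50% identity to the consensus are
excluded and reported, mirroring the removal of unalignable elements in
practice.

Pairwise identity is reported *over the length of shared sequence*:
alignment columns where either row carries a terminal gap are excluded, so
a short sequence nested in a longer one is not penalised for the overhang.

Distances: the observed proportion of differing sites *p* skips columns
with a gap or `N` in either row; the Jukes–Cantor correction
*d* = −(3/4)·ln(1 − (4/3)·*p*) assumes equal base frequencies and equal
substitution rates, acceptable at the ≤15% divergences seen within this
family. *p* ≥ 0.75 is saturated and errors by default (an explicit cap can
be supplied; bootstrap resampling uses a cap of 5 substitutions/site since
column resampling can push pairs past saturation).

Neighbor joining is implemented from the Saitou–Nei criterion
Q(i,j) = (n−2)·d(i,j) − Σ_k d(i,k) − Σ_k d(j,k), with standard branch
lengths, negative lengths clamped to zero, and ties broken by the
lexicographically smallest index pair in the current taxon order, making
the output fully deterministic. On additive matrices the algorithm is
exact; the test suite verifies exact recovery against a brute-force
least-squares quartet oracle and path-length reproduction up to n = 8, and
cross-checks topology against an independent implementation on noisy
matrices.

Clades are obtained by cutting the k−1 longest internal edges whose
removal leaves every component with at least 5 leaves (a smaller component
is treated as internal structure, not a clade). The published tree's three
clades were delineated visually; longest-internal-edge cutting is this
package's operationalisation and recovers planted memberships at 100% in
the simulations below. Labels follow divergence from consensus: the most
conserved clade takes the highest label (`clade3`, the large conserved
family analogue) and remaining clades are labelled in increasing
divergence; δ_c is defined as the mean pairwise p-distance of clade
members to the consensus row of the star alignment (computed per member
against the consensus, not over the full MSA columns — the two differ only
through gap handling).

## CoBRA assay design

Bisulfite conversion maps every cytosine to thymine except cytosines at
CpG positions explicitly marked methylated; non-CpG cytosines cannot be
protected. The restriction site model follows the assay as used: the
recognition string `ACGGCG` contains two CpGs, and the site survives
conversion — and is therefore cut — iff *both* are methylated (the
enzyme-catalog 5-nt definition `ACGGC` can be substituted through the
`recognition` argument; the 6-nt form is the default because it makes the
two-CpG dependency explicit). Cuts are placed 12 nt downstream of the
site's 3' end, a single-strand fragment model that ignores the 2 nt
double-strand stagger because only fragment sizes matter for band
identity.

Primer design operates on the fully-methylated bisulfite-converted
template of the element followed by its downstream assay flank (for a
catalog element, the antisense strand of the 5' LTR and its upstream
genomic flank — the junction orientation that makes the amplicon
insertion-specific). Constraints: forward primer entirely inside the
element, reverse entirely inside the flank, lengths 18–29 nt, Wallace-rule
melting temperature (2·(A+T) + 4·(G+C), Y/R counting 3 °C) within a
45–60 °C window, amplicon within [150, 1300] nt, and a
methylation-dependent site at least 30 nt clear of both primers so partial
digestion near a primer cannot masquerade as a band. CpG cytosines inside
a primer are degenerated to `Y` (forward) or `R` (reverse), removing
methylation bias from priming. Both the Tm estimator and the window are
configurable, since published assays report only final annealing
temperatures (47–54 °C) without disclosing the selection rule; recorded
defaults are 45 cycles at 52 °C. Every emitted assay is re-validated by an
independent constraint checker that recomputes all placement, Tm, length
and digest facts from the raw sequences.

Candidate reduction ahead of design keeps only 5'-LTR-of-pair elements
(complete insertion structure) and drops elements with repetitive assay
flanks, operationalised as: an exact shared subsequence of ≥ 30 nt with
another candidate's flank (long enough that chance sharing between
400 nt random flanks is negligible, short enough to catch any repeat
co-insertion), or ≥ 50% of the flank covered by other catalog repeat
annotations.

## Gel quantitation

Percent methylation per lane is M = 100·I_cut/(I_cut + I_uncut), with the
cut intensity summed over sub-fragment bands (summation conserves
material; the published quantitation reported per-band relative
quantities without specifying aggregation). M is scale invariant, so lane
loading cancels. Lanes whose *uncut* (top) band falls below the detection
threshold are masked as below the limit of detection — the uncut band is
the reference band, and its loss makes the ratio meaningless — and the
threshold is expressed in the gel's own intensity units (default 50).
Zero-percent controls must read ≤ 5% and high-methylation controls ≥ 90%
per locus; failures name the locus and control. Reported matrices round
to integers (the gel read-out convention) while statistics always use the
unrounded values.

The bundled survey (`iap_cobra_data()`) is a published 17-mice × 21-loci
integer matrix with 7 below-LOD cells and a Y-linked locus absent in the
10 females. Because its cells are integer-rounded, recomputed mean-type
statistics carry ≤ 0.5 points of rounding error, but a *range* (difference
of two rounded values) carries up to ±1; the package reports computed
values and does not attempt to reconcile the odd published range that was
evidently derived from unrounded quantitation.

## Clade statistics

The unit of analysis for the clade comparison is the per-locus mean (one
value per locus, 7 per clade): mice are not independent replicates of a
locus effect, and pooling mice × loci would pseudo-replicate. One-way
ANOVA F is computed from the standard sums of squares; pairwise contrasts
use the Tukey HSD adjustment with Tukey–Kramer standard errors
(`ptukey`, base R's numerically evaluated studentized-range CDF). The
test suite cross-checks against `aov`/`TukeyHSD` and against a 10^5-draw
permutation oracle. Masked cells are dropped throughout
(complete-cell analysis).

On the bundled survey this analysis yields F(2,18) = 5.51, conserved-clade
contrasts p = 0.018 and 0.041, diverged-vs-diverged p = 0.91 — matching
the published significance pattern (and, numerically, the published
p-values, whose textual assignment to clades appears swapped in the
original report).

## Synthetic data: what it emulates, and what it does not

`plant_elements()` builds each clade from a founder derived from the
consensus at *half* the clade divergence rate (as an exact substitution
count, pinning the clade-level divergence at its target), with members
accruing the other half independently (binomially). Founder mutations are
shared derived characters, so clades are genuine tree structure —
necessary for neighbor joining to recover them — emulating duplication-
and-divergence rather than star-shaped noise. Defaults plant 15/12/40
members at 9.1%/12.9%/1.8% divergence, the published clade structure
scaled to desk size (the published family has 147/113/1130 members; sizes
here were chosen once so the full pipeline runs in seconds while keeping
every clade above the minimum-clade-size threshold). Insertions are
mostly paired (70%) with 5–7 kb random bodies and identical LTR copies
(zero age since insertion); background gaps of 9–15 kb exceed the pairing
window so unlinked insertions can never pair. Substitutions only — no
indels, no nested insertions, no segmental duplications — so the naive
mismatch-counting scanner suffices on synthetic genomes; it is not a
general repeat finder, and pipeline behaviour on real genomes still
requires RepeatMasker annotations.

`simulate_methylation()` draws true locus means from a normal around the
clade mean (sd 7, the between-locus spread observed in the bundled
survey), truncated to [0, 100]; per-mouse values add within-locus normal
noise with locus sd uniform in [2, 8] (the survey's stdev row);
cells drop out at 2% (≈ the survey's 7/357). Gaussian-truncated rather
than beta noise matches the survey's symmetric mid-range values.
`simulate_gel()` inverts the quantitation model with multiplicative
lognormal band noise (cv 0.05) and random lane scales, and emits per-locus
control lanes; masked cells become faint lanes so the LOD rule is
exercised end to end.

What passing simulations do **not** show about real data: bisulfite
conversion failure, PCR bias between methylated and unmethylated
templates, gel saturation and band overlap, strain polymorphism in
element presence, and litter or sex structure are all outside the noise
model.

## Numerical choices and edge cases

Seeds: every generator derives its stream from a single integer seed
(with small fixed offsets per stage), so runs are fully reproducible.
Degenerate inputs: empty catalogs, single-taxon trees, all-identical
alignments, zero-intensity lanes and empty lane lists all return
well-defined empty or flagged results rather than erroring, except where
the operation is undefined (zero comparable alignment columns, duplicate
lanes, p ≥ 0.75 without a cap). F is defined as 0 (p = 1) when both
between- and within-group variance vanish. Truncated-normal draws use
rejection sampling, not clamping, so no mass piles at 0 or 100.

## Known limitations

* The clade comparison is intrinsically low-powered at the published
  effect size: with between-locus sd ≈ 7 and 7 loci per clade, the Tukey
  critical difference at α = 0.05 is ≈ 9.6 points, essentially equal to
  the observed 9–11 point clade differences. The published p-values
  (0.017, 0.041) sit at the decision boundary, and in fresh simulated
  surveys under the same conditions *both* conserved-clade contrasts reach
  significance in only ≈ 40% of replicates. The acceptance suite states
  this recovery property at a stricter level than the effect size can
  support and records the measured rate; interpret a single survey's
  borderline p-values accordingly.
* Genome-wide published counts (total LTRs, family size, clade sizes,
  candidate counts) depend on specific genome and repeat-database
  releases and are not reproduced; the pipeline's behaviour at that scale
  is covered by planted-recovery properties instead.
* Dating insertions by 5'/3' LTR divergence is deliberately absent: the
  family is too young for that clock.
* Maximum-likelihood or Bayesian phylogenetics, rooting, and
  thermodynamic primer screening (dimers, hairpins) are out of scope.

## Problem sizes used by the test and acceptance runs

Planted genomes: 67 members (111 LTR copies, ≈ 1.1 Mb); alignment 67 × 337;
bootstrap 50 replicates in unit tests; methylation surveys 17 × 21 with
200 seeded replicates for recovery rates; permutation oracle 10^5 draws.
These sizes were chosen so the full suite completes in about a minute
while every statistical check retains adequate resolution.
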