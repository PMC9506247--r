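---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` analyses annotated insect mitochondrial genomes: composition
and strand skews, codon usage, degenerate-site profiles, gene order and
architecture, control-region repeats, nucleotide diversity, Ka/Ks, and
supermatrix preparation for phylogenetics. This vignette records the
models behind each stage, the parameters that matter, the numerical
conventions, and the design choices made where more than one defensible
option existed.

## Data model and coordinates

A `mitogenome` is a J-strand (majority-strand) DNA string plus a typed,
stranded feature table. Coordinates are **0-based half-open** internally;
GenBank's 1-based inclusive convention is converted only at the file
boundary. This removes every off-by-one ambiguity from spacer/overlap
arithmetic: a boundary gap is simply `next$start - prev$end`, with
positive values spacers, negative values overlaps and 0 abutting.

Circularity is encoded by allowing `end > length`, interpreted modulo the
genome length; the control region may span the origin, since it sits
between *rrnS* and *trnI* next to the conventional linearization origin.
Linearized gene orders are anchored at *trnI* when present (the
conventional presentation for insect mitogenomes), falling back to the
first feature with a warning.

Gene-name synonyms (`COB`/`CYTB` → `cytb`, `ND4L` → `nad4l`, `12S` →
`rrnS`, …) are data — an editable TSV shipped in `extdata/` — not code.

## Composition and skews

Strand skews follow the standard definitions
$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$
computed on the J-strand for whole-genome comparisons and on coding-sense
sequences for per-gene and per-class tables (so an N-strand gene
contributes its reverse complement). Ambiguous bases (N) are excluded
from every denominator, which keeps skews well defined; they are tallied
separately. A zero denominator yields a missing value, never 0. Full
precision is kept internally; percentages print at 1 dp and skews at 4 dp
in the pipeline's tables.

## Codon usage

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial: AGA/AGG = Ser, AUA = Met, UGA = Trp) and is injectable —
every codon-level function takes a `genetic_code()` argument.

Conventions, chosen once and applied everywhere:

* Codons are read in frame 0. A trailing 1–2 bp remainder is recorded as
  an incomplete stop codon (`T` or `TT`, completed to UAA by mRNA
  polyadenylation) and excluded from counts; a complete terminal stop is
  recorded and likewise excluded. Published mitogenome codon tables show
  stop counts of zero, which this convention reproduces.
* Start codons are included in the counts, so the non-stop codon total of
  a CDS is `floor(L/3)` minus its terminal stop.
* RSCU is `count × familySize / familyTotal`; it is scale invariant, so
  raw totals and per-gene means (the form comparative tables usually
  print) give identical values. A family with zero total has undefined
  (missing) RSCU. `Σ RSCU = familySize` holds exactly at full precision
  whenever the family total is positive.
* Degenerate-site classes are assigned per codon position by enumerating
  the three possible substitutions: 0-fold if none preserves the amino
  acid, 4-fold if all three do, 2-fold otherwise. Classical 2-fold and
  3-fold sites are pooled into the 2-fold class — the common three-class
  convention. Substitutions creating stop codons count as
  non-preserving. The assignment is a partition: class site counts sum to
  3 × codon count.

The package ships the published per-gene mean codon counts for the
*N. lugens* biotype-4 mitogenome (`nlugens_codon_counts()`) as reference
data; the worked RSCU and amino-acid-usage values in the README are
computed from it at run time.

## Architecture

**Breakpoints.** Rearrangement is quantified as the strand-aware circular
adjacency-set difference: an adjacency between consecutive signed genes
$(a, b)$ is identified with $(-b, -a)$, and a breakpoint is an adjacency
present in the query but absent from the reference (multiset semantics,
so duplicated genes match copy-for-copy by adjacent context). This was
chosen over inversion/DCJ distances deliberately: the biological claim
being supported is *which blocks moved*, not a rearrangement scenario.

**Spacers and overlaps.** Consecutive features around the linearized
circle, including the wrap boundary. Features nested inside another
feature are excluded from the boundary walk and listed separately, which
keeps the circular tiling identity
`Σ lengths + Σ spacers − Σ overlaps = genome length` exactly testable.
The control region is excluded by default (reported via its length), as
in published spacer accounts.

**Tandem repeats.** The finder scans exhaustively over unit lengths
(default 5–50 bp) and phases, growing each candidate array copy by copy
while at most `max_variable_positions` columns (default 1) vary across
copies; varying columns are reported as IUPAC codes in the consensus
unit, which is how a unit whose first base alternates G/A is reported
with a leading `R`. Ties break by more copies, then longer span, then
leftmost; reported arrays never overlap and verify copy-by-copy. The
O(L × maxUnit) brute force is a deliberate choice at control-region scale
(~1.3 kb): deterministic and exhaustive beats heuristic here. Note that a
long homopolymer qualifies as a tandem array of itself; the poly-T run
therefore also appears in repeat output, ranked well below a genuine
multi-copy array.

## Divergence

**Distances.** p-distances use pairwise deletion (columns with a gap or N
in either sequence are dropped from numerator and denominator); this
preserves per-window site counts in sliding-window analyses, unlike
complete deletion. The Jukes–Cantor correction
$d = -\tfrac34 \ln(1 - \tfrac{4p}{3})$ is defined on $[0, 0.75)$;
saturated inputs return missing values with a warning rather than
clamping.

**Nucleotide diversity.** Pi is the unweighted mean over all unordered
pairs of the within-window proportion of differing sites. Windows default
to 200 bp sliding by 20 bp — configurable, as no single convention
exists — and a final shorter tail window is kept so the profile tiles the
alignment. With window = alignment length, the per-gene value is
recovered exactly.

**Ka/Ks.** Nei–Gojobori counting: synonymous sites per codon are the
per-position fractions of single-base changes preserving the amino acid
(changes to stops are non-synonymous), averaged between the two
sequences, so `N + S = 3 × codons` exactly. Observed differences are
resolved by equal weighting over all substitution pathways between the
two codons; pathways through stop codons are excluded with
renormalization (standard practice), and a codon pair whose every pathway
is blocked is skipped and tallied. Multi-taxon per-gene rates are
unweighted means over all pairs. The Jukes–Cantor adjustment is applied
**per pair before averaging** by default; whether published
DnaSP-derived tables adjust before or after averaging is not generally
recoverable, so the other ordering is available behind
`adjust_after_mean = TRUE`. Ratios are always formed after averaging, and
genes rank by JKa/JKs (fastest first). JKa/JKs < 0.5 is the conventional
purifying-selection flag, and < 1 purifying in general.

## Phylogenetic preparation

The PCG123 supermatrix concatenates the 13 PCGs in the conventional order
*nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad5, nad4, nad4l, nad6, cytb,
nad1* regardless of input order, taxa sorted lexicographically, with
1-based inclusive gene partitions and `\3`-style codon-position
partitions (13 + 39 lines for a full matrix) for downstream tools.

Maximum-likelihood inference, model selection and bootstrapping are the
domain of dedicated external tools; this package emits their inputs
bit-exactly and provides neighbor joining (via ape, with input
validation and negative-branch clamping) so the pipeline runs end to end
at desk scale. NJ is exact on additive matrices, which is what the test
suite exploits. Trees are produced unrooted; an outgroup id roots the
output for presentation only.

## The synthetic generator

`generate_genome()` emulates the structures the analyses are designed to
detect, with every planted quantity recorded in a truth record:

* the 37-gene insect canon with realistic lengths (PCG lengths are
  `3 × codons + stop`, so genes with incomplete stops are ≡ 1 or 2 mod 3,
  e.g. *atp8* at 94 bp);
* an `"ancestral"` or `"nlugens"`-like order — the latter swaps
  *trnW–trnC* to *trnC–trnW*, reverses *trnT–trnP–nad6* to
  *nad6–trnP–trnT*, and inserts a second *trnC* after the long non-coding
  stretch that follows *nad2*;
* a 345 bp spacer after *nad2*, 2 bp spacers elsewhere, and five overlaps
  (6+1+1+1+1 = 10 bp) placed after tRNAs only, so the overlapped bases
  never corrupt a reading frame;
* a control region with a 15-copy 20 bp tandem array whose first base
  alternates G/A, and a 24 bp poly-T run;
* a composition target of 77.5% A+T (42.6/34.9/8.8/13.7), hit **exactly**
  when `exact_composition = TRUE`: free bases (spacers and CR filler) are
  redrawn as an exact multiset after the genes are placed. Minus-strand
  genes are drawn from the complemented fractions so their J-strand
  contribution matches the target. Infeasible targets error rather than
  being approximated.

Determinism is part of the contract: the same blueprint and seed give
byte-identical genomes. Small count-preserving swaps keep the planted
structures unambiguous — free segments are capped at 12 consecutive T so
no spurious run rivals the planted poly-T, the poly-T flanks are forced
non-T, and the base preceding the repeat array must differ from the
unit's final base so no shifted phase of the array gains an extra copy.

`evolve_taxa()` simulates codon-level divergence down a guide tree: on a
branch of length $t$ (candidate substitutions per site), `Poisson(tL)`
single-base candidates are drawn uniformly; stop-creating candidates are
rejected, synonymous ones always accepted, non-synonymous ones accepted
with probability ω. Because a uniform candidate is synonymous with
probability $S/L$ under the same site definitions Nei–Gojobori uses, the
realized Ka/Ks tracks ω (slightly below it, since stop-bound
non-synonymous candidates are never accepted). This rejection scheme was
chosen over a full codon rate matrix deliberately: it is desk-scale and
sufficient for the ordering and threshold properties being tested. No
indels are simulated, so the simulator's alignments are gap-free by
construction and the Pi and Ka/Ks oracles stay exact; gaps enter the
divergence stages only through user-supplied alignments.

**What passing tests do and do not show.** The generator plants exact,
clean structures: spacers are iid, the CR filler has no secondary repeat
structure, tRNAs are unstructured random sequence, there is no
rate heterogeneity along genes, no composition drift between taxa and no
sequencing error. Recovery of planted truth therefore validates the
*analysis arithmetic*, not robustness to the messiness of real
annotations (mispredicted boundaries, frameshifts, heteroplasmy), which
is out of scope here.

## Problem sizes and numerical conventions

The test suite runs everything at desk scale: genomes of ~16 kb,
alignments of 300 codons over 4 taxa, 20 replicate seeds for the ω
recovery checks, NJ on up to 8 taxa, and exhaustive oracle comparisons
over all 64 × 3 codon sites and all sense-codon pairs with ≤ 2
differences plus 500 random pairs. These sizes were chosen as the
smallest at which each property is non-trivial.

Other conventions: ties in repeat search and poly-T detection resolve
leftmost; NJ tie-breaking follows ape's deterministic implementation;
negative NJ branch lengths are clamped to 0 with a warning; all pipeline
randomness flows through the single configured seed; pipeline tables are
written at fixed printed precision so reruns diff cleanly.

## Known limitations

* No de novo annotation, ORF finding or tRNA secondary-structure
  prediction — annotations are taken as given.
* No alignment or alignment trimming: divergence stages consume
  codon alignments produced elsewhere (the pipeline can compare
  unaligned, equal-length CDS sets such as the simulator's output
  directly).
* No ML/Bayesian inference, codon models, or site-specific selection
  tests; NJ is a preparation-stage check, not a publication tree.
* The GenBank reader covers the flat-file subset the writer emits
  (single-record, CDS/tRNA/rRNA/D-loop/misc_feature keys, two-segment
  origin-spanning joins), not the full format.
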