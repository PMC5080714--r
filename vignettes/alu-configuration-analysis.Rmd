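---
title: "Alu configuration analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alu configuration analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscape)
```

## The scientific question

Alu elements are ~300-nt primate SINEs derived from 7SL RNA. When two Alus
sit near each other on opposite genomic strands, the mature transcript that
contains both can fold them into a long intramolecular duplex; such inverted
configurations are associated with reduced mRNA levels, while tandem
(same-strand) arrangements are not. `aluscape` quantifies three aspects of
this phenomenon: how Alu configurations are distributed across the genome,
how the exonic configuration of a transcript relates to its expression, and
how to engineer artificial UTRs that reproduce the secondary structure of an
inverted-Alu UTR without its sequence.

## Repeat clustering and pair orientation

Alus are clustered per chromosome by single-linkage chaining: consecutive
elements (sorted by start) join one cluster iff the gap between them is at
most `max_gap` (default 300 nt). Gaps are end-to-start differences in
0-based half-open coordinates, so a gap of 0 means adjacency and the
"at most 300 nt" boundary is inclusive; a gap of exactly 300 joins.
Overlapping RepeatMasker records (occasionally emitted as fragmented hits)
count as gap 0 and are always merged, never split.

Pairs — clusters of exactly two — are classified by strand arrangement:
equal strands give a tandem pair (`dSINE`); `(+,-)` points the two 3′ ends
at each other (tail-to-tail, `tiSINE`); `(-,+)` points the 5′ ends at each
other (head-to-head, `hiSINE`). Orientation fractions are computed over
*all* Alus (both members of each pair counted), so the tandem and inverted
fractions sum to the paired fraction. Clusters of three or more contribute
to the clustered fraction but not to orientation statistics, which are
deliberately restricted to Alus with exactly one partner within the gap
threshold — with more partners the pairwise orientation is ambiguous.

Two neighbour-spacing statistics summarize clustering tendency. The median
neighbour gap is, by default, the median over gaps between consecutive Alus
per chromosome; the fraction "within" that distance counts Alus whose
nearest same-chromosome neighbour is at most the median away. Counting
*elements* against a median over *gaps* is what allows the fraction to
exceed one half (a single close pair gives two elements with a small nearest
gap but only one small gap); since other readings are defensible, both the
median basis (`median_over`) and the counting basis (`within_counts`) are
switchable arguments of `summarize_catalog()`.

A note on symmetry: flipping every strand — or mirroring all coordinates —
exchanges head-to-head and tail-to-tail counts while leaving tandem pairs
and cluster structure unchanged. Applying *both* operations is a rigid
reflection of the locus and preserves every class; the tests check the two
generators separately and the composition as identity.

## Hierarchical genome partition and the Aluome

Overlapping genes and isoforms give single nucleotides multiple identities.
These are removed by projecting annotation hierarchically: level 1 labels a
nucleotide genic iff any gene span covers it; level 2 splits genic territory
into exonic (any isoform's exon) and intronic; level 3 splits exonic
territory into coding, 5′ UTR, 3′ UTR and non-coding with precedence
coding > utr5 > utr3 > noncoding. The within-level precedence is a design
choice (annotation formats do not dictate one): CDS is the most specific,
experimentally anchored claim, and the 5′ UTR is rarer than the 3′ UTR so
it wins ties; the order can matter only at positions where isoforms
disagree. Strand is ignored throughout — partitions describe genomic
territory, not transcription units. Gene types are restricted to Pol II
transcribed classes (protein coding, IG/TR segment genes and pseudogenes,
polymorphic pseudogene, pseudogene, processed transcript, lincRNA, sense
intronic, sense overlapping, 3′ overlapping non-coding RNA, antisense).

The *Aluome* is the set of nucleotides annotated as Alu (overlapping records
merged). Coverage is strictly base-wise: an Alu spanning a label boundary
contributes its nucleotides to each side pro rata, because the quantity of
interest is the proportional coverage of nucleotides, not element counts.
If Alus were uniformly spread, the Aluome fraction of every partition would
equal its genome fraction; the ratio of the two is the enrichment. Per
level, both fraction vectors sum to 1 by construction, which the tests
assert to 1e-9 and verify against per-nucleotide brute-force labeling on
10-kb chromosomes.

## Transcript configurations

Only Alus *fully contained in a single exon* of a transcript count toward
its configuration: an element straddling an exon boundary is not present in
the mature RNA as an intact unit. Contained Alus are mapped through the
spliced exon chain into mature-transcript coordinates (reversed for
minus-strand transcripts) and ordered 5′→3′; the relative orientation of an
Alu is sense iff its strand equals the transcript's. Categories follow the
adjacent-pair rules: no Alus → `noSINE`; one → `single`; two or more with
every adjacent pair in equal orientation → `tandem`; any adjacent inverted
pair → `iAlu`. In transcript coordinates a (sense, antisense) adjacent pair
is tail-to-tail and (antisense, sense) is head-to-head; an `iAlu` transcript
is flagged `head_head` or `tail_tail` only when *every* adjacent pair shares
that arrangement, so the two flags are disjoint and both are subsets of
`iAlu`. Unlike the genomic clustering there is no distance threshold between
transcript-level neighbours: within one mature RNA, any inverted pair can in
principle base-pair. Categories are per transcript, not per gene, because
expression is quantified per transcript; the same-family flag of adjacent
pairs is recorded as annotation but never enters the category.

## Expression comparison

Transcripts survive the expression filter iff their FPKM is at least
`min_fpkm` (default 3) in *every* cell line, boundary inclusive. Each
surviving transcript then contributes one observation per cell line to the
pool of its category (and to `all`), matching the convention of counting
transcript × cell-line occurrences. Pools are compared with the two-sample
Wilcoxon rank-sum test: exact enumeration when both pools have ≤ 25
observations and no ties, otherwise the normal approximation with tie and
continuity correction. The one-sided alternative defaults to "the first
group is stochastically lower", encoding the directional hypothesis that
inverted-configuration transcripts are less expressed. Raw p-values are
reported by default — a Bonferroni (or any `p.adjust`) option exists for the
pairwise grid. Reported means are on the raw FPKM scale; rank-sum p-values
are invariant under any strictly monotone transform, so the choice of scale
affects only the descriptive statistics.

## Sequence design

A design template is a UTR split into spacer segments (never mutated) and
designable segments (the Alu elements to be replaced). The target is the
template's MFE structure, MFE and EFE. The search is seeded stochastic
hill-climbing with restart on plateau: designable positions are initialized
uniformly at random; each step mutates one random designable nucleotide and
keeps the result iff it does not worsen the objective, which compares first
the base-pair set distance between the current MFE structure and the target
and then the total MFE+EFE mismatch; after `plateau` steps without strict
improvement the fill restarts at random. Neutral ("sideways") moves are
accepted to let the search drift across plateaus. A state is accepted as a
candidate when its MFE structure equals the target *exactly*, its MFE and
EFE are within ±0.5 kcal/mol (configurable; exact equality across different
sequences is unattainable, and 0.5 is of the order of one
thermodynamic-parameter quantum), and its fill aligns to the replaced
original at ≤ 60 % identity — the divergence bound that makes
"structure-alike but sequence-unlike" testable. Identity is computed per
designable segment (Needleman–Wunsch, unit match/mismatch/gap scoring,
matches over alignment columns) and maximized over segments; the spacers are
byte-identical by construction, so a whole-sequence identity bound would be
dominated by them and meaningless. Accepted candidates are ranked by
`gc_weight · |ΔGC| + bpp_weight · bpp_distance`, where the base-pair
probability distance is the Frobenius norm of the upper-triangular
difference of the two pair-probability matrices divided by sequence length.

Two folding engines satisfy one contract. The default engine is a base-pair
maximization model: canonical Watson–Crick plus GU wobble pairs, a minimum
hairpin loop of 3 unpaired nucleotides, energy −1 per pair, RT = 1. Its MFE
comes from the Nussinov recursion with a deterministic traceback; its
partition function and base-pair probabilities come from the exact
inside–outside decomposition (each pair is either exterior or sits directly
under its innermost enclosing pair), so EFE = −ln Z and the probability
matrix are exact, and the tests verify both against exhaustive structure
enumeration on sequences up to ~14 nt. This engine is deliberately simple:
it makes every design guarantee checkable by enumeration. The `"vienna"`
engine shells out to RNAfold (Turner nearest-neighbour thermodynamics,
pair probabilities from the dot plot) for realistic energies; design results
under the two engines are not interchangeable, and all structural tests run
under the self-contained engine.

## The synthetic genomes

`sim_params()` fixes the reference study conditions: two 500-kb
chromosomes, 30 protein-coding genes (2–6 exons, 3′ UTRs of 1600–2600 nt so
any planted unit fits inside one), and planted repeat units of 60
singletons, 13 tandem pairs, 4 tail-to-tail pairs, 3 head-to-head pairs and
5 clusters of three 300-nt Alus. Within-unit gaps are drawn from 20–300 nt
(never above the clustering threshold) and units keep ≥ 1000 nt clearance
from each other (always above it), so the planted labels are recoverable
with zero error — recovery failures therefore indicate implementation bugs,
not ambiguity. Units are placed in 3′ UTR exons, introns or intergenic space
with configurable probabilities (default 25/25/50 %), which exercises both
the genomic and the transcript pipelines; the first gene carries a second
isoform with an exon inside a sibling intron to exercise hierarchical
projection. Expression is log-normal FPKM (log-mean log 20, log-sd 0.8 — a
realistic heavy-tailed surrogate for moderately expressed transcripts), with
independent draws per transcript and cell line and the expectation of
inverted-category transcripts multiplied by `repression_factor` (default
0.6, i.e. the ~40 % reduction planted as truth).

What the simulation does *not* emulate bounds what passing tests show about
real data: there is no within-transcript correlation across cell lines (real
FPKM values of one transcript are strongly correlated between cell lines, so
pooled rank-sum p-values on real data overstate independent evidence), no
sequence content under the simulated coordinates, no Alu subfamily
structure, no overlapping genes beyond the single planted isoform case, and
no read-level noise. The tests demonstrate correctness of the operations and
calibration of the statistics under these conditions, not biological effect
sizes.

## Numerical and degenerate-input choices

* Empty repeat input yields zero counts with `NA` fractions, never 0/0.
* Overlapping repeat records: merged (gap treated as 0), logged via message.
* Clusters spanning a genic/intergenic boundary are assigned by span
  midpoint and counted once.
* Alus on chromosomes absent from a partition are skipped with a warning;
  features past a chromosome end are clipped with a warning.
* Nussinov traceback breaks ties deterministically (unpaired decomposition
  first, then the smallest pairing partner), so MFE structures — and hence
  design targets — are reproducible.
* All simulation functions restore the caller's RNG state; identical seeds
  give byte-identical outputs.

## Problem sizes used in the test-suite

The default suite runs the full pipeline on the 2 × 500-kb reference genome,
rank-sum calibration on 1000 small null cohorts (30 transcripts per group,
3 cell lines) and power on 100 cohorts of 200 transcripts per group across
15 cell lines, folding oracles on sequences ≤ 14 nt, and design searches of
up to 2000 steps on a 24-nt toy template. These sizes make the whole suite
run in a few minutes while keeping every check exact or
Monte-Carlo-stable.
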