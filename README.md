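# aluscape

Alu elements — primate short interspersed elements (SINEs) of ~300 nt derived
from 7SL RNA — make up a large fraction of the human genome, and their
*arrangement* matters: two nearby Alus inserted on opposite strands (an
inverted pair, *i*SINE) can base-pair intramolecularly in a mature transcript
and repress its expression, while tandem pairs (*d*SINEs) do not. `aluscape`
implements the computational side of that question for genomicists and
transcriptomicists:

* **Repeat catalog** — parse RepeatMasker-style repeat tracks, restrict to
  the Alu family, cluster elements by genomic distance (single-linkage,
  gap ≤ 300 nt by default, inclusive), and classify clusters of two by
  strand arrangement: `dSINE` (++ / −−, tandem), `tiSINE` (+−, tail-to-tail)
  and `hiSINE` (−+, head-to-head).
* **Genome partition / "Aluome"** — project gene annotation hierarchically
  onto the genome (genic/intergenic → exonic/intronic → coding/5′ UTR/3′
  UTR/non-coding) and compute proportional coverage of the Aluome (the set of
  all Alu nucleotides) per partition, with the enrichment ratio
  aluome_fraction / genome_fraction.
* **Transcript configurations** — keep Alus fully contained in single exons,
  project them into mature-transcript coordinates through the spliced exon
  chain, and categorize each transcript (`noSINE`, `single`, `tandem`,
  `iAlu`, with pure `head_head` / `tail_tail` sub-classes).
* **Expression stratification** — filter FPKM tables (≥ 3 FPKM in every cell
  line by default), pool transcript × cell-line observations per category,
  and compare categories with Wilcoxon rank-sum tests (exact for small
  tie-free pools, normal approximation with tie/continuity correction
  otherwise).
* **Sequence design** — design artificial UTR analogs: keep spacer segments
  fixed, replace Alu segments with random sequence, and hill-climb until the
  candidate reproduces the template's minimum-free-energy (MFE) structure
  with matching MFE and ensemble free energy (EFE = −RT ln Z) while staying
  ≤ 60 % identical to the replaced Alu. A self-contained base-pair
  maximization engine (exact partition function, oracle-checkable) is the
  default; `engine = "vienna"` delegates to RNAfold.
* **Synthetic data** — simulate repeat annotations with planted
  configuration classes, multi-isoform gene models and FPKM tables with a
  planted repression of inverted-configuration transcripts, so every stage
  has exact ground truth.

## Worked example

```r
library(aluscape)

p   <- sim_params(seed = 1)                       # planted study conditions
ga  <- simulate_gene_annotation(p)
sim <- simulate_repeat_annotation(p, ga$gene_models)

cl <- cluster_alus(sim$repeats, max_gap = 300)
summarize_catalog(cl)
#> # A tibble: 1 x 10
#>   n_alus fraction_single fraction_clustered fraction_in_pairs fraction_dSINE
#>      115           0.522              0.478             0.348          0.226
#>   fraction_iSINE fraction_hiSINE fraction_tiSINE median_neighbor_gap ...
#>            0.122          0.0522          0.0696                2594

part <- project_partitions(ga$gene_models, ga$chrom_sizes)
aluome_coverage(sim$repeats, part)   # per-label fractions and enrichment

prof <- transcript_alu_profiles(ga$gene_models, sim$repeats)
ex   <- simulate_expression(prof, repression_factor = 0.6, seed = 1)
pool <- pool_by_category(filter_expressed(ex$fpkm, min_fpkm = 3), prof)
compare_categories(pool, "iAlu", "tandem")
#> Wilcoxon rank-sum comparison: iAlu (n=45) vs tandem (n=30)
#>   U = 421, p (two-sided) = 0.0061152, p (one-sided, iAlu < tandem) = 0.0030576
#>   iAlu lower; normal approximation with tie/continuity correction
```

The catalog row says: of 115 simulated Alus, 52 % are isolated, 35 % sit in
pairs, and tandem pairs (22.6 %) outnumber inverted ones (12.2 %) — the
planted configuration counts recovered exactly. The rank-sum comparison
shows the planted ~40 % FPKM reduction of inverted-configuration transcripts
as a directional significant difference (small cohort here; the acceptance
script uses 200 transcripts per group).

Plots: `plot_catalog()`, `plot_aluome()`, `plot_expression()` return ggplot
objects for the three result tables.

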