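# Small hand-built gene model helper: one-row-per-feature tibble.
gm_row <- function(chrom, start, end, strand, feature, gene, tx = NA,
                   gene_type = "protein_coding") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = strand, feature = feature, gene_id = gene,
                 gene_type = gene_type, transcript_id = tx)
}

test_that("GTF import filters gene types and sides generic UTRs", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 100, 1000, "+", "gene", "g1"),
    gm_row("chr1", 100, 1000, "+", "transcript", "g1", "g1.t1"),
    gm_row("chr1", 100, 400, "+", "exon", "g1", "g1.t1"),
    gm_row("chr1", 700, 1000, "+", "exon", "g1", "g1.t1"),
    gm_row("chr1", 200, 400, "+", "cds", "g1", "g1.t1"),
    gm_row("chr1", 700, 800, "+", "cds", "g1", "g1.t1"),
    gm_row("chr1", 100, 200, "+", "utr5", "g1", "g1.t1"),
    gm_row("chr1", 800, 1000, "+", "utr3", "g1", "g1.t1"),
    gm_row("chr1", 3000, 3500, "-", "gene", "g2", gene_type = "miRNA"),
    gm_row("chr1", 3000, 3500, "-", "transcript", "g2", "g2.t1", gene_type = "miRNA"),
    gm_row("chr1", 3000, 3500, "-", "exon", "g2", "g2.t1", gene_type = "miRNA"),
    gm_row("chr1", 5000, 5600, "-", "gene", "g3", gene_type = "lincRNA"),
    gm_row("chr1", 5000, 5600, "-", "transcript", "g3", "g3.t1", gene_type = "lincRNA"),
    gm_row("chr1", 5000, 5600, "-", "exon", "g3", "g3.t1", gene_type = "lincRNA")
  )
  f <- tempfile(fileext = ".gtf")
  write_gtf(gm, f)
  got <- read_gtf(f)
  # miRNA excluded, lincRNA included
  expect_false("g2" %in% got$gene_id)
  expect_true("g3" %in% got$gene_id)
  # generic UTR rows were re-sided against the CDS span
  u5 <- dplyr::filter(got, feature == "utr5", gene_id == "g1")
  u3 <- dplyr::filter(got, feature == "utr3", gene_id == "g1")
  expect_equal(c(u5$start, u5$end), c(100L, 200L))
  expect_equal(c(u3$start, u3$end), c(800L, 1000L))

  # exon outside its transcript span is a validation error
  bad <- dplyr::bind_rows(
    gm_row("chr1", 100, 500, "+", "gene", "g1"),
    gm_row("chr1", 100, 500, "+", "transcript", "g1", "g1.t1"),
    gm_row("chr1", 600, 900, "+", "exon", "g1", "g1.t1")
  )
  fb <- tempfile(fileext = ".gtf")
  write_gtf(bad, fb)
  expect_error(read_gtf(fb), "outside its transcript span")
})

test_that("UTRs are derived from exon minus CDS when not annotated", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 0, 900, "-", "gene", "g1"),
    gm_row("chr1", 0, 900, "-", "transcript", "g1", "g1.t1"),
    gm_row("chr1", 0, 300, "-", "exon", "g1", "g1.t1"),
    gm_row("chr1", 600, 900, "-", "exon", "g1", "g1.t1"),
    gm_row("chr1", 100, 300, "-", "cds", "g1", "g1.t1"),
    gm_row("chr1", 600, 800, "-", "cds", "g1", "g1.t1")
  )
  f <- tempfile(fileext = ".gtf")
  write_gtf(gm, f)
  got <- read_gtf(f)
  # minus strand: genomic-left tail is the 3' UTR, genomic-right the 5' UTR
  expect_equal(dplyr::filter(got, feature == "utr3")$start, 0L)
  expect_equal(dplyr::filter(got, feature == "utr3")$end, 100L)
  expect_equal(dplyr::filter(got, feature == "utr5")$start, 800L)
  expect_equal(dplyr::filter(got, feature == "utr5")$end, 900L)
})

test_that("a single gene splits the chromosome into genic and intergenic", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 100, 200, "+", "gene", "g1"),
    gm_row("chr1", 100, 200, "+", "transcript", "g1", "g1.t1"),
    gm_row("chr1", 100, 200, "+", "exon", "g1", "g1.t1")
  )
  part <- project_partitions(gm, tibble::tibble(chrom = "chr1", size = 1000L))
  l1 <- dplyr::filter(part, level == 1)
  expect_equal(sum(l1$end[l1$label == "genic"] - l1$start[l1$label == "genic"]), 100L)
  expect_equal(sum(l1$end[l1$label == "intergenic"] - l1$start[l1$label == "intergenic"]),
               900L)
})

test_that("hierarchical precedence resolves overlapping isoforms", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 0, 1000, "+", "gene", "g1"),
    gm_row("chr1", 0, 1000, "+", "transcript", "g1", "A"),
    gm_row("chr1", 0, 400, "+", "exon", "g1", "A"),
    gm_row("chr1", 800, 1000, "+", "exon", "g1", "A"),
    gm_row("chr1", 100, 400, "+", "cds", "g1", "A"),
    gm_row("chr1", 0, 1000, "+", "transcript", "g1", "B"),
    gm_row("chr1", 0, 100, "+", "exon", "g1", "B"),
    gm_row("chr1", 500, 700, "+", "exon", "g1", "B"),   # intron of A
    gm_row("chr1", 200, 400, "+", "utr3", "g1", "B")    # coding in A
  )
  part <- project_partitions(gm, tibble::tibble(chrom = "chr1", size = 1200L))
  lab2 <- expand_partition(part, "chr1", 1200L, 2L)
  # position 550: exon of B, intron of A -> exonic
  expect_equal(lab2[551], "exonic")
  lab3 <- expand_partition(part, "chr1", 1200L, 3L)
  # position 250: coding in A, utr3 in B -> coding wins
  expect_equal(lab3[251], "coding")
})

test_that("partition tiling is conserved and matches per-base brute force", {
  p <- sim_params(n_chromosomes = 1L, chrom_length = 10000L, n_genes = 2L,
                  exons_per_gene = c(2L, 3L), utr3_length = c(400L, 700L),
                  planted_counts = c(sSINE = 4L, tiSINE = 1L), seed = 3L)
  ga <- simulate_gene_annotation(p)
  part <- project_partitions(ga$gene_models, ga$chrom_sizes)
  sim <- simulate_repeat_annotation(p)  # uniform placement
  cov <- aluome_coverage(sim$repeats, part)

  for (lv in 1:3) {
    d <- dplyr::filter(cov, level == lv)
    expect_equal(sum(d$genome_fraction), 1, tolerance = 1e-9)
    expect_equal(sum(d$aluome_fraction), 1, tolerance = 1e-9)
  }
  # nesting: level sizes are consistent
  nt <- function(lv, lab) sum(cov$genome_nt[cov$level == lv & cov$label == lab])
  expect_equal(nt(2, "exonic") + nt(2, "intronic"), nt(1, "genic"))
  expect_equal(nt(3, "coding") + nt(3, "utr5") + nt(3, "utr3") + nt(3, "noncoding"),
               nt(2, "exonic"))

  # per-nucleotide brute force on the 10-kb chromosome
  oracle <- brute_partition_labels(ga$gene_models, "chrS1", 10000L)
  expect_equal(expand_partition(part, "chrS1", 10000L, 1L), oracle$lvl1)
  expect_equal(expand_partition(part, "chrS1", 10000L, 2L), oracle$lvl2)
  expect_equal(expand_partition(part, "chrS1", 10000L, 3L), oracle$lvl3)

  # brute-force aluome: count Alu-covered positions per level-1 label
  alu_cov <- rep(FALSE, 10000L)
  for (i in seq_len(nrow(sim$repeats))) {
    alu_cov[(sim$repeats$start[i] + 1):(sim$repeats$end[i])] <- TRUE
  }
  got_genic <- cov$aluome_nt[cov$level == 1 & cov$label == "genic"]
  expect_equal(got_genic, sum(alu_cov & oracle$lvl1 == "genic"))
})

test_that("aluome fractions and enrichment follow their definitions", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 200, 500, "+", "gene", "g1"),
    gm_row("chr1", 200, 500, "+", "transcript", "g1", "t1"),
    gm_row("chr1", 200, 300, "+", "exon", "g1", "t1"),
    gm_row("chr1", 400, 500, "+", "exon", "g1", "t1")
  )
  part <- project_partitions(gm, tibble::tibble(chrom = "chr1", size = 1000L))

  # single Alu fully intergenic
  alu <- tibble::tibble(chrom = "chr1", start = 700L, end = 1000L,
                        strand = "+", name = "AluY", family = "Alu")
  cov <- aluome_coverage(alu, part)
  expect_equal(cov$aluome_fraction[cov$level == 1 & cov$label == "intergenic"], 1)

  # Alus covering every label proportionally -> all enrichments 1:
  # one Alu covering the whole chromosome does exactly that
  whole <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                          strand = "+", name = "AluY", family = "Alu")
  cov2 <- aluome_coverage(whole, part)
  expect_true(all(abs(cov2$enrichment - 1) < 1e-12))

  # planted 70 % of Alu nucleotides in introns, exactly
  alus <- tibble::tibble(
    chrom = "chr1",
    start = c(310L, 700L),  # 70 nt in the intron [300,400), 30 nt intergenic
    end = c(380L, 730L),
    strand = "+", name = "AluY", family = "Alu"
  )
  cov3 <- aluome_coverage(alus, part)
  expect_equal(cov3$aluome_fraction[cov3$level == 2 & cov3$label == "intronic"], 1)
  expect_equal(cov3$aluome_nt[cov3$level == 1 & cov3$label == "genic"] /
                 sum(cov3$aluome_nt[cov3$level == 1]), 0.70)

  # Alu on an unknown chromosome is skipped with a warning
  expect_warning(
    aluome_coverage(dplyr::mutate(alu, chrom = "chrX"), part),
    "absent from the partition"
  )
})

test_that("features past the chromosome end are clipped with a warning", {
  gm <- dplyr::bind_rows(
    gm_row("chr1", 800, 1200, "+", "gene", "g1"),
    gm_row("chr1", 800, 1200, "+", "transcript", "g1", "t1"),
    gm_row("chr1", 800, 1200, "+", "exon", "g1", "t1")
  )
  expect_warning(
    part <- project_partitions(gm, tibble::tibble(chrom = "chr1", size = 1000L)),
    "clipped"
  )
  l1 <- dplyr::filter(part, level == 1, label == "genic")
  expect_equal(max(l1$end), 1000L)
})
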