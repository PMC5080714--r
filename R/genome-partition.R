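# Hierarchical genome partition (genic/intergenic, exonic/intronic,
# coding/UTR/non-coding) and proportional "Aluome" coverage.
#
# The Aluome is the set of genomic nucleotides annotated as Alu. If Alus were
# evenly distributed, the fraction of Alu nucleotides in a partition would
# equal the fraction of genome nucleotides in that partition; the enrichment
# ratio aluome_fraction / genome_fraction measures the deviation.

# Pol II gene types retained by default (GENCODE tokens).
polii_gene_types <- function() {
  c("protein_coding",
    "IG_C_gene", "IG_C_pseudogene", "IG_D_gene", "IG_J_gene",
    "IG_J_pseudogene", "IG_V_gene", "IG_V_pseudogene",
    "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_J_pseudogene",
    "TR_V_gene", "TR_V_pseudogene",
    "polymorphic_pseudogene", "pseudogene", "processed_transcript",
    "lincRNA", "sense_intronic", "sense_overlapping",
    "3prime_overlapping_ncRNA", "antisense")
}

#' Read gene models from a GTF file
#'
#' Imports a GENCODE-style GTF (1-based inclusive coordinates, attributes
#' `gene_id`, `transcript_id`, `gene_type`) and returns a flat feature table
#' in 0-based half-open coordinates, restricted to Pol II gene types.
#' 5' and 3' UTR intervals are taken from explicit `UTR` /
#' `five_prime_utr` / `three_prime_utr` features when present and otherwise
#' derived per transcript as exon territory upstream/downstream of the CDS
#' span (strand-aware); generic `UTR` features are sided against the CDS span.
#'
#' @param path GTF file path.
#' @param allowed_gene_types Character vector of gene types to keep; default
#'   the Pol II list (protein_coding, IG/TR segment genes and pseudogenes,
#'   polymorphic_pseudogene, pseudogene, processed_transcript, lincRNA,
#'   sense_intronic, sense_overlapping, 3prime_overlapping_ncRNA, antisense).
#' @return Tibble with one row per feature interval: `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `feature` in
#'   `{gene, transcript, exon, cds, utr5, utr3}`, `gene_id`, `gene_type`,
#'   `transcript_id` (`NA` for gene rows).
#' @export
read_gtf <- function(path, allowed_gene_types = polii_gene_types()) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (nrow(df) == 0) return(empty_gene_models())
  for (col in c("type", "gene_id", "gene_type")) {
    if (is.null(df[[col]])) stop("GTF missing mandatory attribute/field: ", col)
  }
  bad <- which(df$type %in% c("transcript", "exon", "CDS", "UTR",
                              "five_prime_utr", "three_prime_utr") &
                 (is.na(df$transcript_id) | is.na(df$gene_id)))
  if (length(bad) > 0) {
    stop("GTF feature #", bad[1], " (", df$type[bad[1]],
         ") lacks a gene_id/transcript_id attribute")
  }
  feats <- tibble::tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,   # to 0-based half-open
    end = as.integer(df$end),
    strand = as.character(df$strand),
    feature = dplyr::recode(as.character(df$type),
                            CDS = "cds", UTR = "utr",
                            five_prime_utr = "utr5", three_prime_utr = "utr3"),
    gene_id = df$gene_id,
    gene_type = df$gene_type,
    transcript_id = if (!is.null(df$transcript_id)) df$transcript_id else NA_character_
  )
  feats <- dplyr::filter(feats, .data$gene_type %in% allowed_gene_types,
                         .data$feature %in% c("gene", "transcript", "exon",
                                              "cds", "utr", "utr5", "utr3"))
  validate_gene_models(feats)
  resolve_utrs(feats)
}

empty_gene_models <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), feature = character(),
                 gene_id = character(), gene_type = character(),
                 transcript_id = character())
}

validate_gene_models <- function(feats) {
  tx <- dplyr::filter(feats, .data$feature == "transcript")
  ex <- dplyr::filter(feats, .data$feature == "exon")
  if (nrow(tx) > 0 && nrow(ex) > 0) {
    span <- dplyr::summarise(dplyr::group_by(tx, .data$transcript_id),
                             tstart = min(.data$start), tend = max(.data$end),
                             .groups = "drop")
    chk <- dplyr::inner_join(ex, span, by = "transcript_id")
    out <- which(chk$start < chk$tstart | chk$end > chk$tend)
    if (length(out) > 0) {
      stop("exon outside its transcript span (transcript ",
           chk$transcript_id[out[1]], ")")
    }
  }
  invisible(feats)
}

# Assign generic "utr" features a side against the transcript CDS span and
# derive missing UTRs from exon - CDS territory.
resolve_utrs <- function(feats) {
  cds_span <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(feats, .data$feature == "cds"), .data$transcript_id),
    cstart = min(.data$start), cend = max(.data$end), .groups = "drop"
  )
  generic <- dplyr::filter(feats, .data$feature == "utr")
  rest <- dplyr::filter(feats, .data$feature != "utr")
  if (nrow(generic) > 0) {
    generic <- dplyr::left_join(generic, cds_span, by = "transcript_id")
    generic$feature <- ifelse(
      is.na(generic$cstart), "utr3",  # no CDS: treat as non-coding tail
      ifelse(generic$end <= generic$cstart,
             ifelse(generic$strand == "+", "utr5", "utr3"),
             ifelse(generic$strand == "+", "utr3", "utr5"))
    )
    generic <- dplyr::select(generic, -"cstart", -"cend")
  }
  feats <- dplyr::bind_rows(rest, generic)

  # Derive UTRs for coding transcripts that lack explicit UTR features.
  have_utr <- unique(feats$transcript_id[feats$feature %in% c("utr5", "utr3")])
  need <- dplyr::filter(cds_span, !(.data$transcript_id %in% have_utr))
  if (nrow(need) > 0) {
    ex <- dplyr::inner_join(
      dplyr::filter(feats, .data$feature == "exon"), need, by = "transcript_id"
    )
    left <- dplyr::filter(dplyr::mutate(ex, end = pmin(.data$end, .data$cstart)),
                          .data$start < .data$end)
    right <- dplyr::filter(dplyr::mutate(ex, start = pmax(.data$start, .data$cend)),
                           .data$start < .data$end)
    left$feature <- ifelse(left$strand == "+", "utr5", "utr3")
    right$feature <- ifelse(right$strand == "+", "utr3", "utr5")
    derived <- dplyr::select(dplyr::bind_rows(left, right), -"cstart", -"cend")
    feats <- dplyr::bind_rows(feats, derived)
  }
  dplyr::arrange(feats, .data$chrom, .data$start, .data$end, .data$feature)
}

as_iranges_list <- function(feats, chroms) {
  sp <- split(feats, factor(feats$chrom, levels = chroms))
  lapply(sp, function(d) IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

#' Project gene models onto a hierarchical genome partition
#'
#' Labels every genomic nucleotide on three nested levels: level 1 genomic
#' (`genic` iff covered by at least one gene span, else `intergenic`);
#' level 2 within genic (`exonic` iff covered by at least one exon of any
#' isoform, else `intronic`); level 3 within exonic (`coding`, `utr5`,
#' `utr3`, `noncoding`) with precedence coding > utr5 > utr3 > noncoding
#' across overlapping isoforms. Strand is ignored: partitions describe
#' genomic territory. Features extending past a chromosome end are clipped
#' with a warning.
#'
#' @param gene_models Feature table from [read_gtf()] or
#'   [simulate_gene_annotation()].
#' @param chrom_sizes Tibble with columns `chrom`, `size`.
#' @return A partition map: tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `level` (1, 2 or 3) and `label`; per level the intervals are
#'   disjoint and tile their parent territory (level 1 tiles the genome).
#' @export
project_partitions <- function(gene_models, chrom_sizes) {
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  missing_chr <- setdiff(unique(gene_models$chrom), chrom_sizes$chrom)
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from chrom_sizes: ", paste(missing_chr, collapse = ", "))
  }
  if (any(gene_models$end > chrom_sizes$size[match(gene_models$chrom, chrom_sizes$chrom)])) {
    warning("feature(s) extend past chromosome end; clipped")
    gene_models$end <- pmin(gene_models$end,
                            chrom_sizes$size[match(gene_models$chrom, chrom_sizes$chrom)])
    gene_models <- dplyr::filter(gene_models, .data$start < .data$end)
  }
  chroms <- chrom_sizes$chrom
  full <- lapply(seq_along(chroms), function(i) {
    IRanges::IRanges(start = 1L, end = chrom_sizes$size[i])
  })
  names(full) <- chroms

  gene_spans <- compute_spans(gene_models, "gene", "gene_id")
  genic <- as_iranges_list(gene_spans, chroms)
  exonic_raw <- as_iranges_list(dplyr::filter(gene_models, .data$feature == "exon"), chroms)
  coding_raw <- as_iranges_list(dplyr::filter(gene_models, .data$feature == "cds"), chroms)
  utr5_raw <- as_iranges_list(dplyr::filter(gene_models, .data$feature == "utr5"), chroms)
  utr3_raw <- as_iranges_list(dplyr::filter(gene_models, .data$feature == "utr3"), chroms)

  rows <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    g <- genic[[ch]]
    ig <- IRanges::setdiff(full[[ch]], g)
    ex <- IRanges::intersect(exonic_raw[[ch]], g)
    intr <- IRanges::setdiff(g, ex)
    cod <- IRanges::intersect(coding_raw[[ch]], ex)
    u5 <- IRanges::setdiff(IRanges::intersect(utr5_raw[[ch]], ex), cod)
    u3 <- IRanges::setdiff(IRanges::setdiff(IRanges::intersect(utr3_raw[[ch]], ex), cod), u5)
    nc <- IRanges::setdiff(IRanges::setdiff(IRanges::setdiff(ex, cod), u5), u3)
    rows[[ch]] <- dplyr::bind_rows(
      ir_to_tbl(g, ch, 1L, "genic"), ir_to_tbl(ig, ch, 1L, "intergenic"),
      ir_to_tbl(ex, ch, 2L, "exonic"), ir_to_tbl(intr, ch, 2L, "intronic"),
      ir_to_tbl(cod, ch, 3L, "coding"), ir_to_tbl(u5, ch, 3L, "utr5"),
      ir_to_tbl(u3, ch, 3L, "utr3"), ir_to_tbl(nc, ch, 3L, "noncoding")
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$level, .data$chrom, .data$start)
  attr(out, "chrom_sizes") <- chrom_sizes
  class(out) <- c("partition_map", class(out))
  out
}

compute_spans <- function(gene_models, feature, id_col) {
  explicit <- dplyr::filter(gene_models, .data$feature == !!feature)
  if (nrow(explicit) > 0) return(explicit)
  # fall back to exon hulls per gene/transcript
  dplyr::summarise(
    dplyr::group_by(dplyr::filter(gene_models, .data$feature == "exon"),
                    .data$chrom, .data[[id_col]]),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
}

ir_to_tbl <- function(ir, chrom, level, label) {
  if (length(ir) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          level = integer(), label = character()))
  }
  tibble::tibble(chrom = chrom, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), level = level, label = label)
}

# Label of the partition at single positions (0-based) on one level.
partition_label_at <- function(partition, chrom, pos, level = 1L) {
  lev <- dplyr::filter(partition, .data$level == !!level)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(lev$chrom, IRanges::IRanges(lev$start + 1L, lev$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  lev$label[hit]
}

#' Proportional Aluome coverage of genome partitions
#'
#' Intersects the Aluome (the union of all Alu nucleotides; overlapping
#' records are merged) with each partition label by exact base-wise
#' intersection (minimum one-nucleotide overlap), so an Alu spanning two
#' labels contributes its nucleotides to each pro rata. Reports, per level
#' and label, the nucleotide counts and fractions for genome and Aluome and
#' the enrichment ratio `aluome_fraction / genome_fraction`.
#'
#' @param alus Repeat tibble ([read_repeats()] columns). Alus on chromosomes
#'   absent from the partition are skipped with a warning.
#' @param partition Partition map from [project_partitions()].
#' @return Tibble: `level`, `label`, `genome_nt`, `genome_fraction`,
#'   `aluome_nt`, `aluome_fraction`, `enrichment`. Within each level the
#'   genome and Aluome fractions each sum to 1.
#' @export
aluome_coverage <- function(alus, partition) {
  known <- unique(partition$chrom)
  drop <- !(alus$chrom %in% known)
  if (any(drop)) {
    warning(sum(drop), " Alu record(s) on chromosomes absent from the partition; skipped")
    alus <- alus[!drop, , drop = FALSE]
  }
  aluome <- GenomicRanges::reduce(GenomicRanges::GRanges(
    alus$chrom, IRanges::IRanges(alus$start + 1L, alus$end)
  ))
  part_gr <- GenomicRanges::GRanges(
    partition$chrom, IRanges::IRanges(partition$start + 1L, partition$end)
  )
  hits <- GenomicRanges::findOverlaps(part_gr, aluome)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(part_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(aluome)[S4Vectors::subjectHits(hits)]
  ))
  alu_nt <- rep(0, nrow(partition))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  alu_nt[as.integer(names(agg))] <- agg

  tab <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(partition, width = .data$end - .data$start, alu_nt = alu_nt),
      .data$level, .data$label),
    genome_nt = sum(.data$width), aluome_nt = sum(.data$alu_nt), .groups = "drop_last"
  )
  tab <- dplyr::ungroup(dplyr::mutate(
    tab,
    genome_fraction = .data$genome_nt / sum(.data$genome_nt),
    aluome_fraction = if (sum(.data$aluome_nt) > 0)
      .data$aluome_nt / sum(.data$aluome_nt) else NA_real_
  ))
  lvl_order <- c(genic = 1, intergenic = 2, exonic = 1, intronic = 2,
                 coding = 1, utr5 = 2, utr3 = 3, noncoding = 4)
  dplyr::arrange(
    dplyr::mutate(tab, enrichment = .data$aluome_fraction / .data$genome_fraction),
    .data$level, lvl_order[.data$label]
  )[, c("level", "label", "genome_nt", "genome_fraction",
        "aluome_nt", "aluome_fraction", "enrichment")]
}
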