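# Writers for the standard plain-text formats the pipeline exchanges:
# UCSC rmsk-dialect TSV, BED6, GENCODE-style GTF, chrom.sizes and FPKM TSV.

#' Write a repeat table as an rmsk-dialect TSV
#'
#' Columns `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`,
#' `repClass`, `repFamily`, 0-based half-open, with a header line; the
#' dialect [read_repeats()] parses.
#'
#' @param repeats Tibble in the [read_repeats()] schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsk <- function(repeats, path) {
  out <- tibble::tibble(
    genoName = repeats$chrom, genoStart = repeats$start, genoEnd = repeats$end,
    strand = repeats$strand, repName = repeats$name, repClass = "SINE",
    repFamily = repeats$family
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a repeat or pair table as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end`, `strand` and either `name`
#'   or `orientation` (used as the BED name field; pair tables from
#'   [alu_pairs()] export their orientation class).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("orientation" %in% names(x)) x$orientation else x$name
  strand <- if ("strand" %in% names(x)) x$strand else "."
  out <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        name = name, score = 0L, strand = strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write gene models as a GENCODE-style GTF
#'
#' Emits `gene`, `transcript`, `exon`, `CDS` and `UTR` features (UTR sides
#' are re-derived by [read_gtf()] on import), 1-based inclusive coordinates,
#' with `gene_id`, `transcript_id` and `gene_type` attributes.
#'
#' @param gene_models Feature tibble in the [read_gtf()] schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##description: simulated GENCODE-style annotation", con)
  if (nrow(gene_models) == 0) return(invisible(path))
  feat <- dplyr::recode(gene_models$feature, cds = "CDS", utr5 = "UTR",
                        utr3 = "UTR", utr = "UTR")
  attrs <- ifelse(
    gene_models$feature == "gene",
    sprintf('gene_id "%s"; gene_type "%s";',
            gene_models$gene_id, gene_models$gene_type),
    sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
            gene_models$gene_id, gene_models$transcript_id,
            gene_models$gene_type)
  )
  lines <- sprintf("%s\taluscape_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   gene_models$chrom, feat, gene_models$start + 1L,
                   gene_models$end, gene_models$strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Write a chromosome-size table
#'
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param path Output path (two-column TSV, no header).
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a chromosome-size table
#'
#' @param path Two-column TSV (`chrom`, `size`), no header.
#' @return Tibble with `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"), col_types = "ci",
                  progress = FALSE)
}

#' Write / read an FPKM table
#'
#' Rows are transcripts, columns cell lines, first column `transcript_id`.
#'
#' @param fpkm Wide FPKM tibble.
#' @param path TSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_fpkm <- function(fpkm, path) {
  readr::write_tsv(fpkm, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fpkm
#' @export
read_fpkm <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
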