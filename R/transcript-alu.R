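# Per-transcript Alu configuration: keep Alus fully contained in exons of the
# mature transcript, project them into spliced transcript coordinates, and
# assign each transcript a configuration category (noSINE / single / tandem /
# iAlu, the inverted class refined into head_head / tail_tail when every
# adjacent pair shares that arrangement).

#' Alus fully contained in the exons of one transcript
#'
#' An Alu is retained iff its genomic interval lies entirely within a single
#' exon of the transcript: Alus straddling an exon boundary, spanning an
#' intron, or lying in introns are excluded (mature-transcript containment).
#'
#' @param exons Tibble of the transcript's exons: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param alus Repeat tibble ([read_repeats()] columns) on the same chromosome.
#' @return The subset of `alus` fully contained in single exons.
#' @export
assign_exonic_alus <- function(exons, alus) {
  if (nrow(alus) == 0 || nrow(exons) == 0) return(alus[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(alus)), function(i) {
    alus$chrom[i] %in% exons$chrom &&
      any(exons$chrom == alus$chrom[i] &
            exons$start <= alus$start[i] & alus$end[i] <= exons$end)
  }, logical(1))
  alus[keep, , drop = FALSE]
}

#' Project contained Alus into mature-transcript coordinates
#'
#' Maps genomic positions through the spliced exon chain. Transcript
#' coordinates are 0-based half-open along the mature transcript, 5' to 3':
#' for a minus-strand transcript the genomic order of exons and of positions
#' within them is reversed. `relative_orientation` is `sense` iff the repeat
#' strand equals the transcript strand.
#'
#' @param exons Tibble of the transcript's exons (`chrom`, `start`, `end`).
#' @param tx_strand `"+"` or `"-"`.
#' @param alus Output of [assign_exonic_alus()].
#' @return Tibble `name`, `family`, `tx_start`, `tx_end`,
#'   `relative_orientation`, sorted by `tx_start`.
#' @export
to_transcript_coords <- function(exons, tx_strand, alus) {
  stopifnot(tx_strand %in% c("+", "-"))
  exons <- dplyr::arrange(exons, .data$start)
  width <- exons$end - exons$start
  tx_len <- sum(width)
  offset <- cumsum(c(0L, width[-length(width)]))  # plus-strand spliced offset
  out <- purrr::map_dfr(seq_len(nrow(alus)), function(i) {
    e <- which(exons$start <= alus$start[i] & alus$end[i] <= exons$end)[1]
    p5 <- offset[e] + (alus$start[i] - exons$start[e])
    p3 <- offset[e] + (alus$end[i] - exons$start[e])
    if (tx_strand == "-") {
      tmp <- tx_len - p3
      p3 <- tx_len - p5
      p5 <- tmp
    }
    tibble::tibble(
      name = alus$name[i], family = alus$family[i],
      tx_start = p5, tx_end = p3,
      relative_orientation = if (alus$strand[i] == tx_strand) "sense" else "antisense"
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(name = character(), family = character(),
                          tx_start = integer(), tx_end = integer(),
                          relative_orientation = character()))
  }
  dplyr::arrange(out, .data$tx_start)
}

#' Classify a transcript by its exonic Alu configuration
#'
#' From the transcript-ordered relative orientations: zero Alus gives
#' `noSINE`; one gives `single`; two or more with every adjacent pair in the
#' same orientation gives `tandem`; at least one adjacent inverted pair gives
#' `iAlu`. Adjacent-pair arrangement in transcript coordinates:
#' (sense, antisense) is tail-to-tail, (antisense, sense) head-to-head,
#' equal orientations tandem. An `iAlu` transcript is additionally flagged
#' `head_head` when every adjacent pair is head-to-head and `tail_tail` when
#' every adjacent pair is tail-to-tail.
#'
#' @param orientations Character vector in `{"sense", "antisense"}`, ordered
#'   by transcript coordinate.
#' @return One-row tibble: `n_alus`, `category` in
#'   `{noSINE, single, tandem, iAlu}`, logical `head_head`, `tail_tail`.
#' @export
classify_transcript <- function(orientations) {
  n <- length(orientations)
  if (n > 0) stopifnot(all(orientations %in% c("sense", "antisense")))
  if (n == 0) {
    return(tibble::tibble(n_alus = 0L, category = "noSINE",
                          head_head = FALSE, tail_tail = FALSE))
  }
  if (n == 1) {
    return(tibble::tibble(n_alus = 1L, category = "single",
                          head_head = FALSE, tail_tail = FALSE))
  }
  a <- orientations[-n]
  b <- orientations[-1]
  pair <- dplyr::case_when(
    a == b ~ "tandem",
    a == "sense" ~ "tail_tail",
    TRUE ~ "head_head"
  )
  if (all(pair == "tandem")) {
    return(tibble::tibble(n_alus = n, category = "tandem",
                          head_head = FALSE, tail_tail = FALSE))
  }
  tibble::tibble(
    n_alus = n, category = "iAlu",
    head_head = all(pair == "head_head"),
    tail_tail = all(pair == "tail_tail")
  )
}

#' Adjacent-pair orientations of a transcript's Alus
#'
#' @param tx_alus Output of [to_transcript_coords()].
#' @return Tibble `orientation` in `{tandem, head_head, tail_tail}` and
#'   `same_family` per adjacent pair (length `max(0, n - 1)`); the family
#'   flag is annotation only and never enters category assignment.
#' @export
adjacent_pairs <- function(tx_alus) {
  n <- nrow(tx_alus)
  if (n < 2) {
    return(tibble::tibble(orientation = character(), same_family = logical()))
  }
  a <- tx_alus$relative_orientation[-n]
  b <- tx_alus$relative_orientation[-1]
  tibble::tibble(
    orientation = dplyr::case_when(
      a == b ~ "tandem",
      a == "sense" ~ "tail_tail",
      TRUE ~ "head_head"
    ),
    same_family = tx_alus$family[-n] == tx_alus$family[-1]
  )
}

#' Per-transcript Alu configuration profiles
#'
#' Runs the containment, projection and classification steps for every
#' transcript in a gene-model table. Categories are assigned per transcript
#' (not per gene), since expression is quantified per transcript.
#'
#' @param gene_models Feature table from [read_gtf()] or
#'   [simulate_gene_annotation()].
#' @param alus Repeat tibble ([read_repeats()] columns).
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `strand`, `n_alus`, `category`, `head_head`, `tail_tail`, and a
#'   list-column `alus` holding each transcript's [to_transcript_coords()]
#'   table.
#' @export
transcript_alu_profiles <- function(gene_models, alus) {
  ex <- dplyr::filter(gene_models, .data$feature == "exon")
  if (nrow(ex) == 0) {
    return(tibble::tibble(transcript_id = character(), gene_id = character(),
                          strand = character(), n_alus = integer(),
                          category = character(), head_head = logical(),
                          tail_tail = logical(), alus = list()))
  }
  alus <- dplyr::arrange(alus, .data$chrom, .data$start)
  purrr::map_dfr(split(ex, ex$transcript_id), function(exons) {
    cand <- alus[alus$chrom %in% exons$chrom, , drop = FALSE]
    contained <- assign_exonic_alus(exons, cand)
    txa <- to_transcript_coords(exons, exons$strand[1], contained)
    cls <- classify_transcript(txa$relative_orientation)
    dplyr::bind_cols(
      tibble::tibble(transcript_id = exons$transcript_id[1],
                     gene_id = exons$gene_id[1], strand = exons$strand[1]),
      cls,
      tibble::tibble(alus = list(txa))
    )
  })
}
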