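# Synthetic genomes with planted structure: repeat annotations whose true
# configuration class is known, multi-isoform gene models, and FPKM tables
# with a planted expression down-shift for inverted-configuration
# transcripts. Ground truth is returned alongside every table so downstream
# stages can be verified exactly.

encode_cell_lines <- function() {
  c("HepG2", "HSMM", "IMR90", "MCF7", "NHEK", "NHLF", "K562", "GM12878",
    "Huvec", "Sknsh", "A549", "AG04450", "BJ", "H1hESC", "HeLaS3")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation parameters for synthetic genomes
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests: two 500-kb chromosomes, 30 genes, and planted repeat
#' configurations of 60 singletons, 13 tandem pairs, 4 tail-to-tail pairs,
#' 3 head-to-head pairs and 5 clusters of three. Within-cluster gaps never
#' exceed the clustering threshold and between-cluster clearance always
#' exceeds it, so the planted class labels are unambiguous and recoverable
#' without error.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome, nt.
#' @param n_genes Number of genes (split across chromosomes).
#' @param exons_per_gene Integer range `c(min, max)` of exons per transcript.
#' @param utr3_length Range `c(min, max)` of 3' UTR length, nt; the
#'   default 1600-2600 keeps every UTR wide enough to host any planted unit.
#' @param planted_counts Named counts of planted configuration units over
#'   `sSINE`, `dSINE`, `hiSINE`, `tiSINE`, `cluster3plus`.
#' @param gap_range_within_cluster Range of gaps inside a planted cluster;
#'   its maximum must not exceed `cluster_max_gap`.
#' @param gap_min_between_clusters Minimum clearance between planted units;
#'   must exceed `cluster_max_gap`.
#' @param cluster_max_gap The clustering threshold the planted structure is
#'   calibrated against (default 300 nt).
#' @param alu_length Length of each simulated Alu element (default 300 nt,
#'   the characteristic length of a 7SL-derived Alu).
#' @param seed Integer seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_chromosomes = 2L,
                       chrom_length = 500000L,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 6L),
                       utr3_length = c(1600L, 2600L),
                       planted_counts = c(sSINE = 60L, dSINE = 13L,
                                          tiSINE = 4L, hiSINE = 3L,
                                          cluster3plus = 5L),
                       gap_range_within_cluster = c(20L, 300L),
                       gap_min_between_clusters = 1000L,
                       cluster_max_gap = 300L,
                       alu_length = 300L,
                       seed = 1L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chrom_length = as.integer(chrom_length),
            n_genes = as.integer(n_genes),
            exons_per_gene = as.integer(exons_per_gene),
            utr3_length = as.integer(utr3_length),
            planted_counts = planted_counts,
            gap_range_within_cluster = as.integer(gap_range_within_cluster),
            gap_min_between_clusters = as.integer(gap_min_between_clusters),
            cluster_max_gap = as.integer(cluster_max_gap),
            alu_length = as.integer(alu_length),
            seed = as.integer(seed))
  stopifnot(p$n_chromosomes >= 1, p$chrom_length >= 1000, p$n_genes >= 0,
            length(p$exons_per_gene) == 2, p$exons_per_gene[1] >= 2,
            length(p$utr3_length) == 2, p$utr3_length[1] >= 1,
            p$alu_length >= 1)
  unknown <- setdiff(names(p$planted_counts),
                     c("sSINE", "dSINE", "hiSINE", "tiSINE", "cluster3plus"))
  if (length(unknown) > 0) stop("unknown planted class(es): ", paste(unknown, collapse = ", "))
  if (max(p$gap_range_within_cluster) > p$cluster_max_gap) {
    stop("gap_range_within_cluster must not exceed the clustering threshold (",
         p$cluster_max_gap, " nt): planted cluster labels would be ambiguous")
  }
  if (p$gap_min_between_clusters <= p$cluster_max_gap) {
    stop("gap_min_between_clusters must exceed the clustering threshold (",
         p$cluster_max_gap, " nt): planted units could merge")
  }
  structure(p, class = "sim_params")
}

unit_sizes <- c(sSINE = 1L, dSINE = 2L, tiSINE = 2L, hiSINE = 2L, cluster3plus = 3L)

alu_subfamilies <- function() {
  c("AluSp", "AluSx", "AluSg", "AluSc", "AluY", "AluJb", "AluJo", "AluSq")
}

#' Simulate a repeat annotation with planted configurations
#'
#' Places the configuration units of `params$planted_counts` on the simulated
#' chromosomes: singletons, strand-defined pairs (tandem `dSINE` on equal
#' strands, tail-to-tail `tiSINE` as `(+,-)`, head-to-head `hiSINE` as
#' `(-,+)`) and clusters of three with random strands. Within-unit gaps are
#' drawn from `gap_range_within_cluster`; every unit keeps at least
#' `gap_min_between_clusters` clearance from every other, so distance
#' clustering at the calibrated threshold recovers the planted labels
#' exactly. When gene models are supplied, each unit is placed in a genomic
#' compartment (3' UTR exon, intron or intergenic space) drawn from
#' `placement`; otherwise units are placed uniformly along the chromosomes
#' (compartment recorded as `"genome"`).
#'
#' @param params A [sim_params()] object.
#' @param gene_models Optional feature table from
#'   [simulate_gene_annotation()] for compartment-aware placement.
#' @param placement Named probabilities over `utr3`, `intron`, `intergenic`.
#' @return List with `repeats` (tibble in [read_repeats()] schema) and
#'   `truth` (tibble `unit_id`, `class`, `chrom`, `start`, `end`, `size`,
#'   `compartment`). Identical seeds give identical tables.
#' @export
simulate_repeat_annotation <- function(params, gene_models = NULL,
                                       placement = c(utr3 = 0.25, intron = 0.25,
                                                     intergenic = 0.5)) {
  stopifnot(inherits(params, "sim_params"))
  placement <- placement / sum(placement)
  chroms <- paste0("chrS", seq_len(params$n_chromosomes))
  regions <- compartment_regions(params, gene_models, chroms)
  with_local_seed(params$seed + 1L, {
    units <- rep(names(params$planted_counts), times = params$planted_counts)
    if (length(units) > 0) units <- sample(units)  # interleave classes
    placed <- list()       # per chromosome: matrix of occupied [start, end)
    reps <- list()
    truth <- list()
    for (u in seq_along(units)) {
      cls <- units[u]
      size <- unit_sizes[[cls]]
      gaps <- if (size > 1) {
        sample(seq(params$gap_range_within_cluster[1],
                   params$gap_range_within_cluster[2]), size - 1, replace = TRUE)
      } else integer(0)
      span <- size * params$alu_length + sum(gaps)
      comp <- if (is.null(gene_models)) "genome" else
        sample(names(placement), 1, prob = placement)
      pos <- place_unit(regions[[comp]], span, params$gap_min_between_clusters,
                        placed)
      if (is.null(pos)) {
        stop("cannot fit planted unit ", u, " (", cls, ", span ", span,
             " nt) in compartment '", comp, "': capacity exceeded")
      }
      ch <- pos$chrom
      placed[[ch]] <- rbind(placed[[ch]], c(pos$start, pos$start + span))
      starts <- pos$start + cumsum(c(0L, rep(params$alu_length, size - 1) + gaps))
      strands <- switch(cls,
        sSINE = sample(c("+", "-"), 1),
        dSINE = rep(sample(c("+", "-"), 1), 2),
        tiSINE = c("+", "-"),
        hiSINE = c("-", "+"),
        cluster3plus = sample(c("+", "-"), size, replace = TRUE)
      )
      reps[[u]] <- tibble::tibble(
        chrom = ch, start = starts, end = starts + params$alu_length,
        strand = strands,
        name = sample(alu_subfamilies(), size, replace = TRUE),
        family = "Alu"
      )
      truth[[u]] <- tibble::tibble(
        unit_id = u, class = cls, chrom = ch, start = pos$start,
        end = pos$start + span, size = size, compartment = comp
      )
    }
    repeats <- if (length(reps) > 0) dplyr::bind_rows(reps) else
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), name = character(), family = character())
    list(repeats = dplyr::arrange(repeats, .data$chrom, .data$start),
         truth = if (length(truth) > 0) dplyr::bind_rows(truth) else
           tibble::tibble(unit_id = integer(), class = character(),
                          chrom = character(), start = integer(),
                          end = integer(), size = integer(),
                          compartment = character()))
  })
}

# Candidate intervals per compartment as a tibble (chrom, start, end).
compartment_regions <- function(params, gene_models, chroms) {
  whole <- tibble::tibble(chrom = chroms, start = 0L, end = params$chrom_length)
  if (is.null(gene_models)) {
    return(list(genome = whole))
  }
  utr3 <- dplyr::select(dplyr::filter(gene_models, .data$feature == "utr3"),
                        "chrom", "start", "end")
  ex <- dplyr::filter(gene_models, .data$feature == "exon")
  introns <- dplyr::bind_rows(lapply(split(ex, ex$transcript_id), function(d) {
    d <- dplyr::arrange(d, .data$start)
    if (nrow(d) < 2) return(NULL)
    tibble::tibble(chrom = d$chrom[1], start = d$end[-nrow(d)], end = d$start[-1])
  }))
  # intergenic = chromosome minus gene spans
  genes <- dplyr::filter(gene_models, .data$feature == "gene")
  intergenic <- dplyr::bind_rows(lapply(chroms, function(ch) {
    g <- dplyr::filter(genes, .data$chrom == ch)
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, params$chrom_length), ir)
    tibble::tibble(chrom = ch, start = IRanges::start(gaps) - 1L,
                   end = IRanges::end(gaps))
  }))
  list(utr3 = utr3, intron = introns, intergenic = intergenic)
}

# Pick a start for a unit of the given span inside one of the candidate
# regions, keeping `clearance` nt from every already-placed unit.
place_unit <- function(regions, span, clearance, placed, max_tries = 400L) {
  if (nrow(regions) == 0) return(NULL)
  ok <- regions[regions$end - regions$start >= span, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  for (t in seq_len(max_tries)) {
    r <- ok[sample.int(nrow(ok), 1), ]
    start <- r$start + sample.int(r$end - r$start - span + 1L, 1) - 1L
    occ <- placed[[r$chrom]]
    clash <- !is.null(occ) &&
      any(start < occ[, 2] + clearance & occ[, 1] - clearance < start + span)
    if (!clash) return(list(chrom = r$chrom, start = start))
  }
  NULL
}

#' Simulate a multi-isoform gene annotation
#'
#' Builds `n_genes` multi-exon genes with CDS, 5' UTR and 3' UTR features,
#' alternating strands, placed left-to-right across the chromosomes with
#' randomized intergenic spacing. The first gene carries a second isoform
#' with an extra exon inside an intron of the first isoform (and one exon
#' skipped), so a position can be exonic in one isoform and intronic in
#' another — the case hierarchical projection has to resolve.
#'
#' @param params A [sim_params()] object.
#' @return List with `gene_models` (feature tibble in the [read_gtf()]
#'   schema) and `chrom_sizes` (tibble `chrom`, `size`).
#' @export
simulate_gene_annotation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  chroms <- paste0("chrS", seq_len(params$n_chromosomes))
  chrom_sizes <- tibble::tibble(chrom = chroms, size = params$chrom_length)
  if (params$n_genes == 0) {
    return(list(gene_models = empty_gene_models(), chrom_sizes = chrom_sizes))
  }
  with_local_seed(params$seed + 2L, {
    rows <- list()
    per_chrom <- split(seq_len(params$n_genes),
                       rep(chroms, length.out = params$n_genes))
    for (ch in names(per_chrom)) {
      cursor <- min(5000L, params$chrom_length %/% 10L)
      for (g in per_chrom[[ch]]) {
        n_ex <- sample(seq(params$exons_per_gene[1], params$exons_per_gene[2]), 1)
        u3 <- sample(seq(params$utr3_length[1], params$utr3_length[2]), 1)
        u5 <- sample(100:200, 1)
        exon_w <- c(u5 + 300L,
                    if (n_ex > 2) sample(150:400, n_ex - 2, replace = TRUE) else integer(0),
                    u3 + 300L)
        intron_max <- max(600L, min(2000L, params$chrom_length %/% 250L))
        intron_w <- sample(500:intron_max, n_ex - 1, replace = TRUE)
        strand <- if (g %% 2 == 0) "-" else "+"
        span <- sum(exon_w) + sum(intron_w)
        if (cursor + span + 2000L > params$chrom_length) {
          stop("cannot fit gene ", g, " on ", ch, ": capacity exceeded")
        }
        gid <- sprintf("GENE%04d", g)
        rows[[length(rows) + 1L]] <-
          build_gene(gid, ch, cursor, strand, exon_w, intron_w, u5, u3,
                     with_alt_isoform = (g == 1))
        spc_min <- max(800L, params$chrom_length %/% 150L)
        spc_max <- max(1600L, params$chrom_length %/% 60L)
        cursor <- cursor + span + sample(spc_min:spc_max, 1)
      }
    }
    list(gene_models = dplyr::arrange(dplyr::bind_rows(rows),
                                      .data$chrom, .data$start, .data$feature),
         chrom_sizes = chrom_sizes)
  })
}

# Assemble one gene's feature rows. Exon widths/intron widths are genomic
# left-to-right; the mature 5'UTR/CDS/3'UTR layout is mapped through the
# spliced chain respecting strand.
build_gene <- function(gid, chrom, start, strand, exon_w, intron_w, u5, u3,
                       with_alt_isoform = FALSE) {
  n_ex <- length(exon_w)
  ex_start <- start + cumsum(c(0L, exon_w[-n_ex] + intron_w))
  ex_end <- ex_start + exon_w
  tx1 <- paste0(gid, ".T1")
  mature_len <- sum(exon_w)
  cds_m <- c(u5, mature_len - u3)  # mature-coordinate CDS interval [a, b)
  stopifnot(cds_m[2] - cds_m[1] >= 3)

  # map a mature-coordinate interval to genomic sub-intervals of the exons
  map_back <- function(m_start, m_end) {
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    off <- 0L
    out <- NULL
    for (e in ord) {
      w <- exon_w[e]
      lo <- max(m_start - off, 0L)
      hi <- min(m_end - off, w)
      if (lo < hi) {
        gen <- if (strand == "+") c(ex_start[e] + lo, ex_start[e] + hi)
        else c(ex_end[e] - hi, ex_end[e] - lo)
        out <- rbind(out, gen)
      }
      off <- off + w
    }
    out
  }
  feat_rows <- function(mat, feature, tx) {
    if (is.null(mat)) return(NULL)
    tibble::tibble(chrom = chrom, start = as.integer(mat[, 1]),
                   end = as.integer(mat[, 2]), strand = strand,
                   feature = feature, gene_id = gid,
                   gene_type = "protein_coding", transcript_id = tx)
  }
  rows <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, start = ex_start[1], end = ex_end[n_ex],
                   strand = strand, feature = "gene", gene_id = gid,
                   gene_type = "protein_coding", transcript_id = NA_character_),
    tibble::tibble(chrom = chrom, start = ex_start[1], end = ex_end[n_ex],
                   strand = strand, feature = "transcript", gene_id = gid,
                   gene_type = "protein_coding", transcript_id = tx1),
    tibble::tibble(chrom = chrom, start = ex_start, end = ex_end,
                   strand = strand, feature = "exon", gene_id = gid,
                   gene_type = "protein_coding", transcript_id = tx1),
    feat_rows(map_back(cds_m[1], cds_m[2]), "cds", tx1),
    feat_rows(map_back(0L, cds_m[1]), "utr5", tx1),
    feat_rows(map_back(cds_m[2], mature_len), "utr3", tx1)
  )
  if (with_alt_isoform && n_ex >= 3) {
    tx2 <- paste0(gid, ".T2")
    # skip exon 2, add a novel exon in the middle of intron 2 (non-coding)
    novel_start <- ex_end[2] + (ex_start[3] - ex_end[2]) %/% 3L
    novel_end <- novel_start + 120L
    alt_starts <- c(ex_start[1], novel_start, ex_start[3:n_ex])
    alt_ends <- c(ex_end[1], novel_end, ex_end[3:n_ex])
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(chrom = chrom, start = alt_starts[1],
                     end = alt_ends[length(alt_ends)], strand = strand,
                     feature = "transcript", gene_id = gid,
                     gene_type = "protein_coding", transcript_id = tx2),
      tibble::tibble(chrom = chrom, start = as.integer(alt_starts),
                     end = as.integer(alt_ends), strand = strand,
                     feature = "exon", gene_id = gid,
                     gene_type = "protein_coding", transcript_id = tx2)
    )
  }
  rows
}

#' Simulate an FPKM expression table with a planted repression
#'
#' Draws log-normal FPKM values independently per transcript and cell line.
#' Transcripts in an inverted configuration (category `iAlu`, which includes
#' the head-to-head and tail-to-tail subsets) have their expectation
#' multiplied by `repression_factor`, emulating the reduced expression of
#' inverted-Alu transcripts; with `repression_factor = 1` all categories are
#' drawn from the identical distribution.
#'
#' @param profiles Tibble with `transcript_id` and `category` columns
#'   (e.g. from [transcript_alu_profiles()]).
#' @param n_cell_lines Number of cell lines (default 15, the ENCODE panel;
#'   the first 15 columns carry the ENCODE cell-line names).
#' @param baseline_log_mean,baseline_log_sd Mean and sd of log FPKM
#'   (defaults `log(20)` and 0.8).
#' @param repression_factor Multiplicative FPKM shift for inverted-category
#'   transcripts, in (0, 1] (default 0.6, i.e. a 40 % reduction).
#' @param seed Integer seed.
#' @return List with `fpkm` (wide tibble, `transcript_id` plus one column
#'   per cell line) and `truth` (tibble `transcript_id`, `category`,
#'   `repressed`, `factor`).
#' @export
simulate_expression <- function(profiles, n_cell_lines = 15L,
                                baseline_log_mean = log(20),
                                baseline_log_sd = 0.8,
                                repression_factor = 0.6, seed = 1L) {
  stopifnot(repression_factor > 0, repression_factor <= 1, n_cell_lines >= 1)
  cells <- encode_cell_lines()
  cells <- if (n_cell_lines <= length(cells)) cells[seq_len(n_cell_lines)] else
    c(cells, sprintf("cell%02d", seq_len(n_cell_lines - length(cells))))
  with_local_seed(seed + 3L, {
    repressed <- profiles$category == "iAlu"
    mu <- baseline_log_mean + log(ifelse(repressed, repression_factor, 1))
    vals <- matrix(
      exp(stats::rnorm(nrow(profiles) * n_cell_lines,
                       mean = rep(mu, each = n_cell_lines),
                       sd = baseline_log_sd)),
      nrow = nrow(profiles), ncol = n_cell_lines, byrow = TRUE
    )
    colnames(vals) <- cells
    fpkm <- dplyr::bind_cols(
      tibble::tibble(transcript_id = profiles$transcript_id),
      tibble::as_tibble(vals)
    )
    truth <- tibble::tibble(
      transcript_id = profiles$transcript_id,
      category = profiles$category,
      repressed = repressed,
      factor = ifelse(repressed, repression_factor, 1)
    )
    list(fpkm = fpkm, truth = truth)
  })
}
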