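# Repeat catalog: parse repeat annotation, cluster Alu elements by genomic
# distance, and classify single / tandem / inverted configurations.

#' Read a repeat annotation track
#'
#' Parses a repeat annotation file and restricts it to one repeat family.
#' Two dialects are supported: `"rmsk"`, a UCSC RepeatMasker-style TSV with
#' columns `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`,
#' `repClass`, `repFamily` (0-based half-open coordinates, header line
#' required), and `"bed6"`, standard BED6 (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`, no header). BED6 carries no family column, so a record
#' is kept iff its name field starts with `family_filter` (e.g. `AluSp`
#' matches family `Alu`).
#'
#' @param path Path to the annotation file.
#' @param dialect `"rmsk"` or `"bed6"`.
#' @param family_filter Repeat family to retain (default `"Alu"`).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `name`, `family`, sorted by `(chrom, start, end)`.
#' @export
read_repeats <- function(path, dialect = c("rmsk", "bed6"), family_filter = "Alu") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("repeat file not found: ", path)
  if (dialect == "rmsk") {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName", "repFamily")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) stop("rmsk file missing column(s): ", paste(miss, collapse = ", "))
    starts <- suppressWarnings(as.integer(tab$genoStart))
    ends <- suppressWarnings(as.integer(tab$genoEnd))
    bad <- which(is.na(starts) | is.na(ends) |
                   !(tab$strand %in% c("+", "-")) | starts >= ends)
    if (length(bad) > 0) {
      stop("malformed rmsk row at line ", bad[1] + 1L,
           " (non-numeric coordinates, bad strand, or start >= end)")
    }
    out <- tibble::tibble(
      chrom = tab$genoName, start = starts, end = ends,
      strand = tab$strand, name = tab$repName, family = tab$repFamily
    )
  } else {
    tab <- readr::read_tsv(path,
                           col_names = c("chrom", "start", "end", "name", "score", "strand"),
                           col_types = "ciiccc", progress = FALSE)
    bad <- which(is.na(tab$start) | is.na(tab$end) |
                   !(tab$strand %in% c("+", "-")) | tab$start >= tab$end)
    if (length(bad) > 0) stop("malformed BED row at line ", bad[1])
    out <- tibble::tibble(
      chrom = tab$chrom, start = tab$start, end = tab$end,
      strand = tab$strand, name = tab$name,
      family = ifelse(startsWith(tab$name, family_filter), family_filter,
                      sub("[0-9].*$", "", tab$name))
    )
  }
  out <- dplyr::filter(out, .data$family == family_filter)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Cluster Alu elements by genomic distance
#'
#' Single-linkage chaining along each chromosome: consecutive repeats (sorted
#' by start) join the same cluster iff the gap between them, computed as
#' `next start - previous end` in 0-based half-open coordinates, is at most
#' `max_gap`. A gap of 0 means the elements are adjacent; the boundary is
#' inclusive, so a gap of exactly `max_gap` joins. Overlapping records
#' (negative gap) are treated as gap 0 and always joined.
#'
#' @param repeats Tibble of repeat records as returned by [read_repeats()].
#' @param max_gap Maximum gap in nucleotides for two neighbours to share a
#'   cluster (default 300).
#' @return The input tibble with added columns `cluster_id` (integer, unique
#'   across chromosomes), `cluster_size`, and `member_index` (1-based position
#'   within the cluster by genomic order).
#' @export
cluster_alus <- function(repeats, max_gap = 300) {
  stopifnot(is.numeric(max_gap), max_gap >= 0)
  if (nrow(repeats) == 0) {
    return(dplyr::mutate(repeats, cluster_id = integer(), cluster_size = integer(),
                         member_index = integer()))
  }
  repeats <- dplyr::arrange(repeats, .data$chrom, .data$start, .data$end)
  new_chrom <- c(TRUE, repeats$chrom[-1] != repeats$chrom[-nrow(repeats)])
  # running max of end per chromosome guards against contained intervals
  prev_end <- dplyr::lag(cummax_by_group(repeats$end, repeats$chrom))
  gap <- repeats$start - prev_end
  n_overlap <- sum(!new_chrom & gap < 0, na.rm = TRUE)
  if (n_overlap > 0) {
    message(n_overlap, " overlapping repeat record(s) merged (gap < 0 treated as 0)")
  }
  breaks <- new_chrom | (gap > max_gap)
  cluster_id <- cumsum(breaks)
  repeats$cluster_id <- cluster_id
  repeats <- dplyr::mutate(
    dplyr::group_by(repeats, .data$cluster_id),
    cluster_size = dplyr::n(),
    member_index = dplyr::row_number()
  )
  dplyr::ungroup(repeats)
}

cummax_by_group <- function(x, g) {
  unlist(lapply(split(x, factor(g, levels = unique(g))), cummax), use.names = FALSE)
}

#' Classify the orientation of an Alu pair
#'
#' For two repeats on the same chromosome in genomic order: both on the same
#' strand form a direct (tandem) pair, `dSINE`; `(+,-)` puts the two 3' ends
#' facing each other, a tail-to-tail inverted pair, `tiSINE`; `(-,+)` puts the
#' 5' ends facing, a head-to-head inverted pair, `hiSINE`.
#'
#' @param strand_left,strand_right Strand of the left and right element
#'   (genomic order); vectorized.
#' @return Character vector in `{"dSINE", "hiSINE", "tiSINE"}`.
#' @export
classify_pair <- function(strand_left, strand_right) {
  stopifnot(all(strand_left %in% c("+", "-")), all(strand_right %in% c("+", "-")))
  dplyr::case_when(
    strand_left == strand_right ~ "dSINE",
    strand_left == "+" ~ "tiSINE",
    TRUE ~ "hiSINE"
  )
}

#' Per-cluster configuration labels
#'
#' Collapses a clustered repeat table to one row per cluster with the
#' configuration class: `sSINE` for singletons, `dSINE`/`hiSINE`/`tiSINE`
#' for pairs (by [classify_pair()]), and `cluster3plus` for clusters of three
#' or more elements.
#'
#' @param clustered Output of [cluster_alus()].
#' @return Tibble with `cluster_id`, `chrom`, `start`, `end` (cluster span),
#'   `size`, `class`.
#' @export
cluster_classes <- function(clustered) {
  per <- dplyr::summarise(
    dplyr::group_by(clustered, .data$cluster_id),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$start),
    end = max(.data$end),
    size = dplyr::n(),
    s1 = dplyr::first(.data$strand),
    s2 = dplyr::nth(.data$strand, 2L),
    .groups = "drop"
  )
  per$class <- ifelse(per$size == 1L, "sSINE",
                      ifelse(per$size > 2L, "cluster3plus", NA_character_))
  two <- which(per$size == 2L)
  if (length(two) > 0) per$class[two] <- classify_pair(per$s1[two], per$s2[two])
  dplyr::select(per, -"s1", -"s2")
}

#' Summarize an Alu catalog
#'
#' Computes genome-wide configuration fractions over all Alu elements:
#' single vs clustered, the fraction arranged in pairs (clusters of exactly
#' two; both members counted), and the split of paired Alus into direct
#' (`dSINE`) and inverted (`iSINE`) pairs, the latter further into
#' head-to-head (`hiSINE`) and tail-to-tail (`tiSINE`). Clusters of three or
#' more contribute to `fraction_clustered` only: orientation fractions are
#' restricted to Alus with exactly one partner within the clustering gap.
#'
#' Neighbour-spacing statistics are also reported. `median_neighbor_gap` is,
#' by default, the median over gaps between consecutive Alus per chromosome;
#' `fraction_within_median` is the fraction of Alus whose nearest
#' same-chromosome neighbour gap is at most that median. `median_over =
#' "nearest"` instead takes the median of per-element nearest-neighbour gaps,
#' and `within_counts = "gaps"` counts consecutive gaps rather than elements.
#'
#' @param clustered Output of [cluster_alus()].
#' @param median_over `"consecutive"` (default) or `"nearest"`.
#' @param within_counts `"alus"` (default) or `"gaps"`.
#' @return One-row tibble: `n_alus`, `fraction_single`, `fraction_clustered`,
#'   `fraction_in_pairs`, `fraction_dSINE`, `fraction_iSINE`,
#'   `fraction_hiSINE`, `fraction_tiSINE`, `median_neighbor_gap`,
#'   `fraction_within_median`. Fractions are `NA` on empty input.
#' @export
summarize_catalog <- function(clustered,
                              median_over = c("consecutive", "nearest"),
                              within_counts = c("alus", "gaps")) {
  median_over <- match.arg(median_over)
  within_counts <- match.arg(within_counts)
  n <- nrow(clustered)
  if (n == 0) {
    return(tibble::tibble(
      n_alus = 0L, fraction_single = NA_real_, fraction_clustered = NA_real_,
      fraction_in_pairs = NA_real_, fraction_dSINE = NA_real_,
      fraction_iSINE = NA_real_, fraction_hiSINE = NA_real_,
      fraction_tiSINE = NA_real_, median_neighbor_gap = NA_real_,
      fraction_within_median = NA_real_
    ))
  }
  cls <- cluster_classes(clustered)
  n_single <- sum(cls$size[cls$class == "sSINE"])
  n_d <- 2L * sum(cls$class == "dSINE")
  n_hi <- 2L * sum(cls$class == "hiSINE")
  n_ti <- 2L * sum(cls$class == "tiSINE")

  gaps <- neighbor_gaps(clustered)
  med <- if (length(gaps$consecutive) > 0) {
    if (median_over == "consecutive") stats::median(gaps$consecutive)
    else stats::median(gaps$nearest[is.finite(gaps$nearest)])
  } else NA_real_
  fwm <- if (is.na(med)) NA_real_ else if (within_counts == "alus") {
    mean(gaps$nearest <= med)
  } else {
    mean(gaps$consecutive <= med)
  }

  tibble::tibble(
    n_alus = n,
    fraction_single = n_single / n,
    fraction_clustered = 1 - n_single / n,
    fraction_in_pairs = (n_d + n_hi + n_ti) / n,
    fraction_dSINE = n_d / n,
    fraction_iSINE = (n_hi + n_ti) / n,
    fraction_hiSINE = n_hi / n,
    fraction_tiSINE = n_ti / n,
    median_neighbor_gap = med,
    fraction_within_median = fwm
  )
}

# Consecutive and nearest-neighbour gaps (end-to-start, clamped at 0) for a
# coordinate-sorted repeat table. nearest is Inf for a chromosome singleton.
neighbor_gaps <- function(repeats) {
  repeats <- dplyr::arrange(repeats, .data$chrom, .data$start, .data$end)
  consecutive <- numeric(0)
  nearest <- numeric(0)
  for (d in split(repeats, factor(repeats$chrom, levels = unique(repeats$chrom)))) {
    m <- nrow(d)
    if (m == 1) {
      nearest <- c(nearest, Inf)
      next
    }
    g <- pmax(d$start[-1] - d$end[-m], 0)
    consecutive <- c(consecutive, g)
    nearest <- c(nearest, pmin(c(Inf, g), c(g, Inf)))
  }
  list(consecutive = consecutive, nearest = nearest)
}

#' Stratify a catalog by genomic region
#'
#' Assigns each Alu cluster to the genic or intergenic stratum by the
#' level-1 partition label at its span midpoint, then summarizes each stratum
#' with [summarize_catalog()]. A cluster spanning a genic/intergenic boundary
#' is assigned by its midpoint and counted once.
#'
#' @param clustered Output of [cluster_alus()].
#' @param partition Partition map from [project_partitions()].
#' @param ... Passed to [summarize_catalog()].
#' @return Tibble with a `region` column (`genic`, `intergenic`) followed by
#'   the [summarize_catalog()] columns, one row per stratum.
#' @export
stratify_by_region <- function(clustered, partition, ...) {
  spans <- dplyr::summarise(
    dplyr::group_by(clustered, .data$cluster_id),
    chrom = dplyr::first(.data$chrom),
    mid = (min(.data$start) + max(.data$end)) %/% 2L,
    .groups = "drop"
  )
  spans$region <- partition_label_at(partition, spans$chrom, spans$mid, level = 1L)
  lab <- dplyr::left_join(
    clustered, dplyr::select(spans, "cluster_id", "region"), by = "cluster_id"
  )
  out <- dplyr::bind_rows(lapply(c("genic", "intergenic"), function(r) {
    dplyr::bind_cols(
      tibble::tibble(region = r),
      summarize_catalog(dplyr::filter(lab, .data$region == r), ...)
    )
  }))
  out
}

#' Per-pair table with orientations
#'
#' Extracts all clusters of exactly two Alus as a pair table with the gap and
#' the orientation class, suitable for BED-style export.
#'
#' @param clustered Output of [cluster_alus()].
#' @return Tibble: `chrom`, `start`, `end` (pair span), `gap`, `orientation`,
#'   `name_left`, `name_right`, `same_name`.
#' @export
alu_pairs <- function(clustered) {
  pairs <- dplyr::filter(clustered, .data$cluster_size == 2L)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          gap = integer(), orientation = character(),
                          name_left = character(), name_right = character(),
                          same_name = logical()))
  }
  dplyr::summarise(
    dplyr::group_by(pairs, .data$cluster_id),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$start),
    end = max(.data$end),
    gap = max(.data$start) - min(.data$end),
    orientation = classify_pair(dplyr::first(.data$strand), dplyr::nth(.data$strand, 2L)),
    name_left = dplyr::first(.data$name),
    name_right = dplyr::nth(.data$name, 2L),
    same_name = dplyr::n_distinct(.data$name) == 1L,
    .groups = "drop"
  )
}
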