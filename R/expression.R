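# Expression stratification by Alu configuration: FPKM filtering, pooling of
# transcript x cell-line observations per configuration category, and
# Wilcoxon rank-sum comparisons between categories.

#' Filter transcripts by expression level
#'
#' Keeps a transcript iff its FPKM is at least `min_fpkm` in every cell line
#' (boundary inclusive: FPKM exactly equal to the cutoff survives). With
#' `require_all_cell_lines = FALSE` a single passing cell line suffices.
#' Transcripts with any missing value are dropped with a message.
#'
#' @param fpkm Tibble with a `transcript_id` column and one numeric column
#'   per cell line.
#' @param min_fpkm FPKM cutoff (default 3).
#' @param require_all_cell_lines Require the cutoff in every cell line
#'   (default `TRUE`).
#' @return The surviving rows of `fpkm`.
#' @export
filter_expressed <- function(fpkm, min_fpkm = 3, require_all_cell_lines = TRUE) {
  stopifnot(min_fpkm >= 0)
  cell_cols <- setdiff(names(fpkm), "transcript_id")
  if (length(cell_cols) == 0) stop("FPKM table has no cell-line columns")
  vals <- as.matrix(fpkm[, cell_cols, drop = FALSE])
  has_na <- rowSums(is.na(vals)) > 0
  if (any(has_na)) {
    message(sum(has_na), " transcript(s) with missing FPKM dropped")
  }
  pass <- if (require_all_cell_lines) {
    rowSums(vals >= min_fpkm) == ncol(vals)
  } else {
    rowSums(vals >= min_fpkm) >= 1
  }
  fpkm[!has_na & pass, , drop = FALSE]
}

#' Pool expression observations by configuration category
#'
#' Each surviving transcript contributes one observation per cell line to the
#' pool of every category it belongs to. The seven categories follow the
#' configuration classes: `all` (every surviving transcript), `noSINE`,
#' `single`, `tandem`, `iAlu`, and the `head_head` / `tail_tail` subsets of
#' `iAlu`. `noSINE`, `single`, `tandem` and `iAlu` are mutually exclusive;
#' `all`, `head_head` and `tail_tail` overlap them by construction.
#'
#' @param fpkm Filtered FPKM tibble (see [filter_expressed()]).
#' @param profiles Output of [transcript_alu_profiles()] (needs
#'   `transcript_id`, `category`, `head_head`, `tail_tail`). Transcripts
#'   without a profile are excluded with a warning.
#' @return Long tibble of pooled observations: `category`, `transcript_id`,
#'   `cell_line`, `fpkm`.
#' @export
pool_by_category <- function(fpkm, profiles) {
  missing <- setdiff(fpkm$transcript_id, profiles$transcript_id)
  if (length(missing) > 0) {
    warning(length(missing), " transcript(s) without a configuration profile excluded")
    fpkm <- dplyr::filter(fpkm, !(.data$transcript_id %in% missing))
  }
  long <- tidyr::pivot_longer(fpkm, -"transcript_id",
                              names_to = "cell_line", values_to = "fpkm")
  long <- dplyr::left_join(
    long,
    dplyr::select(profiles, "transcript_id", "category", "head_head", "tail_tail"),
    by = "transcript_id"
  )
  dplyr::select(
    dplyr::bind_rows(
      dplyr::mutate(long, category = "all"),
      long,
      dplyr::mutate(dplyr::filter(long, .data$head_head), category = "head_head"),
      dplyr::mutate(dplyr::filter(long, .data$tail_tail), category = "tail_tail")
    ),
    "category", "transcript_id", "cell_line", "fpkm"
  )
}

#' Per-category pool summaries
#'
#' @param pooled Output of [pool_by_category()].
#' @return Tibble `category`, `n` (pooled transcript x cell-line
#'   observations), `mean_fpkm`, `median_fpkm`. Means are on the raw FPKM
#'   scale.
#' @export
category_summary <- function(pooled) {
  dplyr::summarise(
    dplyr::group_by(pooled, .data$category),
    n = dplyr::n(),
    mean_fpkm = mean(.data$fpkm),
    median_fpkm = stats::median(.data$fpkm),
    .groups = "drop"
  )
}

#' Compare two configuration categories with the Wilcoxon rank-sum test
#'
#' Pools are compared with the two-sample Wilcoxon (Mann-Whitney) rank-sum
#' test, with midrank handling of ties: the exact null distribution is
#' enumerated when both pools have at most 25 observations and no ties are
#' present, otherwise the normal approximation with tie and continuity
#' correction is used. Both the two-sided p-value and the one-sided p-value
#' for the alternative "group `a` is stochastically lower than group `b`"
#' are reported (the default directional claim: inverted-configuration
#' transcripts are less expressed).
#'
#' @param pooled Output of [pool_by_category()].
#' @param a,b Category names to compare; `a` is the group hypothesised lower.
#' @return An object of class `alu_ranksum`; see [tidy.alu_ranksum()].
#' @export
compare_categories <- function(pooled, a, b) {
  x <- pooled$fpkm[pooled$category == a]
  y <- pooled$fpkm[pooled$category == b]
  if (length(x) == 0 || length(y) == 0) {
    stop("empty pool for category: ", if (length(x) == 0) a else b)
  }
  rank_sum_test(x, y, group_a = a, group_b = b)
}

# Core rank-sum comparison on two numeric vectors.
rank_sum_test <- function(x, y, group_a = "a", group_b = "b") {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  two <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = exact, correct = !exact)
  one <- stats::wilcox.test(x, y, alternative = "less",
                            exact = exact, correct = !exact)
  structure(
    list(
      group_a = group_a, group_b = group_b,
      n_a = length(x), n_b = length(y),
      statistic = unname(two$statistic),  # Mann-Whitney U for group a
      p_two_sided = two$p.value,
      p_one_sided = one$p.value,
      direction = if (stats::median(x) <= stats::median(y))
        paste(group_a, "lower") else paste(group_b, "lower"),
      exact = exact
    ),
    class = "alu_ranksum"
  )
}

#' @export
print.alu_ranksum <- function(x, ...) {
  cat("Wilcoxon rank-sum comparison: ", x$group_a, " (n=", x$n_a, ") vs ",
      x$group_b, " (n=", x$n_b, ")\n", sep = "")
  cat("  U = ", format(x$statistic), ", p (two-sided) = ",
      format.pval(x$p_two_sided), ", p (one-sided, ", x$group_a, " < ",
      x$group_b, ") = ", format.pval(x$p_one_sided), "\n", sep = "")
  cat("  ", x$direction, "; ",
      if (x$exact) "exact null distribution" else
        "normal approximation with tie/continuity correction", "\n", sep = "")
  invisible(x)
}

#' Tidy a rank-sum comparison
#'
#' @param x An `alu_ranksum` object from [compare_categories()].
#' @param ... Unused.
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `statistic`,
#'   `p_two_sided`, `p_one_sided`, `direction`, `exact`.
#' @export
tidy.alu_ranksum <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b, n_a = x$n_a, n_b = x$n_b,
    statistic = x$statistic, p_two_sided = x$p_two_sided,
    p_one_sided = x$p_one_sided, direction = x$direction, exact = x$exact
  )
}

#' @rdname tidy.alu_ranksum
#' @export
glance.alu_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_two_sided,
                 method = if (x$exact) "Wilcoxon rank-sum (exact)"
                 else "Wilcoxon rank-sum (normal approximation)")
}

#' All pairwise category comparisons
#'
#' Runs [compare_categories()] for every unordered pair of categories present
#' in the pool. Raw Wilcoxon p-values are reported by default; `adjust =
#' "bonferroni"` (or any [stats::p.adjust()] method) adds adjusted columns.
#'
#' @param pooled Output of [pool_by_category()].
#' @param categories Categories to include; default all present.
#' @param adjust Multiple-testing adjustment method (default `"none"`).
#' @return Tibble with one row per pair (tidy [tidy.alu_ranksum()] columns,
#'   plus `p_two_sided_adj` when `adjust != "none"`).
#' @export
compare_all_categories <- function(pooled, categories = NULL, adjust = "none") {
  if (is.null(categories)) categories <- unique(pooled$category)
  prs <- utils::combn(categories, 2, simplify = FALSE)
  out <- purrr::map_dfr(prs, function(p) {
    generics::tidy(compare_categories(pooled, p[1], p[2]))
  })
  if (adjust != "none") {
    out$p_two_sided_adj <- stats::p.adjust(out$p_two_sided, method = adjust)
  }
  out
}
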