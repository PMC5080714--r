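make_repeats <- function(starts, strands, chrom = "chr1", width = 300L,
                         name = "AluSp") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(starts) + width, strand = strands,
                 name = name, family = "Alu")
}

test_that("read_repeats parses both dialects, filters family, sorts", {
  rmsk <- tempfile(fileext = ".tsv")
  writeLines(c(
    "genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
    "chr1\t5000\t5300\t+\tAluSp\tSINE\tAlu",
    "chr1\t100\t400\t-\tMIRb\tSINE\tMIR",
    "chr1\t1000\t1310\t+\tAluY\tSINE\tAlu"
  ), rmsk)
  reps <- read_repeats(rmsk, "rmsk")
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$start, c(1000L, 5000L))  # sorted
  expect_true(all(reps$family == "Alu"))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t700\t1000\tAluSx\t0\t-",
               "chr2\t10\t300\tL1MC\t0\t+",
               "chr2\t400\t650\tAluJb\t0\t+"), bed)
  reps2 <- read_repeats(bed, "bed6")
  expect_equal(reps2$name, c("AluJb", "AluSx"))

  empty <- tempfile()
  writeLines("genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
             empty)
  expect_equal(nrow(read_repeats(empty, "rmsk")), 0L)

  bad <- tempfile()
  writeLines(c("genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
               "chr1\t100\t50\t+\tAluY\tSINE\tAlu"), bad)
  expect_error(read_repeats(bad, "rmsk"), "line 2")
})

test_that("clustering respects the inclusive gap threshold", {
  one <- make_repeats(100, "+")
  cl1 <- cluster_alus(one, 300)
  expect_equal(cl1$cluster_size, 1L)

  # gaps 100 then 400 with max_gap 300: clusters of sizes 2 and 1
  three <- make_repeats(c(0, 400, 1100), c("+", "+", "+"))
  cl3 <- cluster_alus(three, 300)
  expect_equal(sort(cluster_classes(cl3)$size), c(1L, 2L))

  # a gap of exactly 300 joins (inclusive boundary)
  exact <- make_repeats(c(0, 600), c("+", "+"))
  expect_equal(cluster_alus(exact, 300)$cluster_size, c(2L, 2L))
  # one nucleotide more splits
  apart <- make_repeats(c(0, 601), c("+", "+"))
  expect_equal(cluster_alus(apart, 300)$cluster_size, c(1L, 1L))

  # overlapping records merge into one cluster
  expect_message(
    clo <- cluster_alus(make_repeats(c(0, 100), c("+", "-")), 300),
    "overlapping"
  )
  expect_equal(clo$cluster_size, c(2L, 2L))
})

test_that("clustering equals brute-force transitive closure on random inputs", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      n <- sample(10:50, 1)
      feats <- tibble::tibble(
        chrom = sample(c("c1", "c2"), n, replace = TRUE),
        start = sample.int(20000, n),
        strand = sample(c("+", "-"), n, replace = TRUE),
        name = "AluY", family = "Alu"
      )
      feats$end <- feats$start + sample(50:350, n, replace = TRUE)
      feats <- dplyr::arrange(feats, chrom, start)
      gap <- sample(c(0, 100, 300), 1)
      got <- suppressMessages(cluster_alus(feats, gap))
      oracle <- brute_cluster_sizes(got[, c("chrom", "start", "end")], gap)
      # same partition of indices (bijection between cluster labelings)
      expect_true(all(tapply(oracle, got$cluster_id, dplyr::n_distinct) == 1))
      expect_true(all(tapply(got$cluster_id, oracle, dplyr::n_distinct) == 1))
      # partition of elements: cluster sizes sum to n
      expect_equal(sum(cluster_classes(got)$size), n)
    }
  })
})

test_that("pair orientation follows the strand arrangement", {
  expect_equal(classify_pair("+", "+"), "dSINE")
  expect_equal(classify_pair("-", "-"), "dSINE")
  expect_equal(classify_pair("+", "-"), "tiSINE")  # 3' ends face: tail-to-tail
  expect_equal(classify_pair("-", "+"), "hiSINE")  # 5' ends face: head-to-head
})

test_that("catalog summary reports planted configuration fractions", {
  # 10 isolated Alus
  iso <- make_repeats(seq(0, 9) * 10000, rep("+", 10))
  s <- summarize_catalog(cluster_alus(iso, 300))
  expect_equal(s$fraction_single, 1.0)
  expect_equal(s$fraction_in_pairs, 0)

  # planted {dSINE:13, tiSINE:4, hiSINE:3, sSINE:60} -> 100 Alus
  p <- sim_params(planted_counts = c(sSINE = 60L, dSINE = 13L, tiSINE = 4L,
                                     hiSINE = 3L, cluster3plus = 0L))
  sim <- simulate_repeat_annotation(p)
  s2 <- summarize_catalog(cluster_alus(sim$repeats, 300))
  expect_equal(s2$n_alus, 100L)
  expect_equal(s2$fraction_dSINE, 26 / 100)
  expect_equal(s2$fraction_iSINE, 14 / 100)
  expect_equal(s2$fraction_hiSINE, 6 / 100)
  expect_equal(s2$fraction_tiSINE, 8 / 100)
  expect_equal(s2$fraction_in_pairs, s2$fraction_dSINE + s2$fraction_iSINE)
  expect_equal(s2$fraction_single + s2$fraction_clustered, 1)

  # empty input: no crash, undefined fractions
  s0 <- summarize_catalog(cluster_alus(iso[0, ], 300))
  expect_equal(s0$n_alus, 0L)
  expect_true(is.na(s0$fraction_single))
})

test_that("neighbor-gap statistics match hand enumeration", {
  # consecutive gaps 10 and 1000: median 505, nearest gaps (10, 10, 1000)
  reps <- make_repeats(c(0, 310, 1610), c("+", "+", "+"))
  s <- summarize_catalog(cluster_alus(reps, 300))
  expect_equal(s$median_neighbor_gap, 505)
  expect_equal(s$fraction_within_median, 2 / 3)
  # alternative readings exposed behind flags
  s_n <- summarize_catalog(cluster_alus(reps, 300), median_over = "nearest")
  expect_equal(s_n$median_neighbor_gap, 10)
  s_g <- summarize_catalog(cluster_alus(reps, 300), within_counts = "gaps")
  expect_equal(s_g$fraction_within_median, 1 / 2)
})

test_that("strand flip and coordinate mirror each swap hiSINE and tiSINE", {
  p <- sim_params(seed = 7L)
  sim <- simulate_repeat_annotation(p)
  s <- summarize_catalog(cluster_alus(sim$repeats, 300))
  L <- p$chrom_length

  # strand flip alone: pair order kept, every arrow reversed
  flipped <- dplyr::mutate(sim$repeats,
                           strand = ifelse(.data$strand == "+", "-", "+"))
  sf <- summarize_catalog(cluster_alus(flipped, 300))
  expect_equal(sf$fraction_hiSINE, s$fraction_tiSINE)
  expect_equal(sf$fraction_tiSINE, s$fraction_hiSINE)
  expect_equal(sf$fraction_dSINE, s$fraction_dSINE)
  expect_equal(sf$fraction_single, s$fraction_single)

  # coordinate mirror alone: order reverses, strands kept
  mirrored <- dplyr::arrange(
    dplyr::mutate(sim$repeats,
                  new_start = L - .data$end, end = L - .data$start,
                  start = .data$new_start),
    chrom, start
  )[, c("chrom", "start", "end", "strand", "name", "family")]
  sm <- summarize_catalog(cluster_alus(mirrored, 300))
  expect_equal(sm$fraction_hiSINE, s$fraction_tiSINE)
  expect_equal(sm$fraction_tiSINE, s$fraction_hiSINE)
  expect_equal(sm$fraction_dSINE, s$fraction_dSINE)
  expect_equal(sm$median_neighbor_gap, s$median_neighbor_gap)

  # the composition of both is a true reflection: classes are preserved
  both <- dplyr::mutate(mirrored, strand = ifelse(.data$strand == "+", "-", "+"))
  sb <- summarize_catalog(cluster_alus(both, 300))
  expect_equal(sb$fraction_hiSINE, s$fraction_hiSINE)
  expect_equal(sb$fraction_tiSINE, s$fraction_tiSINE)
})

test_that("fraction_clustered is non-decreasing in max_gap", {
  withr::with_seed(11, {
    feats <- make_repeats(cumsum(sample(100:1500, 60, replace = TRUE)),
                          sample(c("+", "-"), 60, replace = TRUE))
    fr <- vapply(c(0, 50, 150, 300, 600, 1200), function(g) {
      summarize_catalog(cluster_alus(feats, g))$fraction_clustered
    }, numeric(1))
    expect_true(all(diff(fr) >= 0))
  })
})

test_that("stratification splits the catalog by genic territory", {
  p <- sim_params()
  ga <- simulate_gene_annotation(p)
  part <- project_partitions(ga$gene_models, ga$chrom_sizes)
  sim <- simulate_repeat_annotation(p, ga$gene_models)
  cl <- cluster_alus(sim$repeats, 300)
  strat <- stratify_by_region(cl, part)
  expect_setequal(strat$region, c("genic", "intergenic"))
  expect_equal(sum(strat$n_alus), nrow(sim$repeats))
  # genic stratum holds exactly the Alus of units planted in utr3/intron
  genic_truth <- sum(sim$truth$size[sim$truth$compartment != "intergenic"])
  expect_equal(strat$n_alus[strat$region == "genic"], genic_truth)

  # all Alus inside genes -> intergenic stratum empty
  p_small <- sim_params(planted_counts = c(sSINE = 20L, dSINE = 5L, tiSINE = 2L,
                                           hiSINE = 2L, cluster3plus = 1L))
  only_genic <- simulate_repeat_annotation(
    p_small, ga$gene_models, placement = c(utr3 = 0.5, intron = 0.5, intergenic = 0))
  st2 <- stratify_by_region(cluster_alus(only_genic$repeats, 300), part)
  expect_equal(st2$n_alus[st2$region == "intergenic"], 0L)
})
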