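# Independent brute-force oracles, kept free of the package's own
# implementation paths.

# Transitive closure of the pairwise gap relation: two features are related
# iff same chromosome and end-to-start gap (either order, overlap counts as
# <= 0) is at most max_gap; clusters are the connected components.
brute_cluster_sizes <- function(features, max_gap) {
  n <- nrow(features)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || features$chrom[i] != features$chrom[j]) next
      gap <- max(features$start[i], features$start[j]) -
        min(features$end[i], features$end[j])
      adj[i, j] <- gap <= max_gap
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Per-nucleotide partition labels (0-based positions) for one chromosome.
brute_partition_labels <- function(gene_models, chrom, size) {
  pos <- seq_len(size) - 1L
  in_any <- function(d) {
    hit <- rep(FALSE, size)
    for (k in seq_len(nrow(d))) {
      if (d$chrom[k] != chrom) next
      hit[(d$start[k] + 1):(d$end[k])] <- TRUE
    }
    hit
  }
  sub <- function(f) gene_models[gene_models$feature == f, , drop = FALSE]
  genic <- in_any(sub("gene"))
  exonic <- in_any(sub("exon")) & genic
  coding <- in_any(sub("cds")) & exonic
  u5 <- in_any(sub("utr5")) & exonic & !coding
  u3 <- in_any(sub("utr3")) & exonic & !coding & !u5
  lvl1 <- ifelse(genic, "genic", "intergenic")
  lvl2 <- ifelse(!genic, NA, ifelse(exonic, "exonic", "intronic"))
  lvl3 <- ifelse(!exonic, NA,
                 ifelse(coding, "coding",
                        ifelse(u5, "utr5", ifelse(u3, "utr3", "noncoding"))))
  data.frame(pos = pos, lvl1 = lvl1, lvl2 = lvl2, lvl3 = lvl3)
}

# Expand a partition map to per-nucleotide labels for one chromosome/level.
expand_partition <- function(partition, chrom, size, level) {
  d <- partition[partition$level == level & partition$chrom == chrom, , drop = FALSE]
  lab <- rep(NA_character_, size)
  for (k in seq_len(nrow(d))) lab[(d$start[k] + 1):(d$end[k])] <- d$label[k]
  lab
}

# Per-base spliced-transcript projection of a genomic position (0-based).
brute_tx_position <- function(exons, tx_strand, gpos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  bases <- unlist(mapply(function(s, e) seq(s, e - 1L), exons$start, exons$end,
                         SIMPLIFY = FALSE))
  if (tx_strand == "-") bases <- rev(bases)
  match(gpos, bases) - 1L
}

# All secondary structures (pair lists) with canonical+wobble pairs and a
# minimum hairpin loop of `theta` unpaired nucleotides.
enumerate_structures <- function(seq_chr, theta = 3L) {
  s <- strsplit(gsub("T", "U", toupper(seq_chr)), "")[[1]]
  can_pair <- function(i, j) {
    paste0(s[i], s[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG") && j - i > theta
  }
  rec <- function(i, j) {
    if (j <= i) return(list(matrix(integer(0), ncol = 2)))
    out <- lapply(rec(i, j - 1L), identity)  # j unpaired
    for (k in i:(j - 1L)) {
      if (!can_pair(k, j)) next
      left <- rec(i, k - 1L)
      inner <- rec(k + 1L, j - 1L)
      for (L in left) for (I in inner) {
        out[[length(out) + 1L]] <- rbind(L, I, c(k, j))
      }
    }
    out
  }
  rec(1L, length(s))
}

# Ensemble quantities from exhaustive enumeration (energy -1/pair, RT = 1).
enumerate_ensemble <- function(seq_chr, theta = 3L) {
  structs <- enumerate_structures(seq_chr, theta)
  n <- nchar(seq_chr)
  npairs <- vapply(structs, nrow, integer(1))
  w <- exp(npairs)
  Z <- sum(w)
  bpp <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    st <- structs[[k]]
    for (r in seq_len(nrow(st))) {
      bpp[st[r, 1], st[r, 2]] <- bpp[st[r, 1], st[r, 2]] + w[k]
    }
  }
  bpp <- bpp / Z
  list(mfe = -max(npairs), efe = -log(Z), bpp = bpp + t(bpp), n_structures = length(structs))
}

# Exact one-sided rank-sum p-value by enumerating all rank assignments:
# P(rank sum of group x <= observed) under the null.
enumerate_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_along(x)])
  combs <- utils::combn(n, length(x))
  mean(colSums(matrix(seq_len(n)[combs], nrow = length(x))) <= obs)
}

# A small toy design template: a designable hairpin stem between A/U spacers.
toy_template <- function() {
  design_template(
    "AAACAGGGGGAAAACCCCCAAUAA",
    tibble::tibble(kind = c("spacer", "designable", "spacer"),
                   start = c(1L, 6L, 20L), end = c(5L, 19L, 24L))
  )
}
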