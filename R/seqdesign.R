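# Secondary-structure thermodynamics and inverse design of artificial UTR
# analogs: replace designated segments (the Alu elements of a template UTR)
# with random sequence and optimize it until the fold matches the template's
# minimum-free-energy (MFE) structure, MFE and ensemble free energy (EFE),
# while spacer segments stay byte-identical and the new sequence stays
# divergent from the replaced original.
#
# Two folding engines satisfy the same contract. "nussinov" is a base-pair
# maximization model (canonical + GU wobble pairs, minimum hairpin loop 3,
# energy -1 per pair, ensemble quantities from the exact partition function
# with RT = 1), fully self-contained and oracle-checkable by exhaustive
# enumeration at short lengths. "vienna" shells out to RNAfold for
# Turner-model thermodynamics when ViennaRNA is on the PATH.

rna_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

check_rna <- function(sequence) {
  sequence <- toupper(gsub("T", "U", toupper(sequence)))
  s <- strsplit(sequence, "")[[1]]
  if (length(s) < 1 || !all(s %in% c("A", "C", "G", "U"))) {
    stop("sequence must be non-empty over the alphabet {A,C,G,U}")
  }
  s
}

# Pairability matrix with the minimum-hairpin constraint j - i > theta.
pair_matrix <- function(s, theta = 3L) {
  n <- length(s)
  P <- outer(s, s, FUN = function(a, b) rna_pairable(a, b))
  d <- outer(seq_len(n), seq_len(n), FUN = function(i, j) j - i)
  P & (d > theta)
}

# Nussinov maximum-pairing DP with deterministic traceback.
# Returns list(pairs = 2-column matrix, n_pairs).
nussinov_mfe <- function(s, theta = 3L) {
  n <- length(s)
  P <- pair_matrix(s, theta)
  M <- matrix(0L, n, n)
  if (n > theta + 1) {
    for (span in (theta + 1):(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]
        ks <- which(P[i:j, j][seq_len(span)])  # k in [i, j-1] pairing with j
        if (length(ks) > 0) {
          ks <- ks + i - 1L
          left <- ifelse(ks > i, M[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
          left[ks == i] <- 0L
          inner <- M[cbind(ks + 1L, j - 1L)]
          inner[ks + 1L > j - 1L] <- 0L
          best <- max(best, max(left + inner + 1L))
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || M[i, j] == 0L) next
      if (M[i, j] == M[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
        next
      }
      for (k in i:(j - 1L)) {
        if (!P[k, j]) next
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (left + inner + 1L == M[i, j]) {
          pairs <- rbind(pairs, c(k, j))
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          break
        }
      }
    }
  }
  list(pairs = pairs, n_pairs = if (n >= 2) M[1, n] else 0L)
}

pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

dotbracket_to_pairs <- function(db) {
  s <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(s)) {
    if (s[i] == "(") stack <- c(stack, i)
    else if (s[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      out <- rbind(out, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  out
}

# Inside partition function over subsequences; weight w = exp(1/RT) per pair
# (energy -1 per pair, RT = 1). Z[i, j] covers s[i..j]; empty = 1.
partition_inside <- function(P, n, w = exp(1)) {
  # Z[i, j + 1] layout: column j stays 1 for the empty subsequence j < i.
  Z <- matrix(1, n + 1L, n + 1L)
  for (span in seq_len(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      ks <- which(P[i:(j - 1L), j]) + i - 1L
      val <- Z[i, j]  # j unpaired
      if (length(ks) > 0) {
        val <- val + w * sum(Z[i, ks] * Z[cbind(ks + 1L, j)])
      }
      Z[i, j + 1L] <- val
    }
  }
  Z
}

# Base-pair probabilities by the inside-outside decomposition: a pair (i,j)
# is either at the exterior level or sits directly beneath its innermost
# enclosing pair (h,l); processing spans largest-first makes O(h,l) available.
partition_bpp <- function(P, Zin, n, w = exp(1)) {
  get <- function(i, j) if (j < i) 1 else Zin[i, j + 1L]
  Ztot <- get(1L, n)
  O <- matrix(0, n, n)
  bpp <- matrix(0, n, n)
  idx <- which(P, arr.ind = TRUE)
  if (nrow(idx) == 0) return(bpp)
  idx <- idx[order(idx[, 2] - idx[, 1], decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    o <- get(1L, i - 1L) * get(j + 1L, n)
    if (i > 1 && j < n) {
      for (h in seq_len(i - 1L)) {
        ls <- which(P[h, ])
        ls <- ls[ls > j]
        for (l in ls) {
          o <- o + w * O[h, l] * get(h + 1L, i - 1L) * get(j + 1L, l - 1L)
        }
      }
    }
    O[i, j] <- o
    bpp[i, j] <- w * get(i + 1L, j - 1L) * o / Ztot
  }
  bpp  # upper triangular; symmetrized by the caller
}

#' Fold an RNA sequence
#'
#' Predicts the minimum-free-energy secondary structure and ensemble
#' thermodynamics of a sequence under a pluggable engine. The default
#' `"nussinov"` engine is a base-pair maximization model: canonical
#' Watson-Crick plus GU wobble pairs, minimum hairpin loop of 3 unpaired
#' nucleotides, energy -1 (arbitrary kcal/mol-like units) per pair, with the
#' ensemble free energy `-RT log Z` (RT = 1) and base-pair probabilities
#' from the exact partition function. The `"vienna"` engine delegates to the
#' `RNAfold` executable (Turner nearest-neighbour model) when available.
#'
#' @param sequence RNA string over `{A,C,G,U}` (T is accepted as U).
#' @param engine `"nussinov"` (default) or `"vienna"`.
#' @param with_bpp Compute the base-pair probability matrix (default `TRUE`;
#'   the matrix is the costly part and can be skipped during optimization).
#' @return An object of class `fold_result`: list with `sequence`,
#'   `mfe_structure` (dot-bracket), `mfe`, `efe` (both kcal/mol;
#'   `efe <= mfe`), and `bpp` (symmetric n x n matrix, or `NULL`).
#' @export
fold <- function(sequence, engine = c("nussinov", "vienna"), with_bpp = TRUE) {
  engine <- match.arg(engine)
  s <- check_rna(sequence)
  if (engine == "vienna") return(fold_vienna(paste(s, collapse = ""), with_bpp))
  n <- length(s)
  P <- pair_matrix(s)
  mfe_res <- nussinov_mfe(s)
  Zin <- partition_inside(P, n)
  Z <- if (n >= 1) Zin[1L, n + 1L] else 1
  bpp <- NULL
  if (with_bpp) {
    bpp <- partition_bpp(P, Zin, n)
    bpp <- bpp + t(bpp)
  }
  structure(
    list(
      sequence = paste(s, collapse = ""),
      mfe_structure = pairs_to_dotbracket(mfe_res$pairs, n),
      mfe = -as.numeric(mfe_res$n_pairs),
      efe = -log(Z),
      bpp = bpp,
      engine = "nussinov"
    ),
    class = "fold_result"
  )
}

fold_vienna <- function(sequence, with_bpp = TRUE) {
  if (Sys.which("RNAfold") == "") stop("RNAfold executable not found on PATH")
  dir <- tempfile("rnafold")
  dir.create(dir)
  old <- setwd(dir)
  on.exit({ setwd(old); unlink(dir, recursive = TRUE) }, add = TRUE)
  out <- system2("RNAfold", args = c("-p", "--noPS"), input = sequence,
                 stdout = TRUE, stderr = FALSE)
  mfe_line <- out[2]
  m <- regmatches(mfe_line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", mfe_line))[[1]]
  efe_line <- out[3]
  e <- regmatches(efe_line, regexec("\\[\\s*(-?[0-9.]+)\\]", efe_line))[[1]]
  if (length(m) < 3 || length(e) < 2) stop("could not parse RNAfold output")
  n <- nchar(sequence)
  bpp <- NULL
  if (with_bpp) {
    dp <- list.files(".", pattern = "dp\\.ps$|^dot\\.ps$")
    bpp <- matrix(0, n, n)
    if (length(dp) > 0) {
      lines <- readLines(dp[1])
      ub <- grep("ubox$", lines, value = TRUE)
      ub <- ub[grepl("^[0-9]", ub)]
      for (l in ub) {
        f <- strsplit(trimws(l), "\\s+")[[1]]
        i <- as.integer(f[1]); j <- as.integer(f[2]); p <- as.numeric(f[3])^2
        bpp[i, j] <- p; bpp[j, i] <- p
      }
    }
  }
  structure(
    list(sequence = sequence, mfe_structure = m[2], mfe = as.numeric(m[3]),
         efe = as.numeric(e[2]), bpp = bpp, engine = "vienna"),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("RNA fold (", x$engine, " engine), length ", nchar(x$sequence), "\n",
      x$sequence, "\n", x$mfe_structure, "\n",
      "MFE = ", format(x$mfe), " kcal/mol; EFE = ", round(x$efe, 3),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Distance between two base-pair probability matrices
#'
#' Frobenius norm of the difference restricted to the upper triangle,
#' normalized by the sequence length.
#'
#' @param p,q Symmetric base-pair probability matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
bpp_distance <- function(p, q) {
  if (!all(dim(p) == dim(q))) stop("base-pair probability matrices differ in dimension")
  ut <- upper.tri(p)
  sqrt(sum((p[ut] - q[ut])^2)) / nrow(p)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment under unit scoring (match +1,
#' mismatch -1, gap -1 per column); identity is the number of matched
#' columns divided by the alignment length.
#'
#' @param a,b Non-empty nucleotide strings (U and T are equivalent).
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  a <- gsub("U", "T", toupper(a)); b <- gsub("U", "T", toupper(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Build a design template
#'
#' @param sequence Template RNA sequence (the reference UTR).
#' @param segments Tibble with columns `kind` (`"spacer"` or `"designable"`),
#'   `start`, `end` (1-based inclusive positions in `sequence`); segments
#'   must tile the sequence without gaps or overlap and include at least one
#'   designable segment (a template made only of spacers is allowed and
#'   returns the original sequence from [design_analog()]).
#' @return A `design_template` list.
#' @export
design_template <- function(sequence, segments) {
  s <- check_rna(sequence)
  segments <- dplyr::arrange(tibble::as_tibble(segments), .data$start)
  stopifnot(all(segments$kind %in% c("spacer", "designable")))
  if (nrow(segments) == 0 || segments$start[1] != 1 ||
      segments$end[nrow(segments)] != length(s) ||
      (nrow(segments) > 1 && any(segments$start[-1] != segments$end[-nrow(segments)] + 1))) {
    stop("segments must tile the sequence exactly (1-based inclusive, no gaps/overlap)")
  }
  structure(list(sequence = paste(s, collapse = ""), segments = segments),
            class = "design_template")
}

designable_positions <- function(template) {
  seg <- dplyr::filter(template$segments, .data$kind == "designable")
  unlist(purrr::map2(seg$start, seg$end, seq), use.names = FALSE)
}

# Identity of the candidate fill to the replaced original, max over segments.
fill_identity <- function(template, candidate_seq) {
  seg <- dplyr::filter(template$segments, .data$kind == "designable")
  if (nrow(seg) == 0) return(NA_real_)
  max(purrr::map2_dbl(seg$start, seg$end, function(s, e) {
    sequence_identity(substr(template$sequence, s, e), substr(candidate_seq, s, e))
  }))
}

structure_bp_distance <- function(db_a, db_b) {
  pa <- dotbracket_to_pairs(db_a)
  pb <- dotbracket_to_pairs(db_b)
  ka <- paste(pa[, 1], pa[, 2])
  kb <- paste(pb[, 1], pb[, 2])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Design sequence-divergent structural analogs of a template
#'
#' Replaces the designable segments of a template (e.g. the Alu elements of
#' a UTR) with random sequence and optimizes them by seeded stochastic
#' hill-climbing with restart on plateau: each step mutates one random
#' designable nucleotide and keeps the mutation iff it does not worsen the
#' objective, which minimizes first the base-pair distance between the
#' current MFE structure and the template's MFE structure and then the
#' MFE/EFE mismatch. Spacer segments are never mutated. A state is accepted
#' as a candidate when its MFE structure equals the target exactly, its MFE
#' and EFE are within the tolerances, and its fill is at most
#' `max_identity_to_original` identical to the replaced original segments.
#' Accepted candidates are ranked by
#' `gc_weight * gc_diff + bpp_weight * bpp_distance` (ascending).
#'
#' @param template A [design_template()].
#' @param mfe_tolerance,efe_tolerance Maximum allowed deviation from the
#'   template's MFE and EFE, kcal/mol (defaults 0.5).
#' @param gc_weight,bpp_weight Ranking weights (defaults 1, 1).
#' @param max_identity_to_original Maximum alignment identity of a designable
#'   fill to the original segment it replaces (default 0.6).
#' @param max_steps Total mutation steps across restarts (default 2000).
#' @param plateau Steps without strict improvement before a random restart
#'   (default 200).
#' @param seed Integer seed; same seed, same candidate list.
#' @param engine Folding engine passed to [fold()].
#' @return A tibble of accepted candidates (possibly zero rows, with a
#'   diagnostic message): `sequence`, `mfe_structure`, `mfe`, `efe`,
#'   `gc_diff`, `bpp_distance`, `identity_to_original`, `score`, `accepted`.
#'   The template fold is attached as attribute `target`.
#' @export
design_analog <- function(template, mfe_tolerance = 0.5, efe_tolerance = 0.5,
                          gc_weight = 1, bpp_weight = 1,
                          max_identity_to_original = 0.6,
                          max_steps = 2000, plateau = 200, seed = 1,
                          engine = "nussinov") {
  if (mfe_tolerance < 0 || efe_tolerance < 0) stop("tolerances must be non-negative")
  stopifnot(max_identity_to_original > 0, max_identity_to_original <= 1)
  target <- fold(template$sequence, engine = engine, with_bpp = TRUE)
  pos <- designable_positions(template)
  if (length(pos) == 0) {
    out <- tibble::tibble(
      sequence = template$sequence, mfe_structure = target$mfe_structure,
      mfe = target$mfe, efe = target$efe, gc_diff = 0, bpp_distance = 0,
      identity_to_original = NA_real_, score = 0, accepted = TRUE
    )
    attr(out, "target") <- target
    return(out)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  nts <- c("A", "C", "G", "U")
  base <- strsplit(template$sequence, "")[[1]]
  gc_target <- mean(base %in% c("G", "C"))

  random_fill <- function() {
    cur <- base
    cur[pos] <- sample(nts, length(pos), replace = TRUE)
    cur
  }
  objective <- function(f) {
    c(structure_bp_distance(f$mfe_structure, target$mfe_structure),
      abs(f$mfe - target$mfe) + abs(f$efe - target$efe))
  }
  better_or_equal <- function(o1, o2) {
    o1[1] < o2[1] || (o1[1] == o2[1] && o1[2] <= o2[2])
  }
  strictly_better <- function(o1, o2) {
    o1[1] < o2[1] || (o1[1] == o2[1] && o1[2] < o2[2])
  }

  seen <- character(0)
  cands <- list()
  cur <- random_fill()
  cur_fold <- fold(paste(cur, collapse = ""), engine = engine, with_bpp = FALSE)
  cur_obj <- objective(cur_fold)
  since_improve <- 0L

  consider <- function(f, seq_chr) {
    if (seq_chr %in% seen) return(invisible(NULL))
    if (f$mfe_structure != target$mfe_structure) return(invisible(NULL))
    if (abs(f$mfe - target$mfe) > mfe_tolerance) return(invisible(NULL))
    if (abs(f$efe - target$efe) > efe_tolerance) return(invisible(NULL))
    ident <- fill_identity(template, seq_chr)
    if (!is.na(ident) && ident > max_identity_to_original) return(invisible(NULL))
    seen <<- c(seen, seq_chr)
    gc_diff <- abs(mean(strsplit(seq_chr, "")[[1]] %in% c("G", "C")) - gc_target)
    full <- fold(seq_chr, engine = engine, with_bpp = TRUE)
    cands[[length(cands) + 1L]] <<- tibble::tibble(
      sequence = seq_chr, mfe_structure = full$mfe_structure,
      mfe = full$mfe, efe = full$efe, gc_diff = gc_diff,
      bpp_distance = bpp_distance(full$bpp, target$bpp),
      identity_to_original = ident,
      accepted = TRUE
    )
    invisible(NULL)
  }
  consider(cur_fold, paste(cur, collapse = ""))

  for (step in seq_len(max_steps)) {
    prop <- cur
    p <- if (length(pos) == 1) pos else sample(pos, 1)
    prop[p] <- sample(setdiff(nts, prop[p]), 1)
    prop_chr <- paste(prop, collapse = "")
    prop_fold <- fold(prop_chr, engine = engine, with_bpp = FALSE)
    prop_obj <- objective(prop_fold)
    if (better_or_equal(prop_obj, cur_obj)) {
      if (strictly_better(prop_obj, cur_obj)) since_improve <- 0L
      else since_improve <- since_improve + 1L
      cur <- prop; cur_fold <- prop_fold; cur_obj <- prop_obj
      consider(cur_fold, prop_chr)
    } else {
      since_improve <- since_improve + 1L
    }
    if (since_improve >= plateau) {
      cur <- random_fill()
      cur_fold <- fold(paste(cur, collapse = ""), engine = engine, with_bpp = FALSE)
      cur_obj <- objective(cur_fold)
      since_improve <- 0L
      consider(cur_fold, paste(cur, collapse = ""))
    }
  }

  if (length(cands) == 0) {
    message("design_analog: no candidate met the acceptance criteria within ",
            max_steps, " steps")
    out <- tibble::tibble(
      sequence = character(), mfe_structure = character(), mfe = numeric(),
      efe = numeric(), gc_diff = numeric(), bpp_distance = numeric(),
      identity_to_original = numeric(), score = numeric(), accepted = logical()
    )
  } else {
    out <- dplyr::bind_rows(cands)
    out$score <- gc_weight * out$gc_diff + bpp_weight * out$bpp_distance
    out <- dplyr::arrange(out, .data$score)
    out <- out[, c("sequence", "mfe_structure", "mfe", "efe", "gc_diff",
                   "bpp_distance", "identity_to_original", "score", "accepted")]
  }
  attr(out, "target") <- target
  out
}
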