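# PWM scanning of promoter windows and z-test over-representation of CRE
# sites in gene sets and along ranked-transcriptome bins.
#
# Scoring: per-column frequencies are (count + pseudocount) normalized, the
# log-odds against the background are summed over a window, and the window
# score is min-max normalized to [0,1] over the matrix's achievable range.
# The per-promoter statistic is the BEST window score over both strands.

#' Construct a position weight matrix
#'
#' @param counts 4 x width numeric matrix of non-negative counts (or
#'   frequencies), rows A, C, G, T.
#' @param background Base composition of the null model; must sum to 1.
#' @param pseudocount_frac Pseudocount per cell as a fraction of the column
#'   total (default 0.01), guarding against zero counts.
#' @return A `PWM`: list with counts, width, background, pseudocount, the
#'   log-odds matrix `lo` and per-column achievable min/max.
#' @export
pwm_matrix <- function(counts, background = rep(0.25, 4),
                       pseudocount_frac = 0.01) {
  assert_that(is.matrix(counts) && nrow(counts) == 4,
              "counts must be a 4-row matrix (A,C,G,T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  assert_that(setequal(rownames(counts), c("A", "C", "G", "T")),
              "PWM rows must be A, C, G, T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  assert_that(ncol(counts) >= 4, "PWM width must be >= 4")
  assert_that(all(is.finite(counts)) && all(counts >= 0),
              "PWM counts must be finite and non-negative")
  assert_that(all(colSums(counts) > 0), "PWM has an all-zero column")
  assert_that(length(background) == 4 && all(background > 0) &&
                abs(sum(background) - 1) < 1e-8,
              "background must be 4 positive probabilities summing to 1")
  assert_that(pseudocount_frac > 0, "pseudocount must be positive")
  pc <- pseudocount_frac * colSums(counts)
  freq <- sweep(counts, 2, pc, "+")
  freq <- sweep(freq, 2, colSums(freq), "/")
  lo <- log2(freq / background)
  structure(list(counts = counts, width = ncol(counts),
                 background = background,
                 pseudocount = pc,
                 lo = lo,
                 col_min = apply(lo, 2, min),
                 col_max = apply(lo, 2, max)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  consensus <- paste(rownames(x$lo)[apply(x$lo, 2, which.max)], collapse = "")
  cat(sprintf("PWM: width %d, consensus %s\n", x$width, consensus))
  invisible(x)
}

# Map A,C,G,T to 1..4; anything else (N) to 5, which hits a zero log-odds
# row: ambiguous bases neither reward nor penalize a window.
encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  codes
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

# Raw log-odds of every window start for an encoded sequence; vectorized
# over starts, loop only over the (small) motif width.
window_scores <- function(lo_aug, codes, width) {
  n <- length(codes) - width + 1L
  sc <- numeric(n)
  for (j in seq_len(width)) sc <- sc + lo_aug[codes[seq_len(n) + j - 1L], j]
  unname(sc)
}

#' Best PWM site score of one sequence
#'
#' Scores every window on both strands and returns the maximum, min-max
#' normalized to `[0, 1]` over the matrix's achievable score range.
#' Positions are 1-based window starts in forward-strand coordinates; on a
#' tie the forward strand and the leftmost window win.
#'
#' @param pwm A [pwm_matrix()].
#' @param seq Nucleotide sequence (alphabet ACGTN), at least `width` long.
#' @return List with `score` in \[0,1\], `position`, `strand` (`"+"`/`"-"`).
#' @export
best_site_score <- function(pwm, seq) {
  codes <- if (is.character(seq)) encode_seq(seq) else seq
  w <- pwm$width
  if (length(codes) < w)
    stopf("sequence length %d shorter than PWM width %d", length(codes), w)
  lo_aug <- rbind(pwm$lo, 0)
  fwd <- window_scores(lo_aug, codes, w)
  rev <- window_scores(lo_aug, revcomp_codes(codes), w)
  rng <- sum(pwm$col_max) - sum(pwm$col_min)
  norm <- function(x) (x - sum(pwm$col_min)) / rng
  bf <- which.max(fwd); br <- which.max(rev)
  if (fwd[bf] >= rev[br]) {
    list(score = norm(fwd[bf]), position = bf, strand = "+")
  } else {
    # start index on the reverse complement maps back to forward coords
    list(score = norm(rev[br]),
         position = length(codes) - w - br + 2L, strand = "-")
  }
}

#' Score all promoters against a PWM
#'
#' @param pwm A [pwm_matrix()].
#' @param seqs Named character vector of promoter sequences (names are gene
#'   symbols), e.g. from [read_promoters()].
#' @return A `PromoterScoreTable` data frame: gene, best_score,
#'   best_position, best_strand.
#' @export
score_promoters <- function(pwm, seqs) {
  assert_that(length(seqs) > 0 && !is.null(names(seqs)),
              "seqs must be a named character vector")
  res <- lapply(seqs, function(s) best_site_score(pwm, s))
  out <- data.frame(gene = names(seqs),
                    best_score = vapply(res, `[[`, numeric(1), "score"),
                    best_position = vapply(res, `[[`, integer(1), "position"),
                    best_strand = vapply(res, `[[`, character(1), "strand"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("PromoterScoreTable", class(out))
  out
}

#' z-test for motif-score over-representation of a gene set
#'
#' One-sample z of the set's mean best-site score against the score
#' universe, treated as the population (as promoter-scanning tools do):
#' `z = (mean_set - mean_bg) / (sd_bg / sqrt(n_set))`, upper-tail normal p.
#'
#' @param set_scores Scores of the gene set (length >= 2).
#' @param bg_scores Scores of the universe.
#' @return List with `z` and one-sided `p`.
#' @export
zscore_overrepresentation <- function(set_scores, bg_scores) {
  assert_that(length(set_scores) >= 2, "set must have >= 2 scores")
  sd_bg <- stats::sd(bg_scores)
  if (!is.finite(sd_bg) || sd_bg == 0)
    stopf("degenerate universe: zero score variance")
  z <- (mean(set_scores) - mean(bg_scores)) / (sd_bg / sqrt(length(set_scores)))
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Motif over-representation along ranked-transcriptome bins
#'
#' Applies [zscore_overrepresentation()] to each bin of a ranked profile
#' against the whole score universe, reproducing the binned CRE-occurrence
#' profile. Bins with fewer than two scored genes are skipped with a
#' warning (NA row).
#'
#' @param profile A `BinProfile` from [bin_profile()].
#' @param scores A `PromoterScoreTable`.
#' @return The profile with columns `z` and `p` appended.
#' @export
binned_motif_profile <- function(profile, scores) {
  bg <- scores$best_score
  genes <- attr(profile, "bin_genes")
  assert_that(!is.null(genes), "profile lacks bin gene lists")
  out <- as.data.frame(profile)
  out$z <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- scores$best_score[scores$gene %in% genes[[i]]]
    if (length(s) < 2) {
      warnf("bin %d has fewer than 2 scored genes; skipped", out$bin[i])
      next
    }
    zt <- zscore_overrepresentation(s, bg)
    out$z[i] <- zt$z; out$p[i] <- zt$p
  }
  attr(out, "bin_genes") <- genes
  out
}

#' Motif over-representation of named gene partitions
#'
#' One z-test per named partition (e.g. all / Q1-TRAP / rest / up / down)
#' against the whole score universe.
#'
#' @param scores A `PromoterScoreTable`.
#' @param partitions Named list of gene symbol vectors.
#' @return Data frame: partition, n, z, p.
#' @export
compare_partitions <- function(scores, partitions) {
  assert_that(is.list(partitions) && !is.null(names(partitions)),
              "partitions must be a named list")
  bg <- scores$best_score
  rows <- lapply(names(partitions), function(nm) {
    s <- scores$best_score[scores$gene %in% partitions[[nm]]]
    if (length(s) < 2)
      return(data.frame(partition = nm, n = length(s), z = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    zt <- zscore_overrepresentation(s, bg)
    data.frame(partition = nm, n = length(s), z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Slice promoter windows out of genome sequences
#'
#' Helper for extracting promoter FASTA from larger sequences using 0-based
#' half-open coordinates; minus-strand genes are reverse-complemented so
#' every returned promoter reads 5' to 3' toward the gene.
#'
#' @param genome Named character vector of reference sequences.
#' @param coords Data frame with columns chrom, start, end, gene, strand.
#' @return Named character vector of promoter sequences keyed by gene.
#' @export
slice_promoters <- function(genome, coords) {
  needed <- c("chrom", "start", "end", "gene", "strand")
  assert_that(all(needed %in% names(coords)),
              "coords needs columns %s", paste(needed, collapse = ", "))
  out <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    chrom <- coords$chrom[i]
    if (!chrom %in% names(genome)) stopf("unknown sequence '%s'", chrom)
    s <- coords$start[i]; e <- coords$end[i]
    if (s < 0 || e > nchar(genome[[chrom]]) || s >= e)
      stopf("coordinates out of range for gene '%s'", coords$gene[i])
    frag <- substr(genome[[chrom]], s + 1, e)
    if (coords$strand[i] == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    out[i] <- frag
  }
  stats::setNames(out, coords$gene)
}
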