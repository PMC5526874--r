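# Pre-ranked GSEA: weighted Kolmogorov-Smirnov-like enrichment score,
# gene-set-permutation null, sign-matched NES and nominal p-value.

#' Build a ranked list
#'
#' Orders genes by descending signed score; ties are broken by gene symbol
#' so the ranking is deterministic.
#'
#' @param genes Character vector of unique gene symbols.
#' @param scores Finite signed scores (e.g. log fold changes).
#' @return A `RankedList` data frame with columns gene, score.
#' @export
ranked_list <- function(genes, scores) {
  assert_that(length(genes) == length(scores) && length(genes) >= 2,
              "need >= 2 genes with matching scores")
  assert_that(!anyDuplicated(genes), "duplicate genes in ranked list")
  assert_that(all(is.finite(scores)), "scores must be finite")
  ord <- order(-scores, genes)
  out <- data.frame(gene = genes[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", class(out))
  out
}

#' Weighted enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list accumulating `|score|^w / sum_hits |score|^w` at
#' set hits and `-1/(N - N_hits)` at misses; the enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed). When
#' the maximal positive and negative deviations tie (within 1e-12), the
#' positive one is taken, so the result does not depend on accumulation
#' order or extended-precision rounding.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector; must intersect the ranked genes and
#'   must not cover them entirely.
#' @param exponent Weighting exponent `w` (1 = weighted, 0 = classic).
#' @return List with `es`, the `running` sum vector and `peak_rank`.
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  hit <- ranked$gene %in% gene_set
  nh <- sum(hit)
  n <- nrow(ranked)
  if (nh == 0) stopf("gene set has no members in the ranked list")
  if (nh == n) stopf("gene set covers the entire ranked list")
  w <- abs(ranked$score)^exponent
  denom_hit <- sum(w[hit])
  if (denom_hit == 0)
    stopf("all hit scores are zero at exponent %g; ES undefined", exponent)
  inc <- ifelse(hit, w / denom_hit, -1 / (n - nh))
  running <- cumsum(inc)
  pos <- max(running); neg <- min(running)
  peak <- if (pos >= -neg - 1e-12) which.max(running) else which.min(running)
  list(es = running[peak], running = running, peak_rank = peak)
}

#' Null enrichment scores by gene-set permutation
#'
#' Draws `n_perm` random gene sets of the given size (without replacement
#' from the ranked genes) and computes the enrichment score of each — the
#' pre-ranked GSEA null.
#'
#' @param ranked A [ranked_list()].
#' @param set_size Size of each random set.
#' @param n_perm Number of permutations.
#' @param seed Mandatory seed.
#' @param exponent Weighting exponent.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm, seed, exponent = 1) {
  seed <- require_seed(seed)
  assert_that(is_count(set_size, 1L) && set_size < nrow(ranked),
              "set_size must be in 1..(N-1)")
  assert_that(is_count(n_perm, 1L), "n_perm must be a positive integer")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    rs <- sample(ranked$gene, set_size)
    enrichment_score(ranked, rs, exponent)$es
  }, numeric(1))
}

#' Normalized enrichment score and nominal p-value
#'
#' NES is the observed score divided by the mean absolute null score of the
#' same sign; the nominal p uses the add-one rule over same-sign null
#' values, so it is never zero.
#'
#' @param es Observed enrichment score.
#' @param null_es Null sample from [permutation_null()].
#' @return List with `nes`, `nom_p`, and `n_same_sign`.
#' @export
nes_and_pvalue <- function(es, null_es) {
  same <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (!length(same))
    stopf("no same-sign null scores; raise n_perm to estimate NES")
  nes <- es / mean(abs(same))
  nom_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, nom_p = nom_p, n_same_sign = length(same))
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Runs [enrichment_score()], [permutation_null()] and [nes_and_pvalue()]
#' for every set; set members absent from the ranked list are dropped and
#' counted. Null samples are cached per effective set size.
#'
#' @param ranked A [ranked_list()].
#' @param gsc A [gene_set_collection()].
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param seed Mandatory seed.
#' @param exponent Weighting exponent (default 1).
#' @return A `GseaResult` data frame: set, size, n_dropped, es, nes, nom_p,
#'   n_perm, peak_rank, leading_edge (semicolon-joined).
#' @export
gsea_preranked <- function(ranked, gsc, n_perm = 1000, seed, exponent = 1) {
  seed <- require_seed(seed)
  null_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_along(gsc$sets), function(i) {
    nm <- names(gsc$sets)[i]
    members <- intersect(gsc$sets[[i]], ranked$gene)
    dropped <- length(gsc$sets[[i]]) - length(members)
    if (dropped) log_msg("gsea: set '%s' dropped %d absent gene(s)",
                         nm, dropped)
    if (!length(members) || length(members) >= nrow(ranked)) {
      warnf("set '%s' not testable (size %d of %d); skipped", nm,
            length(members), nrow(ranked))
      return(NULL)
    }
    esr <- enrichment_score(ranked, members, exponent)
    key <- as.character(length(members))
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- permutation_null(
        ranked, length(members), n_perm,
        seed = derive_seed(seed, length(members)), exponent = exponent)
    np <- nes_and_pvalue(esr$es, null_cache[[key]])
    le <- if (esr$es >= 0) {
      intersect(ranked$gene[seq_len(esr$peak_rank)], members)
    } else {
      intersect(ranked$gene[esr$peak_rank:nrow(ranked)], members)
    }
    data.frame(set = nm, size = length(members), n_dropped = dropped,
               es = esr$es, nes = np$nes, nom_p = np$nom_p,
               n_perm = n_perm, peak_rank = esr$peak_rank,
               leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), size = integer(0),
                      n_dropped = integer(0), es = numeric(0),
                      nes = numeric(0), nom_p = numeric(0),
                      n_perm = integer(0), peak_rank = integer(0),
                      leading_edge = character(0), stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("GseaResult", class(out))
  out
}
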