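# TRAP quartile construction, DEG filtration, ranked-transcriptome binning
# and symbol mapping.

#' Genes in a TRAP quartile
#'
#' The first quartile (Q1) is the top `ceil(G/4)` genes by descending
#' abundance, the adult-relevance filter applied to DEG lists. Ties on
#' abundance were already broken by gene symbol when the list was built, so
#' the result does not depend on input row order.
#'
#' @param trap A [trap_list()].
#' @param quartile Which quartile, 1 (highest abundance) to 4.
#' @return Character vector of gene symbols.
#' @export
build_q1 <- function(trap, quartile = 1) {
  assert_that(inherits(trap, "TrapList"), "trap must be a TrapList")
  assert_that(is_count(quartile, 1L) && quartile <= 4,
              "quartile must be 1..4")
  g <- nrow(trap)
  size <- ceiling(g / 4)
  lo <- (quartile - 1) * size + 1
  hi <- min(quartile * size, g)
  if (lo > g) return(character(0))
  trap$gene[lo:hi]
}

#' Average several TRAP profiles into one
#'
#' Per gene, the arithmetic mean of its abundance over the lists that
#' contain it (genes absent from a list contribute no term). Used to
#' collapse multiple neuronal subtype profiles into a single cortical
#' neuron profile.
#'
#' @param traps List of at least two [trap_list()] objects.
#' @return A [trap_list()] over the union of genes.
#' @export
average_trap_profiles <- function(traps) {
  assert_that(is.list(traps) && length(traps) >= 2,
              "need at least 2 TRAP lists to average")
  lapply(traps, function(t)
    assert_that(inherits(t, "TrapList"), "all elements must be TrapList"))
  long <- do.call(rbind, lapply(traps, function(t) t[, c("gene", "abundance")]))
  means <- tapply(long$abundance, long$gene, mean)
  trap_list(names(means), as.numeric(means))
}

#' Partition a DEG table by a gene set
#'
#' Splits a DEG table into the rows whose gene is in `keep` (e.g. Q1-TRAP
#' genes) and the rest (the discarded "REST" genes). The two parts are a
#' disjoint partition of the input.
#'
#' @param degs A `DEGTable`.
#' @param keep Character vector of gene symbols.
#' @return List with elements `kept` and `rest`, both `DEGTable`s.
#' @export
filter_by_set <- function(degs, keep) {
  inset <- degs$gene %in% keep
  list(kept = degs[inset, , drop = FALSE],
       rest = degs[!inset, , drop = FALSE])
}

#' Rank a transcriptome into UP and DOWN sections
#'
#' Orders genes along a single significance axis: the UP section by
#' descending moderated t, then the DOWN section continuing downward (t
#' closest to zero first, so the most significant DOWN genes come last).
#' Ties on t are broken by gene symbol.
#'
#' @param degs A `DEGTable` (typically with `keep_all = TRUE` so the whole
#'   transcriptome is ranked).
#' @return The reordered table with a `section` column (UP/DOWN).
#' @export
rank_transcriptome <- function(degs) {
  up <- degs[degs$direction == "UP", , drop = FALSE]
  dn <- degs[degs$direction == "DOWN", , drop = FALSE]
  up <- up[order(-up$t_mod, up$gene), , drop = FALSE]
  dn <- dn[order(-dn$t_mod, dn$gene), , drop = FALSE]
  out <- rbind(up, dn)
  out$section <- rep(c("UP", "DOWN"), c(nrow(up), nrow(dn)))
  rownames(out) <- NULL
  out
}

#' Bin a ranked transcriptome and summarize each bin
#'
#' Cuts each section of a ranked table into consecutive, non-overlapping
#' bins of `bin_size` genes (a final short remainder bin is retained so bin
#' index remains interpretable as rank), and reports per bin the median log
#' fold change, median adjusted p and the count of genes belonging to the
#' supplied quartile set.
#'
#' @param ranked Output of [rank_transcriptome()].
#' @param bin_size Genes per bin (>= 2).
#' @param q1 Character vector of quartile member genes.
#' @return A `BinProfile` data frame (bin, section, n, median_logFC,
#'   median_p_adj, q1_count) with the per-bin gene lists in attribute
#'   `bin_genes`.
#' @export
bin_profile <- function(ranked, bin_size, q1 = character(0)) {
  assert_that(is_count(bin_size, 2L), "bin_size must be an integer >= 2")
  if (bin_size > nrow(ranked))
    warnf("bin_size %d exceeds input size %d: single bin", bin_size,
          nrow(ranked))
  if (is.null(ranked$section)) ranked$section <- ranked$direction
  rows <- list(); genes <- list(); bin_id <- 0L
  for (sec in intersect(c("UP", "DOWN"), unique(ranked$section))) {
    part <- ranked[ranked$section == sec, , drop = FALSE]
    n <- nrow(part)
    starts <- seq(1L, n, by = bin_size)
    for (s in starts) {
      e <- min(s + bin_size - 1L, n)
      bin_id <- bin_id + 1L
      chunk <- part[s:e, , drop = FALSE]
      rows[[bin_id]] <- data.frame(
        bin = bin_id, section = sec, n = nrow(chunk),
        median_logFC = stats::median(chunk$logFC),
        median_p_adj = stats::median(chunk$p_adj),
        q1_count = sum(chunk$gene %in% q1), stringsAsFactors = FALSE)
      genes[[bin_id]] <- chunk$gene
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bin_genes") <- genes
  class(out) <- c("BinProfile", class(out))
  out
}

#' Translate gene symbols in a keyed table
#'
#' Replaces the gene key via a two-column mapping (e.g. rat to mouse
#' orthologs). Unmapped rows are dropped and counted in the log; when
#' several input genes map to the same target, the collision is resolved
#' like probe collapse: keep the row with maximal `|t_mod|` (if present),
#' ties by lexicographically smallest original key.
#'
#' @param table Data frame with a gene key column.
#' @param mapping Data frame with columns from, to (see [read_mapping()]).
#' @param gene_col Name of the key column.
#' @return The translated table.
#' @export
map_symbols <- function(table, mapping, gene_col = "gene") {
  assert_that(gene_col %in% names(table), "no column '%s' in table", gene_col)
  idx <- match(table[[gene_col]], mapping$from)
  dropped <- sum(is.na(idx))
  if (dropped) log_msg("map_symbols: dropped %d unmapped row(s)", dropped)
  out <- table[!is.na(idx), , drop = FALSE]
  orig <- out[[gene_col]]
  out[[gene_col]] <- mapping$to[idx[!is.na(idx)]]
  tcol <- if ("t_mod" %in% names(out)) -abs(out$t_mod) else rep(0, nrow(out))
  ord <- order(out[[gene_col]], tcol, orig)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[[gene_col]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a bin profile as TSV
#' @param profile A `BinProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
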