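# Term-level enrichment/depletion: two-sided hypergeometric test with
# Bonferroni correction, term-selection filters and Cohen's-kappa term
# grouping (the ClueGO-style parameter set).

#' Two-sided hypergeometric p-value
#'
#' Tail-doubling construction: `p = min(1, 2 * min(P(X >= k), P(X <= k)))`
#' with `X ~ Hypergeometric(N, K, n)` — `N` universe genes of which `K`
#' carry the annotation, `n` drawn, `k` annotated among the drawn.
#'
#' @param k Query genes carrying the annotation.
#' @param K Universe genes carrying the annotation.
#' @param n Query size.
#' @param N Universe size.
#' @return Two-sided p-value in (0, 1].
#' @export
hypergeom_two_sided <- function(k, K, n, N) {
  assert_that(is_count(N, 1L) && is_count(K) && is_count(n) && is_count(k),
              "k, K, n, N must be non-negative integers")
  if (K > N || n > N || k > min(K, n) || k < max(0, n - (N - K)))
    stopf("impossible hypergeometric configuration (k=%d K=%d n=%d N=%d)",
          k, K, n, N)
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  lower <- stats::phyper(k, K, N - K, n)
  min(1, 2 * min(upper, lower))
}

#' Term-selection filters
#'
#' Keeps the terms with at least `min_genes` query hits and with hits
#' covering at least `min_pct` of the term's genes (defaults 3 and 2
#' percent).
#'
#' @param terms A [gene_set_collection()].
#' @param query Character vector of query genes.
#' @param min_genes Minimal number of query hits.
#' @param min_pct Minimal hit fraction of the term size.
#' @return Character vector of eligible term names.
#' @export
term_filters <- function(terms, query, min_genes = 3, min_pct = 0.02) {
  hits <- vapply(terms$sets, function(g) length(intersect(g, query)),
                 integer(1))
  sizes <- lengths(terms$sets)
  names(terms$sets)[hits >= min_genes & hits >= min_pct * sizes]
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Agreement of the two membership indicators across the universe, chance
#' corrected. Identical sets give 1, complementary sets that split the
#' universe give -1.
#'
#' @param a,b Character vectors of member genes.
#' @param universe Character vector of all genes considered.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_pair <- function(a, b, universe) {
  ina <- universe %in% a
  inb <- universe %in% b
  n <- length(universe)
  assert_that(n > 0, "empty universe")
  po <- sum(ina == inb) / n
  pa <- sum(ina) / n; pb <- sum(inb) / n
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Group terms by kappa agreement
#'
#' Builds single-linkage groups over term pairs whose kappa is at least the
#' threshold, then merges groups sharing at least `merge_share` of their
#' genes (fraction of the smaller group's gene union). Terms in groups
#' smaller than `min_group` remain as singleton groups.
#'
#' @param memberships Named list of term gene vectors (non-empty).
#' @param universe Character vector of all genes considered.
#' @param threshold Kappa threshold (default 0.5).
#' @param min_group Minimal number of terms for a true group (default 2).
#' @param merge_share Gene-sharing fraction that triggers a group merge
#'   (default 0.5).
#' @return Named integer vector: group id per term.
#' @export
kappa_grouping <- function(memberships, universe, threshold = 0.5,
                           min_group = 2, merge_share = 0.5) {
  m <- length(memberships)
  assert_that(m >= 1, "no terms to group")
  empty <- lengths(memberships) == 0
  if (any(empty))
    stopf("term(s) with empty membership: %s",
          paste(names(memberships)[empty], collapse = ", "))
  if (m == 1) return(stats::setNames(1L, names(memberships)))
  kap <- kappa_term_matrix(memberships, universe)
  # single-linkage components over the kappa >= threshold graph
  group <- seq_len(m)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (kap[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  # merge groups that share enough of their gene unions
  repeat {
    ids <- unique(comp)
    if (length(ids) < 2) break
    unions <- lapply(ids, function(id)
      unique(unlist(memberships[comp == id], use.names = FALSE)))
    merged <- FALSE
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        shared <- length(intersect(unions[[i]], unions[[j]]))
        smaller <- min(length(unions[[i]]), length(unions[[j]]))
        if (smaller > 0 && shared / smaller >= merge_share) {
          comp[comp == ids[j]] <- ids[i]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # components below the minimal group size fall back to singleton groups
  sizes <- table(comp)
  small <- comp %in% as.integer(names(sizes)[sizes < min_group])
  if (any(small)) comp[small] <- m + seq_len(sum(small))
  stats::setNames(match(comp, unique(comp)), names(memberships))
}

#' Kappa matrix of a list of terms
#' @inheritParams kappa_grouping
#' @return Symmetric matrix of pairwise kappas (diagonal 1).
#' @export
kappa_term_matrix <- function(memberships, universe) {
  m <- length(memberships)
  kap <- diag(1, m)
  if (m > 1) for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    kap[i, j] <- kap[j, i] <- kappa_pair(memberships[[i]], memberships[[j]],
                                         universe)
  }
  dimnames(kap) <- list(names(memberships), names(memberships))
  kap
}

go_result_row <- function(term, k, K, n, N, p_two) {
  data.frame(term = term, k = k, K = K, n = n, N = N, p_two = p_two,
             direction = if (k > n * K / N) "enriched" else "depleted",
             stringsAsFactors = FALSE)
}

#' Term enrichment for one query list
#'
#' Term filters, two-sided hypergeometric test per eligible term,
#' Bonferroni correction over the tested terms, and kappa grouping of the
#' tested terms.
#'
#' @param query Character vector of query genes (e.g. the UP list).
#' @param terms A [gene_set_collection()].
#' @param universe Character vector of universe genes; queries and terms
#'   are intersected with it.
#' @param min_genes,min_pct Term-selection filters (see [term_filters()]).
#' @param kappa_threshold,min_group,merge_share Grouping parameters (see
#'   [kappa_grouping()]).
#' @return A `TermTestResult` data frame: term, k, K, n, N, p_two, p_bonf,
#'   neg_log10_p_bonf, direction, group_id. Empty query gives zero rows.
#' @export
go_enrichment <- function(query, terms, universe, min_genes = 3,
                          min_pct = 0.02, kappa_threshold = 0.5,
                          min_group = 2, merge_share = 0.5) {
  assert_that(length(universe) > 0, "universe must be non-empty")
  query <- intersect(unique(query), universe)
  sets <- lapply(terms$sets, function(g) intersect(g, universe))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  empty_result <- data.frame(term = character(0), k = integer(0),
                             K = integer(0), n = integer(0), N = integer(0),
                             p_two = numeric(0), p_bonf = numeric(0),
                             neg_log10_p_bonf = numeric(0),
                             direction = character(0), group_id = integer(0),
                             stringsAsFactors = FALSE)
  if (!length(query) || !length(sets)) return(empty_result)
  eligible <- term_filters(gene_set_collection(sets), query,
                           min_genes = min_genes, min_pct = min_pct)
  if (!length(eligible)) return(empty_result)
  N <- length(universe); n <- length(query)
  rows <- lapply(eligible, function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(sets[[nm]], query))
    go_result_row(nm, k, K, n, N, hypergeom_two_sided(k, K, n, N))
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p_two * nrow(out))
  out$neg_log10_p_bonf <- -log10(out$p_bonf)
  groups <- kappa_grouping(sets[eligible], universe,
                           threshold = kappa_threshold,
                           min_group = min_group, merge_share = merge_share)
  out$group_id <- as.integer(groups[out$term])
  class(out) <- c("TermTestResult", class(out))
  out
}

#' GO enrichment of the UP and DOWN lists independently
#'
#' Runs [go_enrichment()] separately on the up- and down-regulated query
#' lists, as the direction of functional change is analyzed per section.
#'
#' @param up,down Character vectors of up-/down-regulated query genes.
#' @param terms A [gene_set_collection()].
#' @param universe Universe genes; must be stated explicitly (the choice of
#'   universe materially changes the test and is recorded with the run).
#' @param ... Passed to [go_enrichment()].
#' @return List with elements `UP` and `DOWN`, each a `TermTestResult`.
#' @export
run_go <- function(up, down, terms, universe, ...) {
  list(UP = go_enrichment(up, terms, universe, ...),
       DOWN = go_enrichment(down, terms, universe, ...))
}
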