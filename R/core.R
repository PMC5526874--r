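# Multi-condition core-signature extraction, Venn/Pearson descriptive
# statistics, and cross-cell-type comparison.

#' Venn regions and directional overlap percentages for 2-3 gene sets
#'
#' @param sets Named list of 2 or 3 non-empty gene sets.
#' @return An `OverlapReport`: list with `regions` (named region counts,
#'   names are membership bitmasks like `"A&B"`), `pairs` (data frame of
#'   ordered pairs with intersection size and percentage of A found in B)
#'   and `union_size`.
#' @export
venn_overlap <- function(sets) {
  assert_that(is.list(sets) && length(sets) %in% c(2L, 3L) &&
                !is.null(names(sets)), "sets must be a named list of 2 or 3")
  assert_that(all(lengths(sets) > 0), "sets must be non-empty")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- table(key)
  pairs <- do.call(rbind, lapply(names(sets), function(a) {
    do.call(rbind, lapply(setdiff(names(sets), a), function(b) {
      inter <- length(intersect(sets[[a]], sets[[b]]))
      data.frame(a = a, b = b, intersection = inter,
                 pct_a_in_b = 100 * inter / length(sets[[a]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(regions = stats::setNames(as.integer(regions),
                                           names(regions)),
                 pairs = pairs, union_size = length(universe)),
            class = "OverlapReport")
}

#' Pearson correlation of log fold changes between two DEG tables
#'
#' @param a,b `DEGTable`s (or any data frames with gene and logFC columns).
#' @param universe Optional gene subset; defaults to the genes shared by
#'   both tables (at least 3 required).
#' @return Pearson correlation coefficient.
#' @export
pearson_logfc <- function(a, b, universe = NULL) {
  shared <- intersect(a$gene, b$gene)
  if (!is.null(universe)) shared <- intersect(shared, universe)
  if (length(shared) < 3) stopf("need >= 3 shared genes (got %d)",
                                length(shared))
  x <- a$logFC[match(shared, a$gene)]
  y <- b$logFC[match(shared, b$gene)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in logFC; correlation undefined")
  stats::cor(x, y)
}

#' Extract the multi-condition core signature
#'
#' The headline cascade: genes significant in every condition's DEG table
#' and present in the TRAP first quartile (the shared stage), of those the
#' genes up-regulated in every condition (the UP-in-all stage), flagged by
#' membership in the CRE-target registry (the registry stage). The
#' signature is ordered by descending average log2 fold change across
#' conditions.
#'
#' @param deg_tables Named list (>= 2) of per-condition `DEGTable`s holding
#'   significant genes.
#' @param q1 Character vector of TRAP first-quartile genes.
#' @param registry Character vector of CRE-target registry genes.
#' @param filter_first If `TRUE` (default) the Q1 filter is applied to each
#'   condition list before intersecting, consistent with filtering each DEG
#'   list before downstream analysis; `FALSE` intersects first and filters
#'   the shared set (same final genes, different shared-stage count).
#' @return A `CoreSignature` data frame (gene, `logFC_<condition>` columns,
#'   avg_fc, in_registry, q1_trap) carrying the cascade in
#'   `attr(, "counts")`: n_shared, n_up_in_all, n_in_registry.
#' @export
extract_core <- function(deg_tables, q1, registry, filter_first = TRUE) {
  assert_that(is.list(deg_tables) && length(deg_tables) >= 2 &&
                !is.null(names(deg_tables)),
              "deg_tables must be a named list of >= 2 DEG tables")
  conds <- sort(names(deg_tables))          # order-invariant
  deg_tables <- deg_tables[conds]
  lists <- if (filter_first) {
    lapply(deg_tables, function(d) d[d$gene %in% q1, , drop = FALSE])
  } else deg_tables
  shared <- Reduce(intersect, lapply(lists, `[[`, "gene"))
  if (!filter_first) shared <- intersect(shared, q1)
  up_in_all <- shared
  for (d in deg_tables) {
    upg <- d$gene[d$direction == "UP"]
    up_in_all <- intersect(up_in_all, upg)
  }
  fc <- vapply(deg_tables, function(d) d$logFC[match(up_in_all, d$gene)],
               numeric(length(up_in_all)))
  if (length(up_in_all) == 1L)
    fc <- matrix(fc, nrow = 1, dimnames = list(NULL, conds))
  if (length(up_in_all) == 0L)
    fc <- matrix(numeric(0), nrow = 0, ncol = length(conds),
                 dimnames = list(NULL, conds))
  avg_fc <- if (nrow(fc)) rowMeans(fc) else numeric(0)
  out <- data.frame(gene = up_in_all, fc, avg_fc = avg_fc,
                    in_registry = up_in_all %in% registry,
                    q1_trap = up_in_all %in% q1,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(conds) + 1L] <- paste0("logFC_", conds)
  out <- out[order(-out$avg_fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_shared = length(shared),
                           n_up_in_all = length(up_in_all),
                           n_in_registry = sum(out$in_registry))
  class(out) <- c("CoreSignature", class(out))
  out
}

#' Registry-confirmed genes of a core signature
#' @param sig A `CoreSignature`.
#' @param registry_only If `TRUE` (default) return only genes flagged as
#'   registry members; otherwise all signature genes.
#' @return Character vector of genes in signature order.
#' @export
signature_genes <- function(sig, registry_only = TRUE) {
  if (registry_only) sig$gene[sig$in_registry] else sig$gene
}

#' Compare the core signatures of two cell types
#'
#' Reports the genes shared between the registry-confirmed signatures and,
#' if a category map is supplied, the per-signature category composition
#' (genes without a category are reported as `unassigned`).
#'
#' @param sig_a,sig_b `CoreSignature`s.
#' @param categories Optional data frame with columns gene, category.
#' @param registry_only Compare registry-confirmed genes (default) or all
#'   signature genes.
#' @return List with `shared` (gene vector) and, when categories are given,
#'   `category_pct`: a list of named percentage vectors per signature.
#' @export
compare_cell_signatures <- function(sig_a, sig_b, categories = NULL,
                                    registry_only = TRUE) {
  ga <- signature_genes(sig_a, registry_only)
  gb <- signature_genes(sig_b, registry_only)
  out <- list(shared = intersect(ga, gb),
              n_a = length(ga), n_b = length(gb))
  if (!is.null(categories)) {
    assert_that(all(c("gene", "category") %in% names(categories)),
                "categories needs columns gene, category")
    pct <- function(g) {
      cat <- categories$category[match(g, categories$gene)]
      cat[is.na(cat)] <- "unassigned"
      100 * table(cat) / length(g)
    }
    out$category_pct <- list(a = pct(ga), b = pct(gb))
  }
  out
}

#' Screen curated function lists against the DEG tables
#'
#' For each user-supplied function list (e.g. well-recognized astrocytic
#' functions), reports which member genes are differentially expressed in
#' each condition and which are core (significant in all conditions).
#'
#' @param deg_tables Named list of per-condition `DEGTable`s.
#' @param function_lists Named list of gene vectors.
#' @return Data frame: function, gene, one logical `deg_<condition>` column
#'   per condition, and `core`.
#' @export
curated_function_screen <- function(deg_tables, function_lists) {
  assert_that(is.list(function_lists) && !is.null(names(function_lists)),
              "function_lists must be a named list")
  conds <- names(deg_tables)
  rows <- lapply(names(function_lists), function(fn) {
    genes <- unique(function_lists[[fn]])
    flags <- vapply(deg_tables, function(d) genes %in% d$gene,
                    logical(length(genes)))
    if (length(genes) == 1L)
      flags <- matrix(flags, nrow = 1, dimnames = list(NULL, conds))
    hit <- rowSums(flags) > 0
    if (!any(hit)) return(NULL)
    df <- data.frame(func = fn, gene = genes[hit],
                     flags[hit, , drop = FALSE],
                     core = rowSums(flags[hit, , drop = FALSE]) ==
                       length(conds),
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[seq_along(conds) + 2L] <- paste0("deg_", conds)
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(func = character(0), gene = character(0),
                      core = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a core signature as TSV plus a JSON cascade summary
#' @param sig A `CoreSignature`.
#' @param path TSV output path.
#' @param json_path Optional JSON path for the cascade counts.
#' @return `path`, invisibly.
#' @export
write_core_signature <- function(sig, path, json_path = NULL) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(attr(sig, "counts")), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
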