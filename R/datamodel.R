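# Domain types. Lightweight S3 following the limma style: validated lists
# and data frames, not formal classes.

#' Construct a validated expression matrix
#'
#' Container for normalized log2 expression values, genes in rows and
#' samples in columns, with a condition label per sample.
#'
#' @param values Numeric matrix of log2 intensities with unique gene symbols
#'   as row names and sample identifiers as column names.
#' @param conditions Named character vector mapping every sample identifier
#'   to its condition label.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `conditions`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expression_matrix(m, c(s1 = "CT", s2 = "FSK"))
#' @export
expression_matrix <- function(values, conditions) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  assert_that(!is.null(genes) && !is.null(samples),
              "values must have gene row names and sample column names")
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stopf("duplicate gene identifiers: %s", paste(unique(dup), collapse = ", "))
  assert_that(all(is.finite(values)), "expression values must all be finite")
  assert_that(is.character(conditions) && !is.null(names(conditions)),
              "conditions must be a named character vector")
  missing_cond <- setdiff(samples, names(conditions))
  if (length(missing_cond))
    stopf("samples without a condition label: %s",
          paste(missing_cond, collapse = ", "))
  unknown <- setdiff(names(conditions), samples)
  if (length(unknown))
    stopf("condition map names unknown sample(s): %s",
          paste(unknown, collapse = ", "))
  structure(list(values = values, conditions = conditions[samples]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Samples belonging to a condition
#' @param em An `ExpressionMatrix`.
#' @param condition Condition label.
#' @return Character vector of sample identifiers.
#' @export
condition_samples <- function(em, condition) {
  names(em$conditions)[em$conditions == condition]
}

deg_table_columns <- c("gene", "logFC", "t_mod", "p_raw", "p_adj",
                       "direction", "mean_expr")

#' Validate a differential-expression table
#'
#' Checks the invariants of a per-gene DEG table: one row per gene, `UP`
#' direction iff positive log fold change, probabilities in range and
#' adjusted p at least the raw p.
#'
#' @param df Data frame with columns gene, logFC, t_mod, p_raw, p_adj,
#'   direction, mean_expr.
#' @return The input, invisibly, with class `DEGTable` prepended.
#' @export
validate_deg_table <- function(df) {
  missing_cols <- setdiff(deg_table_columns, names(df))
  if (length(missing_cols))
    stopf("DEG table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup))
    stopf("DEG table has duplicated gene(s): %s",
          paste(unique(dup), collapse = ", "))
  assert_that(all(is.finite(df$logFC)), "logFC must be finite")
  assert_that(all(df$p_raw >= 0 & df$p_raw <= 1), "p_raw out of [0,1]")
  assert_that(all(df$p_adj >= 0 & df$p_adj <= 1), "p_adj out of [0,1]")
  assert_that(all(df$p_adj >= df$p_raw - 1e-12), "p_adj must be >= p_raw")
  assert_that(all(df$direction %in% c("UP", "DOWN")),
              "direction must be UP or DOWN")
  bad <- (df$direction == "UP") != (df$logFC > 0)
  assert_that(!any(bad), "direction must be UP exactly when logFC > 0")
  if (!inherits(df, "DEGTable")) class(df) <- c("DEGTable", class(df))
  invisible(df)
}

#' Construct a TRAP abundance list
#'
#' Ribosome-bound (translated) gene abundances with a dense rank by
#' descending abundance. Ties on abundance are broken by lexicographic gene
#' symbol so ranks are a reproducible permutation of `1..G`.
#'
#' @param gene Character vector of unique gene symbols.
#' @param abundance Non-negative finite abundance score per gene.
#' @return A `TrapList` data frame with columns gene, abundance, rank,
#'   ordered by rank.
#' @export
trap_list <- function(gene, abundance) {
  assert_that(length(gene) == length(abundance) && length(gene) > 0,
              "gene and abundance must be non-empty and of equal length")
  assert_that(!anyDuplicated(gene), "duplicate gene in TRAP list")
  assert_that(all(is.finite(abundance)) && all(abundance >= 0),
              "abundances must be finite and non-negative")
  ord <- order(-abundance, gene)
  out <- data.frame(gene = gene[ord], abundance = abundance[ord],
                    rank = seq_along(gene), stringsAsFactors = FALSE)
  class(out) <- c("TrapList", class(out))
  out
}

#' Construct a gene-set collection
#'
#' Named, non-empty gene sets with a free-text description each, as used for
#' GO terms, GSEA sets, TRAP quartiles and CRE-target registries.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector of descriptions, recycled
#'   from `""`.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  assert_that(is.list(sets), "sets must be a list")
  if (length(sets)) {
    assert_that(!is.null(names(sets)) && all(nzchar(names(sets))),
                "every set needs a name")
    assert_that(!anyDuplicated(names(sets)), "set names must be unique")
    sizes <- lengths(sets)
    if (any(sizes == 0))
      stopf("empty gene set(s): %s",
            paste(names(sets)[sizes == 0], collapse = ", "))
    sets <- lapply(sets, function(g) unique(as.character(g)))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %s\n", length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' significance level 0.05, Benjamini-Hochberg adjustment, 250-gene bins,
#' a (-450, +50) promoter window, weighted GSEA with 1000 gene-set
#' permutations, and the GO term-selection and kappa-grouping parameters
#' (minimum 3 query genes, 2 percent of the term, kappa threshold 0.5).
#'
#' @param alpha DEG significance level in (0, 1).
#' @param adjust_method Multiple-testing adjustment, `"BH"` or `"none"`.
#' @param bin_size Genes per bin in ranked-transcriptome profiles.
#' @param promoter_window Length-2 numeric, offsets (upstream, downstream)
#'   relative to the transcription start site.
#' @param gsea_n_perm Gene-set permutations for the GSEA null (>= 100).
#' @param gsea_exponent GSEA weighting exponent.
#' @param go_min_genes Minimal query hits for a term to be tested.
#' @param go_min_pct Minimal query hits as a fraction of term size.
#' @param kappa_threshold Cohen's kappa threshold for term grouping.
#' @param seed Master seed for randomized stages; recorded in every output.
#' @return A `RunConfig` list.
#' @export
run_config <- function(alpha = 0.05, adjust_method = c("BH", "none"),
                       bin_size = 250, promoter_window = c(-450, 50),
                       gsea_n_perm = 1000, gsea_exponent = 1,
                       go_min_genes = 3, go_min_pct = 0.02,
                       kappa_threshold = 0.5, seed = NULL) {
  adjust_method <- match.arg(adjust_method)
  assert_that(is_prob(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(is_count(bin_size, 2L), "bin_size must be an integer >= 2")
  assert_that(length(promoter_window) == 2 &&
                promoter_window[1] < promoter_window[2],
              "promoter_window must be two increasing offsets")
  assert_that(is_count(gsea_n_perm, 100L), "gsea_n_perm must be >= 100")
  assert_that(is.numeric(gsea_exponent) && gsea_exponent >= 0,
              "gsea_exponent must be non-negative")
  assert_that(is_count(go_min_genes, 1L), "go_min_genes must be >= 1")
  assert_that(is_prob(go_min_pct), "go_min_pct must be in [0,1]")
  assert_that(is.numeric(kappa_threshold) && kappa_threshold >= -1 &&
                kappa_threshold <= 1, "kappa_threshold must be in [-1,1]")
  if (!is.null(seed)) seed <- require_seed(seed)
  structure(list(alpha = alpha, adjust_method = adjust_method,
                 bin_size = as.integer(bin_size),
                 promoter_window = as.numeric(promoter_window),
                 gsea_n_perm = as.integer(gsea_n_perm),
                 gsea_exponent = gsea_exponent,
                 go_min_genes = as.integer(go_min_genes),
                 go_min_pct = go_min_pct,
                 kappa_threshold = kappa_threshold, seed = seed),
            class = "RunConfig")
}
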