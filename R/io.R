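# Readers and writers. All tabular formats are TSV with '.' decimals and
# '#'-prefixed comment lines; joins are by exact, case-sensitive gene symbol.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a log2 expression matrix and its condition map
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column and a header row of sample identifiers; the condition map is a
#' two-column file (sample, condition). Duplicate genes, non-numeric cells
#' and samples missing from the condition map are rejected.
#'
#' @param path Expression TSV path.
#' @param condition_map Path to the sample-to-condition TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition_map) {
  raw <- read_tsv_checked(path, "expression")
  if (ncol(raw) < 2) stopf("expression file needs gene column plus samples")
  genes <- as.character(raw[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stopf("duplicated gene row(s) in %s: %s", path, paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stopf("non-numeric or missing value in %s at gene '%s', sample '%s'",
          path, genes[idx[1]], colnames(vals)[idx[2]])
  }
  rownames(vals) <- genes
  cm <- read_tsv_checked(condition_map, "condition map")
  if (ncol(cm) < 2) stopf("condition map needs two columns (sample, condition)")
  conditions <- stats::setNames(as.character(cm[[2]]), as.character(cm[[1]]))
  expression_matrix(vals, conditions)
}

#' Write an expression matrix (and optionally its condition map)
#' @param em An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param condition_path Optional path for the sample/condition TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, condition_path = NULL) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(condition_path)) {
    cm <- data.frame(sample = names(em$conditions),
                     condition = unname(em$conditions))
    utils::write.table(cm, condition_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' members. Members are deduplicated within a line; lines with fewer than
#' three fields are rejected with their line number.
#'
#' @param path GMT path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("GMT parse error at line %d: fewer than 3 fields", i)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stopf("GMT parse error at line %d: empty gene set '%s'", i, fields[1])
    sets[[fields[1]]] <- members
    descs <- c(descs, fields[2])
  }
  gene_set_collection(sets, descs)
}

#' Write a gene-set collection as GMT
#' @param gsc A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(seq_along(gsc$sets), function(i) {
    paste(c(names(gsc$sets)[i], gsc$descriptions[i], gsc$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ranked list (RNK)
#' @param path RNK path (gene, score; no header required, header tolerated).
#' @return Data frame with columns gene, score, ordered by descending score
#'   (ties broken by gene symbol).
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stopf("RNK file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("RNK file needs two columns (gene, score)")
  # tolerate a header line
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  out <- data.frame(gene = as.character(df[[1]]),
                    score = as.numeric(df[[2]]), stringsAsFactors = FALSE)
  if (anyNA(out$score)) stopf("non-numeric score in RNK file %s", path)
  if (anyDuplicated(out$gene)) stopf("duplicate gene in RNK file %s", path)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' Write a ranked list as RNK
#' @param rnk Data frame with columns gene, score.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(rnk, path) {
  utils::write.table(rnk[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TRAP abundance table
#' @param path TSV with columns gene, abundance (header required).
#' @return A [trap_list()].
#' @export
read_trap <- function(path) {
  df <- read_tsv_checked(path, "TRAP")
  if (ncol(df) < 2) stopf("TRAP table needs columns (gene, abundance)")
  trap_list(as.character(df[[1]]), as.numeric(df[[2]]))
}

#' Write a TRAP list
#' @param trap A `TrapList`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trap <- function(trap, path) {
  utils::write.table(trap[, c("gene", "abundance")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column symbol mapping table
#' @param path TSV with columns (from, to); header required.
#' @return Data frame with columns from, to.
#' @export
read_mapping <- function(path) {
  df <- read_tsv_checked(path, "mapping")
  if (ncol(df) < 2) stopf("mapping table needs two columns")
  data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read promoter sequences from FASTA
#' @param path FASTA path; one record per gene symbol.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stopf("duplicate record names in FASTA %s", path)
  stats::setNames(toupper(as.character(ss)), nm)
}

#' Write promoter sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a position weight matrix
#'
#' Supports JASPAR pfm files (optional `>` header, four rows `A [ ... ]` or
#' bare counts) and TRANSFAC matrix blocks (`P0` header with one row per
#' position). Counts must be non-negative and the matrix at least 4 wide.
#'
#' @param path Matrix file path.
#' @param format `"jaspar"` or `"transfac"`.
#' @param pseudocount_frac Passed to [pwm_matrix()].
#' @return A [pwm_matrix()].
#' @export
read_pwm <- function(path, format = c("jaspar", "transfac"),
                     pseudocount_frac = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("PWM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  counts <- switch(format,
                   jaspar = parse_jaspar(lines),
                   transfac = parse_transfac(lines))
  pwm_matrix(counts, pseudocount_frac = pseudocount_frac)
}

parse_jaspar <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), ">")]
  if (length(lines) < 4) stopf("JASPAR matrix needs 4 base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    base <- NA_character_
    if (toks[1] %in% c("A", "C", "G", "T")) {
      base <- toks[1]; toks <- toks[-1]
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) stopf("JASPAR format error: non-numeric count in '%s'", l)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
  if (!anyNA(bases)) {
    if (!setequal(bases, c("A", "C", "G", "T")))
      stopf("JASPAR format error: alphabet must be A,C,G,T (got %s)",
            paste(bases, collapse = ","))
    mat <- mat[match(c("A", "C", "G", "T"), bases), , drop = FALSE]
  }
  rownames(mat) <- c("A", "C", "G", "T")
  mat
}

parse_transfac <- function(lines) {
  header <- grep("^P0|^PO", lines)
  if (!length(header)) stopf("TRANSFAC format error: no P0 header")
  cols <- strsplit(trimws(sub("^P0|^PO", "", lines[header[1]])), "\\s+")[[1]]
  if (!setequal(cols[1:4], c("A", "C", "G", "T")))
    stopf("TRANSFAC format error: alphabet must be A,C,G,T")
  body <- lines[-seq_len(header[1])]
  body <- body[grepl("^\\s*[0-9]+\\s", body)]
  if (!length(body)) stopf("TRANSFAC format error: no position rows")
  vals <- lapply(body, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]][-1]
    v <- suppressWarnings(as.numeric(toks[1:4]))
    if (anyNA(v)) stopf("TRANSFAC format error: non-numeric row '%s'", l)
    v
  })
  mat <- t(do.call(rbind, vals))        # rows become A,C,G,T in column order
  rownames(mat) <- cols[1:4]
  mat[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Write a PWM in JASPAR pfm format
#' @param pwm A `PWM`.
#' @param path Output path.
#' @param name Header name for the record.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path, name = "PWM") {
  lines <- c(sprintf(">%s", name),
             vapply(c("A", "C", "G", "T"), function(b) {
               sprintf("%s [ %s ]", b,
                       paste(format(pwm$counts[b, ], trim = TRUE),
                             collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records the subcommand, configuration, seed, and md5 digests of the
#' inputs so a run can be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param subcommand Pipeline stage name.
#' @param config List of parameters used.
#' @param seed Seed used (or NULL).
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of files written.
#' @param extra Optional named list merged into the summary.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, subcommand, config = list(), seed = NULL,
                              inputs = character(0), outputs = character(0),
                              extra = list()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  summary <- c(list(subcommand = subcommand, config = config,
                    seed = seed, input_md5 = digests,
                    outputs = as.list(outputs)), extra)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
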