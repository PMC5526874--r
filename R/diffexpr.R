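# Two-group contrasts with empirical-Bayes variance moderation.
#
# The per-gene variances s2_g are shrunk toward a prior s0^2 with prior
# degrees of freedom d0, both estimated by the method of moments on
# e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2). The moderated t uses the
# posterior variance s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g) and is
# referred to a t distribution with d0 + d_g degrees of freedom.

#' Per-gene statistics for a two-group contrast
#'
#' Computes, for every gene, the log2 fold change (treated minus control),
#' the pooled within-group variance, the residual degrees of freedom and the
#' unscaled standard-error factor `v = 1/n_t + 1/n_c`.
#'
#' @param em An [expression_matrix()].
#' @param treated,control Condition labels to contrast.
#' @return A `GeneLevelStats` data frame with columns gene, logFC, s2, df,
#'   v, mean_expr.
#' @export
fit_group_contrast <- function(em, treated, control) {
  st <- condition_samples(em, treated)
  sc <- condition_samples(em, control)
  if (length(st) < 2) stopf("condition '%s' has fewer than 2 samples", treated)
  if (length(sc) < 2) stopf("condition '%s' has fewer than 2 samples", control)
  xt <- em$values[, st, drop = FALSE]
  xc <- em$values[, sc, drop = FALSE]
  nt <- length(st); nc <- length(sc)
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  vt <- rowSums((xt - mt)^2) / (nt - 1)
  vc <- rowSums((xc - mc)^2) / (nc - 1)
  df <- nt + nc - 2
  out <- data.frame(
    gene = rownames(em$values),
    logFC = mt - mc,
    s2 = ((nt - 1) * vt + (nc - 1) * vc) / df,
    df = df,
    v = 1 / nt + 1 / nc,
    mean_expr = rowMeans(cbind(xt, xc)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("GeneLevelStats", class(out))
  out
}

# Inverse of trigamma by Newton iteration on 1/trigamma, which is almost
# linear (same approach as the standard empirical-Bayes implementations).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance moderation and moderated t
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' from the distribution of log sample variances, shrinks each gene's
#' variance toward the prior, and computes moderated t statistics with
#' two-sided p-values on `d0 + d_g` degrees of freedom. Genes with zero
#' sample variance are floored at the smallest positive variance in the
#' dataset and flagged (`s2_floored`), which avoids infinite t while
#' preserving their rank. If the moment estimate of `trigamma(d0/2)` is not
#' positive, `d0` is set to infinity (complete shrinkage).
#'
#' @param stats A `GeneLevelStats` data frame from [fit_group_contrast()].
#' @param d0,s0_sq Optional hyperparameter overrides; when supplied,
#'   estimation is skipped (use `d0 = 0` to recover the ordinary t).
#' @return A `ModeratedStats` data frame with per-gene columns gene, logFC,
#'   s2, s2_post, df_total, t_mod, p_raw, mean_expr, s2_floored, and
#'   attributes `d0` and `s0_sq`.
#' @export
empirical_bayes_moderate <- function(stats, d0 = NULL, s0_sq = NULL) {
  if (nrow(stats) < 30 && is.null(d0))
    stopf("hyperparameter estimation needs >= 30 genes (got %d)", nrow(stats))
  s2 <- stats$s2
  dg <- stats$df
  floored <- s2 <= 0
  if (all(floored)) stopf("all residual variances are zero; degenerate input")
  if (any(floored)) s2[floored] <- min(s2[s2 > 0])
  if (is.null(d0)) {
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    target <- mean((e - emean)^2 * length(e) / (length(e) - 1) -
                     trigamma(dg / 2))
    if (target <= 0) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      d0 <- 2 * trigamma_inverse(target)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    assert_that(d0 >= 0, "d0 must be non-negative")
    if (is.null(s0_sq)) s0_sq <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  df_total <- d0 + dg
  t_mod <- stats$logFC / sqrt(s2_post * stats$v)
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = stats$gene, logFC = stats$logFC, s2 = stats$s2,
                    s2_post = s2_post, df_total = df_total, t_mod = t_mod,
                    p_raw = p_raw, mean_expr = stats$mean_expr,
                    s2_floored = floored, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("ModeratedStats", class(out))
  out
}

#' Call differentially expressed genes
#'
#' Filters moderated statistics at a significance level, after optional
#' Benjamini-Hochberg adjustment, and labels direction from the sign of the
#' log fold change. Both raw and adjusted p-values are retained.
#'
#' @param mstats A `ModeratedStats` data frame.
#' @param alpha Significance level in (0, 1).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param keep_all If `TRUE`, return all genes (with a `significant`
#'   column) instead of only the significant rows.
#' @return A `DEGTable` data frame (gene, logFC, t_mod, p_raw, p_adj,
#'   direction, mean_expr), significant rows only unless `keep_all`.
#' @export
call_degs <- function(mstats, alpha = 0.05, adjust = c("BH", "none"),
                      keep_all = FALSE) {
  adjust <- match.arg(adjust)
  assert_that(is_prob(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  p_adj <- switch(adjust,
                  BH = stats::p.adjust(mstats$p_raw, method = "BH"),
                  none = mstats$p_raw)
  out <- data.frame(gene = mstats$gene, logFC = mstats$logFC,
                    t_mod = mstats$t_mod, p_raw = mstats$p_raw, p_adj = p_adj,
                    direction = ifelse(mstats$logFC > 0, "UP", "DOWN"),
                    mean_expr = mstats$mean_expr, stringsAsFactors = FALSE)
  if (keep_all) {
    out$significant <- out$p_adj < alpha
    return(validate_deg_table(out))
  }
  validate_deg_table(out[out$p_adj < alpha, , drop = FALSE])
}

#' Collapse probe-level statistics to gene level
#'
#' For every gene keeps the probe with the largest absolute moderated t;
#' ties are broken by lexicographically smallest probe identifier so the
#' result is deterministic.
#'
#' @param probe_stats Data frame with a probe column, a gene column and a
#'   `t_mod` column (plus any other columns, carried along).
#' @param probe_col,gene_col Column names.
#' @return The collapsed data frame, one row per gene, probe column dropped.
#' @export
collapse_probes <- function(probe_stats, probe_col = "probe",
                            gene_col = "gene") {
  assert_that(all(c(probe_col, gene_col, "t_mod") %in% names(probe_stats)),
              "probe_stats needs columns '%s', '%s' and 't_mod'",
              probe_col, gene_col)
  ord <- order(probe_stats[[gene_col]], -abs(probe_stats$t_mod),
               probe_stats[[probe_col]])
  sorted <- probe_stats[ord, , drop = FALSE]
  keep <- !duplicated(sorted[[gene_col]])
  out <- sorted[keep, setdiff(names(sorted), probe_col), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression for one contrast, end to end
#'
#' Convenience wrapper: [fit_group_contrast()] then
#' [empirical_bayes_moderate()] then [call_degs()].
#'
#' @inheritParams fit_group_contrast
#' @inheritParams call_degs
#' @return A `DEGTable` (see [call_degs()]).
#' @export
run_de <- function(em, treated, control, alpha = 0.05,
                   adjust = c("BH", "none"), keep_all = FALSE) {
  adjust <- match.arg(adjust)
  gls <- fit_group_contrast(em, treated, control)
  ms <- empirical_bayes_moderate(gls)
  call_degs(ms, alpha = alpha, adjust = adjust, keep_all = keep_all)
}
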