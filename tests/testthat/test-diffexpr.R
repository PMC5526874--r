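# Moderated differential expression.

test_that("group contrast matches the direct pooled-variance formulas", {
  em <- toy_expression()
  gls <- fit_group_contrast(em, "FSK", "CT")
  expect_equal(gls$logFC[gls$gene == "GA"], 1)
  expect_equal(gls$s2[gls$gene == "GA"], 0)
  expect_equal(gls$logFC[gls$gene == "GB"], 0)

  em <- random_expression(200, 3, seed = 1)
  gls <- fit_group_contrast(em, "FSK", "CT")
  x <- em$values
  for (i in c(1, 57, 200)) {
    xt <- x[i, 4:6]; xc <- x[i, 1:3]
    expect_equal(gls$logFC[i], mean(xt) - mean(xc), tolerance = 1e-12)
    expect_equal(gls$s2[i], (var(xt) * 2 + var(xc) * 2) / 4,
                 tolerance = 1e-12)
    expect_equal(gls$df[i], 4)
    expect_equal(gls$v[i], 2 / 3, tolerance = 1e-12)
  }
  expect_error(fit_group_contrast(em, "FSK", "NOPE"), "fewer than 2")
})

test_that("d0 = 0 recovers the ordinary t; shrinkage limits behave", {
  em <- random_expression(100, 4, seed = 2)
  gls <- fit_group_contrast(em, "FSK", "CT")
  ms <- empirical_bayes_moderate(gls, d0 = 0)
  t_ord <- gls$logFC / sqrt(gls$s2 * gls$v)
  expect_equal(ms$t_mod, t_ord, tolerance = 1e-10)

  # equal variances: posterior variance is constant and rank-preserving
  gls_eq <- gls; gls_eq$s2 <- rep(0.3, nrow(gls))
  ms_eq <- empirical_bayes_moderate(gls_eq)
  expect_true(is.infinite(attr(ms_eq, "d0")))
  expect_equal(diff(range(ms_eq$s2_post)), 0)

  # d0 -> Inf closed form: t -> logFC / sqrt(s0_sq * v)
  ms_inf <- empirical_bayes_moderate(gls, d0 = Inf, s0_sq = 0.25)
  expect_equal(ms_inf$t_mod, gls$logFC / sqrt(0.25 * gls$v),
               tolerance = 1e-12)

  # monotonicity: larger s2, all else fixed, shrinks |t|
  g2 <- gls[1:2, ]; g2$logFC <- c(1, 1); g2$s2 <- c(0.1, 0.5)
  m2 <- empirical_bayes_moderate(g2, d0 = 4, s0_sq = 0.2)
  expect_gt(abs(m2$t_mod[1]), abs(m2$t_mod[2]))

  gls0 <- gls; gls0$s2 <- 0
  expect_error(empirical_bayes_moderate(gls0), "degenerate")
})

test_that("hyperparameter estimation recovers a planted prior", {
  set.seed(31)
  G <- 10000; d0 <- 4; s0 <- 0.04; dg <- 4
  sigma2 <- d0 * s0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, dg) / dg
  gls <- data.frame(gene = sprintf("g%05d", 1:G), logFC = rnorm(G),
                    s2 = s2, df = dg, v = 2 / 3, mean_expr = 8)
  ms <- empirical_bayes_moderate(gls)
  expect_lt(abs(attr(ms, "d0") - d0) / d0, 0.25)
  expect_lt(abs(attr(ms, "s0_sq") - s0) / s0, 0.10)
  expect_true(all(ms$s2_post >= pmin(ms$s2, attr(ms, "s0_sq")) - 1e-12))
  expect_true(all(ms$s2_post <= pmax(ms$s2, attr(ms, "s0_sq")) + 1e-12))
})

test_that("moderation agrees with the reference empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(5)
  em <- random_expression(300, 3, seed = 5)
  # heterogeneous variances so the prior df estimate is finite
  em$values <- em$values * matrix(rep(sqrt(0.02 * 4 / rchisq(300, 4)), 6),
                                  ncol = 6)
  gls <- fit_group_contrast(em, "FSK", "CT")
  ms <- empirical_bayes_moderate(gls)

  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(attr(ms, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(ms, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(ms$t_mod), unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(ms$p_raw), unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("DEG calling applies the step-up adjustment and alpha", {
  gls <- data.frame(gene = letters[1:3], logFC = c(1, -1, 2),
                    s2 = 0.1, df = 4, v = 2 / 3, mean_expr = 8)
  ms <- empirical_bayes_moderate(gls, d0 = 0)
  ms$p_raw <- c(0.01, 0.2, 0.04)
  degs <- call_degs(ms, alpha = 0.05, adjust = "none")
  expect_equal(sort(degs$gene), c("a", "c"))
  ms$p_raw <- rep(1, 3)
  expect_equal(nrow(call_degs(ms, adjust = "none")), 0)

  # BH step-up enumeration oracle on 10 arbitrary p-values
  set.seed(8)
  p <- round(runif(10), 3)
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    adj <- numeric(n); prev <- 1
    for (i in seq_len(n)) {
      rank_i <- n - i + 1
      prev <- min(prev, p[o[i]] * n / rank_i)
      adj[o[i]] <- prev
    }
    adj
  }
  gls <- data.frame(gene = letters[1:10], logFC = 1, s2 = 0.1, df = 4,
                    v = 2 / 3, mean_expr = 8)
  ms <- empirical_bayes_moderate(gls, d0 = 0)
  ms$p_raw <- p
  degs <- call_degs(ms, alpha = 0.999, adjust = "BH", keep_all = TRUE)
  expect_equal(degs$p_adj, bh_oracle(p), tolerance = 1e-12)

  # DEG count is non-decreasing in alpha
  counts <- vapply(c(0.01, 0.05, 0.2, 0.8),
                   function(a) nrow(call_degs(ms, alpha = a, adjust = "none")),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("probe collapse keeps the max |t| probe deterministically", {
  tab <- data.frame(probe = c("p2", "p1", "p3", "p4"),
                    gene = c("A", "A", "B", "C"),
                    t_mod = c(3.0, -1.2, 2, 2), x = 1:4,
                    stringsAsFactors = FALSE)
  out <- collapse_probes(tab)
  expect_equal(out$gene, c("A", "B", "C"))
  expect_equal(out$t_mod, c(3.0, 2, 2))
  expect_equal(out$x[out$gene == "A"], 1)

  # ties on |t| -> lexicographically smallest probe id
  tie <- data.frame(probe = c("pZ", "pA"), gene = "G", t_mod = c(2, -2),
                    keep = c("no", "yes"), stringsAsFactors = FALSE)
  expect_equal(collapse_probes(tie)$keep, "yes")

  # brute-force group-by oracle on a random table
  set.seed(13)
  big <- data.frame(probe = sprintf("p%03d", 1:200),
                    gene = sample(sprintf("g%02d", 1:60), 200, replace = TRUE),
                    t_mod = rnorm(200), stringsAsFactors = FALSE)
  out <- collapse_probes(big)
  oracle <- do.call(rbind, lapply(split(big, big$gene), function(d) {
    d <- d[order(-abs(d$t_mod), d$probe), ]
    d[1, ]
  }))
  oracle <- oracle[order(oracle$gene), ]
  expect_equal(out$t_mod, oracle$t_mod)
  expect_equal(out$gene, oracle$gene)
})
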