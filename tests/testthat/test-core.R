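# Core-signature extraction and comparison statistics.

test_that("venn regions and percentages match the bitmask oracle", {
  ab <- venn_overlap(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(ab$regions[["A&B"]], 5L)
  expect_true(all(ab$pairs$pct_a_in_b == 100))

  dj <- venn_overlap(list(A = letters[1:3], B = letters[4:6]))
  expect_true(all(dj$pairs$pct_a_in_b == 0))
  expect_equal(dj$union_size, 6L)

  set.seed(61)
  pool <- sprintf("g%03d", 1:60)
  sets <- list(A = sample(pool, 25), B = sample(pool, 30),
               C = sample(pool, 15))
  rep <- venn_overlap(sets)
  u <- unique(unlist(sets))
  mask <- sapply(sets, function(s) u %in% s)
  oracle <- table(apply(mask, 1, function(r)
    paste(names(sets)[r], collapse = "&")))
  expect_equal(sum(rep$regions), length(u))
  for (nm in names(oracle))
    expect_equal(rep$regions[[nm]], as.integer(oracle[[nm]]))
  for (i in seq_len(nrow(rep$pairs))) {
    a <- rep$pairs$a[i]; b <- rep$pairs$b[i]
    expect_equal(rep$pairs$intersection[i],
                 length(intersect(sets[[a]], sets[[b]])))
    expect_equal(rep$pairs$pct_a_in_b[i],
                 100 * length(intersect(sets[[a]], sets[[b]])) /
                   length(sets[[a]]), tolerance = 1e-12)
  }
})

test_that("logFC correlation equals the covariance formula", {
  a <- make_degs(letters[1:5], c(1, 2, -1, 0.5, 3))
  b <- a; b$logFC <- -a$logFC; b$direction <- ifelse(b$logFC > 0, "UP", "DOWN")
  expect_equal(pearson_logfc(a, a), 1)
  expect_equal(pearson_logfc(a, b), -1)

  set.seed(62)
  x <- make_degs(sprintf("g%02d", 1:40), rnorm(40))
  y <- make_degs(sprintf("g%02d", 1:40), rnorm(40))
  r <- pearson_logfc(x, y)
  cx <- x$logFC - mean(x$logFC); cy <- y$logFC - mean(y$logFC)
  expect_equal(r, sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)),
               tolerance = 1e-12)

  const <- make_degs(letters[1:4], rep(1, 4))
  expect_error(pearson_logfc(const, const), "zero variance")
  expect_error(pearson_logfc(a[1:2, ], a[1:2, ]), ">= 3")
})

test_that("core extraction mirrors the shared / UP-in-all / registry cascade", {
  degs <- list(
    FSK = make_degs(c("core1", "half", "dn"), c(2, 1, -1)),
    NE = make_degs(c("core1", "half", "dn"), c(1, 1, -1)),
    VP16 = make_degs(c("core1", "dn"), c(3, -2)))
  q1 <- c("core1", "half", "dn")
  sig <- extract_core(degs, q1, registry = "core1")
  expect_equal(sig$gene, "core1")
  expect_true(sig$in_registry && sig$q1_trap)
  expect_equal(sig$avg_fc, 2)
  counts <- attr(sig, "counts")
  expect_equal(unname(counts["n_shared"]), 2L)   # core1 and dn
  expect_equal(unname(counts["n_up_in_all"]), 1L)
  expect_equal(unname(counts["n_in_registry"]), 1L)

  # gene UP in only 2 of 3 conditions is excluded ("half" not in VP16)
  expect_false("half" %in% sig$gene)

  # supplying the tables in any order gives the same signature
  sig2 <- extract_core(degs[c(3, 1, 2)], q1, "core1")
  expect_equal(sig2$gene, sig$gene)
  expect_equal(attr(sig2, "counts"), counts)

  # set-algebra oracle on a random study
  set.seed(63)
  pool <- sprintf("g%03d", 1:80)
  mk <- function() {
    g <- sample(pool, 50)
    make_degs(g, rnorm(50))
  }
  tabs <- list(A = mk(), B = mk(), C = mk())
  q1 <- sample(pool, 40); reg <- sample(pool, 25)
  sig <- extract_core(tabs, q1, reg)
  shared_o <- Reduce(intersect, lapply(tabs, function(d)
    intersect(d$gene, q1)))
  up_o <- Reduce(intersect, lapply(tabs, function(d)
    d$gene[d$direction == "UP"]))
  up_o <- intersect(shared_o, up_o)
  expect_setequal(sig$gene, up_o)
  expect_equal(unname(attr(sig, "counts")),
               c(length(shared_o), length(up_o),
                 length(intersect(up_o, reg))))
  expect_true(all(diff(sig$avg_fc) <= 0))
  expect_true(all(sig$avg_fc > 0))

  # core size non-increasing as conditions are added
  sig2 <- extract_core(tabs[1:2], q1, reg)
  expect_gte(nrow(sig2), nrow(sig))
})

test_that("cell-type comparison reports shared genes and categories", {
  mk_sig <- function(genes, reg) {
    degs <- list(A = make_degs(genes, seq_along(genes)),
                 B = make_degs(genes, seq_along(genes)))
    extract_core(degs, genes, reg)
  }
  s1 <- mk_sig(c("x", "y", "z"), c("x", "y", "z"))
  cmp <- compare_cell_signatures(s1, s1)
  expect_setequal(cmp$shared, c("x", "y", "z"))

  s2 <- mk_sig(c("p", "q"), c("p", "q"))
  expect_length(compare_cell_signatures(s1, s2)$shared, 0)

  cats <- data.frame(gene = c("x", "y"), category = c("Signalling", "Vesicles"))
  cmp <- compare_cell_signatures(s1, s1, categories = cats)
  pct <- cmp$category_pct$a
  expect_equal(unname(pct[["unassigned"]]), 100 / 3, tolerance = 1e-12)
})

test_that("curated function screen joins membership correctly", {
  degs <- list(FSK = make_degs(c("a", "b"), c(1, 2)),
               NE = make_degs(c("a", "c"), c(1, 1)))
  out <- curated_function_screen(degs, list(
    gliotransmission = c("a", "b", "zzz"), none = c("q1", "q2")))
  expect_false("none" %in% out$func)
  expect_true(out$core[out$gene == "a"])
  expect_false(out$core[out$gene == "b"])
  expect_false("zzz" %in% out$gene)
})
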