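# TRAP quartiles, filtration, ranking, binning, symbol mapping.

test_that("first-quartile construction uses ceil(G/4) with symbol ties", {
  trap <- trap_list(letters[1:8], 8:1)
  expect_equal(build_q1(trap), c("a", "b"))
  trap9 <- trap_list(letters[1:9], 9:1)
  expect_equal(build_q1(trap9), c("a", "b", "c"))     # ceil(9/4) = 3

  set.seed(4)
  genes <- sprintf("g%04d", 1:1000)
  ab <- sample(round(runif(1000, 0, 50), 1))           # includes ties
  trap <- trap_list(genes, ab)
  oracle <- genes[order(-ab, genes)][1:ceiling(1000 / 4)]
  expect_equal(build_q1(trap), oracle)
  # invariant to input row order
  perm <- sample(1000)
  expect_equal(build_q1(trap_list(genes[perm], ab[perm])), oracle)
  expect_equal(length(build_q1(trap)), ceiling(1000 / 4))
})

test_that("TRAP profile averaging is a per-gene mean over present lists", {
  t1 <- trap_list(c("a", "b", "c"), c(3, 2, 1))
  expect_equal(average_trap_profiles(list(t1, t1))$abundance, t1$abundance)

  t2 <- trap_list(c("a", "b", "d"), c(5, 4, 7))
  avg <- average_trap_profiles(list(t1, t2))
  expect_equal(avg$abundance[avg$gene == "a"], 4)       # (3+5)/2
  expect_equal(avg$abundance[avg$gene == "c"], 1)       # only in t1
  expect_equal(avg$abundance[avg$gene == "d"], 7)       # only in t2

  set.seed(6)
  traps <- lapply(1:3, function(i)
    trap_list(sample(sprintf("g%02d", 1:40), 25), runif(25, 1, 9)))
  avg <- average_trap_profiles(traps)
  for (g in avg$gene) {
    vals <- unlist(lapply(traps, function(t) t$abundance[t$gene == g]))
    expect_equal(avg$abundance[avg$gene == g], mean(vals), tolerance = 1e-12)
  }
  expect_error(average_trap_profiles(list(t1)), "at least 2")
})

test_that("filtration is an exact partition", {
  degs <- make_degs(letters[1:6], c(1, -1, 2, -2, 3, -3))
  parts <- filter_by_set(degs, letters[1:6])
  expect_equal(nrow(parts$rest), 0)
  parts <- filter_by_set(degs, character(0))
  expect_equal(nrow(parts$kept), 0)

  keep <- c("a", "d", "f")
  parts <- filter_by_set(degs, keep)
  expect_setequal(parts$kept$gene, keep)
  expect_setequal(c(parts$kept$gene, parts$rest$gene), degs$gene)
  expect_length(intersect(parts$kept$gene, parts$rest$gene), 0)
})

test_that("transcriptome ranking orders UP desc then DOWN asc by t", {
  degs <- make_degs(c("w", "x", "y", "z"), c(1, 1, -1, -1),
                    t_mod = c(3, 1, -2, -4))
  rk <- rank_transcriptome(degs)
  expect_equal(rk$t_mod, c(3, 1, -2, -4))
  expect_equal(rk$section, c("UP", "UP", "DOWN", "DOWN"))

  all_up <- make_degs(c("a", "b"), c(1, 2), t_mod = c(1, 2))
  expect_true(all(rank_transcriptome(all_up)$section == "UP"))

  set.seed(10)
  degs <- make_degs(sprintf("g%03d", 1:120), rnorm(120),
                    t_mod = round(rnorm(120), 1))  # rounded -> ties
  rk <- rank_transcriptome(degs)
  up <- degs[degs$logFC > 0, ]; dn <- degs[degs$logFC <= 0, ]
  oracle <- c(up$gene[order(-up$t_mod, up$gene)],
              dn$gene[order(-dn$t_mod, dn$gene)])
  expect_equal(rk$gene, oracle)
})

test_that("bin profile partitions with a retained remainder bin", {
  degs <- make_degs(sprintf("g%03d", 1:510), runif(510, 0.1, 2),
                    t_mod = seq(510, 1))
  rk <- rank_transcriptome(degs)
  bp <- bin_profile(rk, 250, q1 = degs$gene[1:100])
  expect_equal(bp$n, c(250, 250, 10))
  expect_equal(sum(bp$n), 510)
  expect_equal(sum(bp$q1_count), 100)

  genes <- attr(bp, "bin_genes")
  for (i in seq_len(nrow(bp))) {
    chunk <- rk[rk$gene %in% genes[[i]], ]
    expect_equal(bp$median_logFC[i], median(chunk$logFC), tolerance = 1e-12)
    expect_equal(bp$median_p_adj[i], median(chunk$p_adj), tolerance = 1e-12)
  }
  expect_length(unlist(genes), 510)
  expect_false(anyDuplicated(unlist(genes)) > 0)

  expect_warning(bin_profile(rk[1:5, ], 250), "single bin")
  expect_error(bin_profile(rk, 1), "bin_size")
})

test_that("symbol mapping drops unmapped and resolves collisions", {
  degs <- make_degs(c("ra", "rb", "rc"), c(1, 2, 3), t_mod = c(1, 5, 3))
  ident <- data.frame(from = c("ra", "rb", "rc"), to = c("ra", "rb", "rc"))
  expect_equal(map_symbols(degs, ident)$gene, degs$gene)

  empty <- data.frame(from = character(0), to = character(0))
  expect_equal(nrow(suppressMessages(map_symbols(degs, empty))), 0)

  # many-to-one: keep max |t_mod|
  m21 <- data.frame(from = c("ra", "rb", "rc"), to = c("MA", "MA", "MC"))
  out <- suppressMessages(map_symbols(degs, m21))
  expect_equal(out$t_mod[out$gene == "MA"], 5)

  set.seed(3)
  genes <- sprintf("r%02d", 1:50)
  degs <- make_degs(genes, runif(50, 0.1, 1), t_mod = rnorm(50))
  mapping <- data.frame(from = sample(genes, 30),
                        to = sample(sprintf("m%02d", 1:20), 30, replace = TRUE))
  out <- suppressMessages(map_symbols(degs, mapping))
  # dictionary-join oracle
  joined <- merge(degs, mapping, by.x = "gene", by.y = "from")
  oracle <- do.call(rbind, lapply(split(joined, joined$to), function(d) {
    d[order(-abs(d$t_mod), d$gene), ][1, ]
  }))
  expect_setequal(out$gene, oracle$to)
  expect_equal(sort(out$t_mod), sort(oracle$t_mod))
})
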