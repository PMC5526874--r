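# Domain types and file round trips.

test_that("expression reader validates shape, duplicates and bad cells", {
  dir <- withr::local_tempdir()
  expr_path <- file.path(dir, "expr.tsv")
  cond_path <- file.path(dir, "cond.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "GA\t1\t2\t3\t4", "GB\t5\t6\t7\t8", "GC\t1\t1\t2\t2"),
             expr_path)
  writeLines(c("sample\tcondition", "s1\tCT", "s2\tCT", "s3\tFSK", "s4\tFSK"),
             cond_path)
  em <- read_expression(expr_path, cond_path)
  expect_equal(dim(em), c(3L, 4L))
  expect_equal(unname(em$conditions), c("CT", "CT", "FSK", "FSK"))

  writeLines(c("gene\ts1\ts2\ts3\ts4", "GA\t1\t2\t3\t4", "GA\t5\t6\t7\t8",
               "GC\t1\t1\t2\t2"), expr_path)
  expect_error(read_expression(expr_path, cond_path), "GA")

  writeLines(c("gene\ts1\ts2\ts3\ts4", "GA\t1\t2\tx\t4", "GC\t1\t1\t2\t2"),
             expr_path)
  expect_error(read_expression(expr_path, cond_path), "GA.*s3")

  writeLines(c("gene\ts1\ts2\ts3\ts4", "GA\t1\t2\t3\t4", "GC\t1\t1\t2\t2"),
             expr_path)
  writeLines(c("sample\tcondition", "s1\tCT", "s2\tCT", "s3\tFSK",
               "s4\tFSK", "s9\tFSK"), cond_path)
  expect_error(read_expression(expr_path, cond_path), "s9")
})

test_that("expression write/read round trip is lossless to 1e-12", {
  dir <- withr::local_tempdir()
  set.seed(42)
  em <- random_expression(50, 3, seed = 42)
  write_expression(em, file.path(dir, "e.tsv"), file.path(dir, "c.tsv"))
  back <- read_expression(file.path(dir, "e.tsv"), file.path(dir, "c.tsv"))
  expect_equal(back$values, em$values, tolerance = 1e-12)
  expect_equal(back$conditions, em$conditions)
})

test_that("GMT parsing deduplicates, rejects short lines, round trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.gmt")
  writeLines("S1\tdesc\ta\tb\tb", path)
  gsc <- read_gmt(path)
  expect_setequal(gsc$sets$S1, c("a", "b"))

  writeLines(c("S1\tdesc\ta", "S2\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2")

  file.create(file.path(dir, "empty.gmt"))
  expect_length(read_gmt(file.path(dir, "empty.gmt")), 0L)

  set.seed(7)
  sets <- lapply(1:100, function(i)
    sprintf("g%03d", sample(500, sample(3:30, 1))))
  names(sets) <- sprintf("SET%03d", 1:100)
  gsc <- gene_set_collection(sets, sprintf("d%d", 1:100))
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_identical(back$sets, gsc$sets)
  expect_identical(unname(back$descriptions), unname(gsc$descriptions))
})

test_that("RNK and TRAP tables round trip and order deterministically", {
  dir <- withr::local_tempdir()
  rnk <- data.frame(gene = c("b", "a", "c"), score = c(2, 2, -1))
  write_rnk(rnk, file.path(dir, "x.rnk"))
  back <- read_rnk(file.path(dir, "x.rnk"))
  expect_equal(back$gene, c("a", "b", "c"))  # tie at 2 broken by symbol

  trap <- trap_list(c("x", "y", "z"), c(3, 9, 3))
  expect_equal(trap$gene, c("y", "x", "z"))
  expect_equal(trap$rank, 1:3)
  write_trap(trap, file.path(dir, "t.tsv"))
  expect_equal(read_trap(file.path(dir, "t.tsv")), trap)
})

test_that("PWM parsers agree across formats and reject malformed input", {
  dir <- withr::local_tempdir()
  counts <- matrix(c(1, 2, 3, 4,
                     8, 1, 1, 1,
                     0, 9, 0, 2,
                     2, 2, 5, 3), nrow = 4, byrow = TRUE) # A,C,G,T x 4...
  counts <- cbind(counts, counts)                          # width 8
  jaspar <- file.path(dir, "m.jaspar")
  writeLines(c(">M1 CRE",
               sprintf("A [ %s ]", paste(counts[1, ], collapse = " ")),
               sprintf("C [ %s ]", paste(counts[2, ], collapse = " ")),
               sprintf("G [ %s ]", paste(counts[3, ], collapse = " ")),
               sprintf("T [ %s ]", paste(counts[4, ], collapse = " "))),
             jaspar)
  pj <- read_pwm(jaspar, "jaspar")
  expect_equal(pj$width, 8L)
  expect_equal(unname(pj$counts), counts)

  transfac <- file.path(dir, "m.transfac")
  writeLines(c("ID M1", "P0  A  C  G  T",
               sprintf("%02d  %d  %d  %d  %d", 1:8, counts[1, ], counts[2, ],
                       counts[3, ], counts[4, ]),
               "XX", "//"), transfac)
  pt <- read_pwm(transfac, "transfac")
  expect_equal(pt$counts, pj$counts)
  expect_equal(pt$lo, pj$lo)

  writeLines(c(">M2", "A [ ]", "C [ ]", "G [ ]", "T [ ]"), jaspar)
  expect_error(read_pwm(jaspar, "jaspar"))
  expect_error(pwm_matrix(matrix(-1, 4, 6)), "non-negative")
})

test_that("constructors enforce their invariants", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(m, c(s1 = "CT")), "s2")
  m2 <- m; m2[1, 1] <- Inf
  expect_error(expression_matrix(m2, c(s1 = "CT", s2 = "CT")), "finite")
  expect_error(gene_set_collection(list(S1 = character(0))), "empty")
  expect_error(trap_list(c("a", "a"), c(1, 2)), "duplicate")
  expect_error(run_config(alpha = 1.5), "alpha")
  expect_error(run_config(bin_size = 1), "bin_size")
  expect_error(run_config(gsea_n_perm = 10), "gsea_n_perm")
  cfg <- run_config(seed = 5)
  expect_identical(cfg$seed, 5L)
})

test_that("rerunning the simulator with one seed is byte-identical", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- small_cfg(seed = 9)
  write_study(simulate_study(cfg), dir1)
  write_study(simulate_study(cfg), dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
})
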