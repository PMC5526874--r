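# Synthetic-study generator: plants a known regulon (core genes UP in every
# stimulus, carrying a CRE motif, enriched in the TRAP first quartile and
# listed in the registry) so that every pipeline stage has recoverable
# ground truth. Writes the same formats the pipeline reads.

#' Configuration of a synthetic study
#'
#' Defaults state the emulated world: a 5000-gene transcriptome with a
#' 100-gene planted regulon, per-stimulus specific UP and DOWN genes,
#' a 1 log2-unit effect size over replicate noise of 0.25, three replicates
#' per condition, 500-nt promoters at 50 percent GC, strong (0.9) first-
#' quartile TRAP enrichment of the regulon and a 5 percent registry
#' false-positive rate.
#'
#' @param n_genes Transcriptome size.
#' @param n_core Planted regulon size (UP in all stimuli).
#' @param n_specific Per-stimulus specific UP genes.
#' @param n_down Per-stimulus DOWN genes.
#' @param delta Effect size, log2 units.
#' @param sigma Replicate noise standard deviation, log2 units.
#' @param n_reps Replicates per condition (>= 2).
#' @param promoter_len Promoter length, nt.
#' @param gc Background GC fraction.
#' @param q1_enrich Probability a core gene falls in the TRAP first quartile.
#' @param registry_fpr Fraction of non-core genes included in the registry.
#' @param decoy_rate Fraction of non-core genes that also receive a planted
#'   motif (decoys; default 0).
#' @param invivo_shift Score shift of core genes in the simulated in-vivo
#'   ranking (standard-normal null).
#' @param stimuli Stimulus labels; each is contrasted against its control
#'   (`VP16` vs `Null`, others vs `CT`).
#' @param seed Mandatory master seed.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 5000, n_core = 100, n_specific = 200,
                              n_down = 200, delta = 1, sigma = 0.25,
                              n_reps = 3, promoter_len = 500, gc = 0.5,
                              q1_enrich = 0.9, registry_fpr = 0.05,
                              decoy_rate = 0, invivo_shift = 2,
                              stimuli = c("FSK", "NE", "VP16"), seed) {
  seed <- require_seed(seed)
  assert_that(is_count(n_genes, 10L), "n_genes must be >= 10")
  assert_that(is_count(n_core, 0L) && is_count(n_specific, 0L) &&
                is_count(n_down, 0L), "gene counts must be integers")
  assert_that(n_core + length(stimuli) * (n_specific + n_down) <= n_genes,
              "planted genes exceed n_genes")
  assert_that(delta >= 0, "delta must be non-negative")
  assert_that(sigma > 0, "sigma must be positive")
  assert_that(is_count(n_reps, 1L), "n_reps must be a positive integer")
  assert_that(is_count(promoter_len, 20L), "promoter_len must be >= 20")
  assert_that(is_prob(gc) && is_prob(q1_enrich) && is_prob(registry_fpr) &&
                is_prob(decoy_rate), "fractions must lie in [0,1]")
  assert_that(length(stimuli) >= 1 && !anyDuplicated(stimuli),
              "stimuli must be distinct labels")
  structure(list(n_genes = as.integer(n_genes), n_core = as.integer(n_core),
                 n_specific = as.integer(n_specific),
                 n_down = as.integer(n_down), delta = delta, sigma = sigma,
                 n_reps = as.integer(n_reps),
                 promoter_len = as.integer(promoter_len), gc = gc,
                 q1_enrich = q1_enrich, registry_fpr = registry_fpr,
                 decoy_rate = decoy_rate, invivo_shift = invivo_shift,
                 stimuli = stimuli, seed = seed),
            class = "SimulationConfig")
}

gene_names <- function(n) sprintf("G%05d", seq_len(n))

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Assign planted-truth labels to genes
#'
#' Randomly assigns each gene one mutually exclusive label: `core`,
#' `specific:<stimulus>`, `down:<stimulus>` or `null`. Motif planting
#' covers the core plus a configurable decoy fraction of non-core genes.
#'
#' @param cfg A [simulation_config()].
#' @param core_genes Optional forced core genes (exactly `n_core` symbols);
#'   used to plant a shared regulon across cell types.
#' @return A `TruthTable` data frame: gene, label, motif_planted, plus
#'   placeholder trap_q1 and registry_member flags filled by the dedicated
#'   simulators.
#' @export
assign_truth <- function(cfg, core_genes = NULL) {
  genes <- gene_names(cfg$n_genes)
  labels <- rep("null", cfg$n_genes)
  names(labels) <- genes
  with_seed(derive_seed(cfg$seed, 1L), {
    pool <- genes
    if (!is.null(core_genes)) {
      assert_that(length(core_genes) == cfg$n_core &&
                    all(core_genes %in% genes),
                  "core_genes must be n_core known gene symbols")
      core <- core_genes
    } else {
      core <- sample(pool, cfg$n_core)
    }
    labels[core] <- "core"
    pool <- setdiff(pool, core)
    for (st in cfg$stimuli) {
      sp <- sample(pool, cfg$n_specific)
      labels[sp] <- paste0("specific:", st)
      pool <- setdiff(pool, sp)
      dn <- sample(pool, cfg$n_down)
      labels[dn] <- paste0("down:", st)
      pool <- setdiff(pool, dn)
    }
    noncore <- genes[labels != "core"]
    decoys <- noncore[stats::runif(length(noncore)) < cfg$decoy_rate]
    out <- data.frame(gene = genes, label = unname(labels),
                      motif_planted = labels == "core" | genes %in% decoys,
                      trap_q1 = NA, registry_member = NA,
                      stringsAsFactors = FALSE)
    class(out) <- c("TruthTable", class(out))
    out
  })
}

truth_core <- function(truth) truth$gene[truth$label == "core"]

effect_of <- function(truth, stimulus) {
  eff <- numeric(nrow(truth))
  eff[truth$label == "core"] <- 1
  eff[truth$label == paste0("specific:", stimulus)] <- 1
  eff[truth$label == paste0("down:", stimulus)] <- -1
  eff
}

#' Simulate the stimulated expression matrices
#'
#' Per-gene baselines are log2 values of a log-normal abundance (so that
#' abundance-correlated structure like TRAP filtering has signal to work
#' with); each replicate adds Normal(0, sigma) noise, and planted genes are
#' shifted by plus or minus delta in their stimulus conditions (core genes
#' in all stimuli). Controls are `CT` (for transient stimuli) and `Null`
#' (for VP16).
#'
#' @param cfg A [simulation_config()].
#' @param truth Optional [assign_truth()] output (generated when missing).
#' @return List with `expr` (an [expression_matrix()] holding every
#'   condition) and `truth`.
#' @export
simulate_expression <- function(cfg, truth = NULL) {
  if (cfg$n_reps < 2) stopf("n_reps must be >= 2 (variance undefined)")
  if (is.null(truth)) truth <- assign_truth(cfg)
  controls <- unique(ifelse(cfg$stimuli == "VP16", "Null", "CT"))
  conditions <- c(controls, cfg$stimuli)
  with_seed(derive_seed(cfg$seed, 2L), {
    mu <- log2(stats::rlnorm(cfg$n_genes, meanlog = log(300), sdlog = 1.2))
    cols <- list(); labels <- character(0)
    for (cond in conditions) {
      shift <- if (cond %in% cfg$stimuli)
        cfg$delta * effect_of(truth, cond) else 0
      for (r in seq_len(cfg$n_reps)) {
        cols[[length(cols) + 1L]] <-
          mu + shift + stats::rnorm(cfg$n_genes, 0, cfg$sigma)
        labels <- c(labels, cond)
      }
    }
    vals <- do.call(cbind, cols)
    samples <- sprintf("%s_%d", labels, stats::ave(seq_along(labels),
                                                   labels, FUN = seq_along))
    dimnames(vals) <- list(truth$gene, samples)
    list(expr = expression_matrix(vals, stats::setNames(labels, samples)),
         truth = truth)
  })
}

#' Control condition for a stimulus
#' @param stimulus Stimulus label.
#' @return `"Null"` for VP16, `"CT"` otherwise.
#' @export
control_of <- function(stimulus) ifelse(stimulus == "VP16", "Null", "CT")

#' A CRE-like position weight matrix
#'
#' Count matrix concentrated on the palindromic TGACGTCA consensus, used as
#' the default planted motif and scanning matrix.
#'
#' @param strength Count of the consensus base per column (of 100).
#' @return A [pwm_matrix()].
#' @export
cre_pwm <- function(strength = 85) {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  counts <- matrix((100 - strength) / 3, nrow = 4, ncol = 8,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- strength
  pwm_matrix(counts)
}

#' Simulate promoter sequences with planted CRE motifs
#'
#' Background bases are iid at the configured GC fraction; every
#' motif-planted gene receives one motif instance sampled from the PWM's
#' column frequencies, inserted at a uniform random position on a uniform
#' random strand.
#'
#' @param cfg A [simulation_config()].
#' @param truth An [assign_truth()] table.
#' @param pwm Motif to plant (default [cre_pwm()]).
#' @return List with `promoters` (named character vector) and `pwm`.
#' @export
simulate_promoters <- function(cfg, truth, pwm = cre_pwm()) {
  w <- pwm$width
  if (cfg$promoter_len < w + 10)
    stopf("promoter_len must be >= PWM width + 10 (%d)", w + 10)
  base_probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  freq <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(cfg$seed, 3L), {
    seqs <- vapply(seq_len(cfg$n_genes), function(i) {
      paste(sample(bases, cfg$promoter_len, replace = TRUE,
                   prob = base_probs), collapse = "")
    }, character(1))
    for (i in which(truth$motif_planted)) {
      inst <- vapply(seq_len(w), function(j)
        sample(bases, 1, prob = freq[, j]), character(1))
      if (stats::runif(1) < 0.5) {
        inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
      }
      pos <- sample.int(cfg$promoter_len - w + 1L, 1)
      substr(seqs[i], pos, pos + w - 1L) <- paste(inst, collapse = "")
    }
    list(promoters = stats::setNames(seqs, truth$gene), pwm = pwm)
  })
}

#' Simulate a TRAP abundance list
#'
#' Core genes are placed in the first quartile with probability
#' `q1_enrich`; all remaining rank slots are filled uniformly at random.
#' Abundances are descending log-normal values matched to the ranks.
#'
#' @param cfg A [simulation_config()].
#' @param truth An [assign_truth()] table.
#' @return A [trap_list()] over all genes.
#' @export
simulate_trap <- function(cfg, truth) {
  g <- cfg$n_genes
  q1_size <- ceiling(g / 4)
  with_seed(derive_seed(cfg$seed, 4L), {
    core <- truth_core(truth)
    in_q1 <- core[stats::runif(length(core)) < cfg$q1_enrich]
    out_q1 <- setdiff(core, in_q1)          # uniform over the REST slots,
    others <- setdiff(truth$gene, core)     # so P(core in Q1) = q1_enrich
    ranks <- integer(g); names(ranks) <- truth$gene
    q1_slots <- sample(seq_len(q1_size), length(in_q1))
    ranks[in_q1] <- q1_slots
    rest_slots <- sample(seq(q1_size + 1L, g), length(out_q1))
    ranks[out_q1] <- rest_slots
    ranks[others] <- sample(setdiff(seq_len(g), c(q1_slots, rest_slots)))
    abundance <- sort(stats::rlnorm(g, meanlog = log(100), sdlog = 1),
                      decreasing = TRUE)
    trap_list(truth$gene, abundance[ranks])
  })
}

#' Simulate the CRE-target registry
#'
#' All core genes plus each non-core gene with probability `registry_fpr`
#' (the emulated database's false positives).
#'
#' @param cfg A [simulation_config()].
#' @param truth An [assign_truth()] table.
#' @return Character vector of registry gene symbols.
#' @export
simulate_registry <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 5L), {
    noncore <- truth$gene[truth$label != "core"]
    extra <- noncore[stats::runif(length(noncore)) < cfg$registry_fpr]
    sort(c(truth_core(truth), extra))
  })
}

#' Simulate an in-vivo ranked list enriched for the regulon
#'
#' Scores are standard normal for null genes, shifted up by `invivo_shift`
#' for core genes and down by `shift_down` for down-planted genes,
#' emulating an adult-brain ranking correlated with the in-vitro response
#' in both directions (so its top and bottom fractions behave like the
#' UP/DOWN gene sets of the in-vivo comparison).
#'
#' @param cfg A [simulation_config()].
#' @param truth An [assign_truth()] table.
#' @param shift Score shift for core genes (default `cfg$invivo_shift`).
#' @param shift_down Downward score shift for down-planted genes (default
#'   `shift`, i.e. symmetric correlation; 0 restores an uncorrelated DOWN
#'   side).
#' @return Data frame (gene, score) ordered by descending score.
#' @export
simulate_invivo_ranked <- function(cfg, truth, shift = cfg$invivo_shift,
                                   shift_down = shift) {
  with_seed(derive_seed(cfg$seed, 6L), {
    score <- stats::rnorm(cfg$n_genes) +
      ifelse(truth$label == "core", shift,
             ifelse(startsWith(truth$label, "down:"), -shift_down, 0))
    out <- data.frame(gene = truth$gene, score = score,
                      stringsAsFactors = FALSE)
    out[order(-out$score, out$gene), , drop = FALSE]
  })
}

#' Simulate a GO-like term collection
#'
#' Random terms drawn from the transcriptome plus one planted term,
#' `CORE_REGULON`, covering the core genes (with 20 percent extra random
#' members so it is not a trivial mirror of the truth table).
#'
#' @param cfg A [simulation_config()].
#' @param truth An [assign_truth()] table.
#' @param n_terms Number of random terms.
#' @param size_range Term size range.
#' @return A [gene_set_collection()].
#' @export
simulate_go_sets <- function(cfg, truth, n_terms = 40,
                             size_range = c(10, 100)) {
  with_seed(derive_seed(cfg$seed, 7L), {
    sets <- lapply(seq_len(n_terms), function(i) {
      sample(truth$gene, sample(size_range[1]:size_range[2], 1))
    })
    names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    core <- truth_core(truth)
    if (length(core)) {
      extra <- sample(setdiff(truth$gene, core),
                      max(1, round(0.2 * length(core))))
      sets$CORE_REGULON <- c(core, extra)
    }
    gene_set_collection(sets)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every simulator and assembles a drop-in study: expression across
#' all conditions, planted truth (with TRAP and registry flags filled in),
#' TRAP list, registry, promoters with the planted PWM, an in-vivo ranked
#' list and a GO-like term collection.
#'
#' @param cfg A [simulation_config()].
#' @param with_promoters Generate promoter sequences (the slowest part);
#'   disable for expression-only studies.
#' @param core_genes Optional forced core-regulon genes (used for the
#'   two-cell-type study).
#' @return A `SyntheticStudy` list.
#' @export
simulate_study <- function(cfg, with_promoters = TRUE, core_genes = NULL) {
  truth <- assign_truth(cfg, core_genes = core_genes)
  sim <- simulate_expression(cfg, truth)
  trap <- simulate_trap(cfg, truth)
  registry <- simulate_registry(cfg, truth)
  q1 <- build_q1(trap)
  truth$trap_q1 <- truth$gene %in% q1
  truth$registry_member <- truth$gene %in% registry
  prom <- if (with_promoters) simulate_promoters(cfg, truth) else
    list(promoters = NULL, pwm = cre_pwm())
  structure(list(config = cfg, expr = sim$expr, truth = truth, trap = trap,
                 registry = registry, promoters = prom$promoters,
                 pwm = prom$pwm,
                 invivo = simulate_invivo_ranked(cfg, truth),
                 go_sets = simulate_go_sets(cfg, truth)),
            class = "SyntheticStudy")
}

#' Generate a two-cell-type study pair
#'
#' The second cell type (a neuron-like culture stimulated with FSK and
#' VP16 only) re-runs the generator with a planted regulon disjoint from
#' the first except for a configurable overlap (default 2, the two genes
#' shared between cell types in the emulated comparison).
#'
#' @param cfg A [simulation_config()] for cell type A.
#' @param overlap Number of core genes shared between the two regulons.
#' @param stimuli_b Stimuli of cell type B.
#' @param with_promoters Passed through to [simulate_study()].
#' @return List with `a` and `b`, both `SyntheticStudy` objects.
#' @export
simulate_study_pair <- function(cfg, overlap = 2,
                                stimuli_b = c("FSK", "VP16"),
                                with_promoters = FALSE) {
  assert_that(is_count(overlap) && overlap <= cfg$n_core,
              "overlap must be in 0..n_core")
  a <- simulate_study(cfg, with_promoters = with_promoters)
  core_a <- truth_core(a$truth)
  null_a <- a$truth$gene[a$truth$label == "null"]
  assert_that(length(null_a) >= cfg$n_core - overlap,
              "not enough null genes for a disjoint second regulon")
  cfg_b <- cfg
  cfg_b$stimuli <- stimuli_b
  cfg_b$seed <- derive_seed(cfg$seed, 97L)
  cfg_b <- do.call(simulation_config, cfg_b[setdiff(names(cfg_b), NULL)])
  core_b <- with_seed(derive_seed(cfg$seed, 98L), {
    c(sample(core_a, overlap), sample(null_a, cfg$n_core - overlap))
  })
  b <- simulate_study(cfg_b, with_promoters = with_promoters,
                      core_genes = core_b)
  list(a = a, b = b)
}

#' Precision and recall of a called signature against the planted truth
#'
#' @param called A `CoreSignature` (its registry-confirmed genes are used)
#'   or a character vector of called genes.
#' @param truth An [assign_truth()] table.
#' @return List with `precision`, `recall`, `n_called`, `n_core`.
#' @export
recovery_metrics <- function(called, truth) {
  if (inherits(called, "CoreSignature")) called <- signature_genes(called)
  core <- truth_core(truth)
  tp <- length(intersect(called, core))
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(core)) tp / length(core) else NA_real_,
       n_called = length(called), n_core = length(core))
}

#' Run the core-signature pipeline on a study
#'
#' Differential expression per stimulus (moderated t, DEG calling), TRAP
#' first-quartile construction, and multi-condition core extraction against
#' the registry.
#'
#' @param study A `SyntheticStudy` (or any list with the same elements).
#' @param alpha,adjust DEG calling parameters (see [call_degs()]).
#' @param filter_first Passed to [extract_core()].
#' @return List with `degs` (named list of `DEGTable`s), `q1`, and
#'   `signature` (a `CoreSignature`).
#' @export
run_core_pipeline <- function(study, alpha = 0.05, adjust = c("BH", "none"),
                              filter_first = TRUE) {
  adjust <- match.arg(adjust)
  degs <- lapply(stats::setNames(nm = study$config$stimuli), function(st) {
    run_de(study$expr, st, control_of(st), alpha = alpha, adjust = adjust)
  })
  q1 <- build_q1(study$trap)
  sig <- extract_core(degs, q1, study$registry, filter_first = filter_first)
  list(degs = degs, q1 = q1, signature = sig)
}

#' Write a synthetic study to a directory
#'
#' Emits the same plain-text formats the pipeline reads, so the output
#' directory is a drop-in study: expression and condition TSVs, truth TSV,
#' TRAP TSV, registry gene list, promoter FASTA, JASPAR PWM, in-vivo RNK,
#' GO-like GMT and a JSON config record.
#'
#' @param study A `SyntheticStudy`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(study$expr, p("expression.tsv"), p("conditions.tsv"))
  utils::write.table(study$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_trap(study$trap, p("trap.tsv"))
  writeLines(study$registry, p("registry.txt"))
  if (!is.null(study$promoters))
    write_promoters(study$promoters, p("promoters.fa"))
  write_pwm(study$pwm, p("pwm.jaspar"), name = "CRE_synthetic")
  write_rnk(study$invivo, p("invivo.rnk"))
  write_gmt(study$go_sets, p("go_sets.gmt"))
  cfg <- study$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "stimuli")], p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("expression.tsv", "conditions.tsv", "truth.tsv", "trap.tsv",
             "registry.txt", "pwm.jaspar", "invivo.rnk", "go_sets.gmt",
             "config.json")
  if (!is.null(study$promoters)) files <- c(files, "promoters.fa")
  invisible(stats::setNames(file.path(dir, files), files))
}
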