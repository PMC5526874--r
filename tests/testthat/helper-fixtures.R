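# Shared fixtures, built in code at test time.

toy_expression <- function() {
  vals <- matrix(c(1, 1, 1, 2, 2, 2,
                   5, 5, 5, 5, 5, 5,
                   3, 4, 5, 6, 7, 8),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("GA", "GB", "GC"),
                                 c("ct1", "ct2", "ct3", "tr1", "tr2", "tr3")))
  expression_matrix(vals, c(ct1 = "CT", ct2 = "CT", ct3 = "CT",
                            tr1 = "FSK", tr2 = "FSK", tr3 = "FSK"))
}

random_expression <- function(n_genes, n_per_group, seed,
                              conditions = c("CT", "FSK")) {
  set.seed(seed)
  n <- n_per_group * length(conditions)
  vals <- matrix(rnorm(n_genes * n, mean = 8, sd = 1), nrow = n_genes,
                 dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n))))
  labs <- rep(conditions, each = n_per_group)
  expression_matrix(vals, setNames(labs, colnames(vals)))
}

# Minimal valid DEG table from explicit vectors.
make_degs <- function(gene, logFC, t_mod = logFC * 3, p_raw = NULL,
                      p_adj = NULL) {
  if (is.null(p_raw)) p_raw <- pmin(1, 2 * pnorm(-abs(t_mod)))
  if (is.null(p_adj)) p_adj <- pmin(1, p_raw * 2)
  validate_deg_table(data.frame(
    gene = gene, logFC = logFC, t_mod = t_mod, p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(logFC > 0, "UP", "DOWN"),
    mean_expr = rep(8, length(gene)), stringsAsFactors = FALSE))
}

small_cfg <- function(seed, promoter_len = 200, ...) {
  simulation_config(n_genes = 400, n_core = 30, n_specific = 40, n_down = 40,
                    promoter_len = promoter_len, seed = seed, ...)
}

# Asymmetric PWM whose worst-scoring sequence is strand-invariant: in every
# column the minimal bases are the complement pair A/T.
at_min_pwm <- function(width = 6) {
  counts <- matrix(rep(c(5, 45, 45, 5), width), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_matrix(counts)
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent window-enumeration oracle for the best PWM site: recomputes
# frequencies and log-odds from the counts, scores every window on both
# strands by explicit looping.
best_score_oracle <- function(pwm, seq) {
  counts <- pwm$counts
  pc <- 0.01 * colSums(counts)
  freq <- sweep(sweep(counts, 2, pc, "+"), 2,
                colSums(counts) + 4 * pc, "/")
  lo <- log2(freq / 0.25)
  w <- ncol(counts)
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_len(w), function(j) {
      if (ch[j] %in% rownames(lo)) lo[ch[j], j] else 0
    }, numeric(1)))
  }
  best <- -Inf
  for (strand_seq in c(seq, revcomp_chr(seq))) {
    for (s in 1:(nchar(strand_seq) - w + 1)) {
      best <- max(best, score_one(substr(strand_seq, s, s + w - 1)))
    }
  }
  lo_min <- sum(apply(lo, 2, min)); lo_max <- sum(apply(lo, 2, max))
  (best - lo_min) / (lo_max - lo_min)
}

# Step-by-step running-sum GSEA oracle.
es_oracle <- function(genes, scores, gene_set, w = 1) {
  n <- length(genes)
  hits <- genes %in% gene_set
  denom <- sum(abs(scores[hits])^w)
  running <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hits[i]) cur + abs(scores[i])^w / denom else
      cur - 1 / (n - sum(hits))
    running[i] <- cur
  }
  # same tie rule as the implementation: positive deviation wins a tie
  if (max(running) >= -min(running) - 1e-12) max(running) else min(running)
}

# Exact hypergeometric two-sided p by enumerating the support with choose().
hyper_oracle <- function(k, K, n, N) {
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  upper <- sum(pmf[support >= k])
  lower <- sum(pmf[support <= k])
  min(1, 2 * min(upper, lower))
}
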