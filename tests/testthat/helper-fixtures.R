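# Shared fixtures and small independent oracles. Heavy synthetic objects are
# built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Desk-scale single-cell config: enough genes that QC retains most cells.
small_sc_config <- function(seed = 11) {
  synth_config(
    seed = seed, cells_per_patient = 40L, n_genes = 1200L,
    cnv_segments = data.frame(chromosome = c("7", "10"),
                              start_gene_index = c(1L, 1L),
                              n_genes = c(30L, 30L),
                              copy_ratio = c(1.5, 0.5)))
}

small_sc <- function() cached("small_sc", gen_single_cell(small_sc_config()))

small_sc_lognorm <- function() {
  cached("small_sc_lognorm", {
    sc <- small_sc()
    qc <- qc_filter(sc$matrix, sc$annotation)
    ln <- normalize_lognorm(qc$matrix)
    cells <- sc$cells[match(ln$cell_ids, sc$cells$cell_id), ]
    list(lognorm = ln, cells = cells, sc = sc)
  })
}

# A lognorm-layer ExpressionMatrix built directly from a dense value matrix.
lognorm_matrix <- function(values) {
  expression_matrix(pmax(values, 0), layer = "lognorm")
}

# Independent oracle: two-sided permutation p-value of the rank-sum
# statistic by full enumeration (recomputes ranks from scratch).
perm_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combos <- combn(length(pooled), n1)
  mean(apply(combos, 2, function(idx) abs(sum(r[idx]) - mu) >= obs - 1e-9))
}

# Independent oracle: AUC by brute-force pairwise concordance counting.
pairwise_auc <- function(scores, labels, positive = "NPD") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / (0.5 * (sum_a + sum_b) - expected)
}

# Serialize the pieces of a pipeline result that must be bit-stable.
pipeline_digest <- function(res) {
  list(markers = lapply(res$markers, function(m) m[order(m$gene), ]),
       signatures = lapply(res$signatures, function(s) s$genes),
       cnv_score = res$cnv$score,
       grid = res$grid$summary,
       selected = c(res$grid$selected$algorithm, res$grid$selected$gene_set),
       scores = res$predictions$score,
       risk = res$risk,
       logrank_p = if (is.null(res$logrank)) NA_real_ else res$logrank$p_value)
}
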