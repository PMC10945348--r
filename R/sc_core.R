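# Single-cell core: QC filtering, log-normalization, graph clustering,
# marker derivation and per-patient composition tables.

#' Quality-control filter for a raw count matrix
#'
#' Removes cells with fewer than `min_genes` or more than `max_genes`
#' detected genes, cells whose mitochondrial count fraction exceeds
#' `max_mito`, and (afterwards) genes detected in fewer than
#' `min_cells_per_gene` of the retained cells.
#'
#' @param matrix An [expression_matrix()] with `layer = "counts"`.
#' @param annotation Gene annotation with an `is_mito` column (see
#'   [gene_annotation()]); genes missing from the annotation are treated as
#'   non-mitochondrial with a warning.
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito Maximum mitochondrial count fraction (cells strictly above
#'   are removed).
#' @param min_cells_per_gene Minimum number of cells (with >= 1 count) a gene
#'   must appear in.
#' @return List with `matrix` (filtered), `cells` (`data.frame` of per-cell
#'   QC stats for the retained cells: `cell_id`, `n_genes_detected`,
#'   `pct_mito`), and `report` (named counts removed per rule).
#' @export
qc_filter <- function(matrix, annotation, min_genes = 200, max_genes = 6000,
                      max_mito = 0.10, min_cells_per_gene = 3) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "counts") stop("qc_filter expects the raw counts layer")
  m <- matrix$counts
  missing_ann <- setdiff(matrix$gene_ids, annotation$gene_id)
  if (length(missing_ann)) {
    warning(sprintf("%d gene(s) missing from annotation treated as non-mitochondrial",
                    length(missing_ann)))
  }
  is_mito <- matrix$gene_ids %in% annotation$gene_id[annotation$is_mito]
  n_detected <- Matrix::colSums(m > 0)
  totals <- Matrix::colSums(m)
  pct_mito <- ifelse(totals > 0, Matrix::colSums(m[is_mito, , drop = FALSE]) / totals, 0)
  low <- n_detected < min_genes
  high <- n_detected > max_genes
  mito_bad <- !low & !high & pct_mito > max_mito
  keep_cells <- !(low | high | mito_bad)
  if (!any(keep_cells)) stop("qc_filter removed every cell")
  m2 <- m[, keep_cells, drop = FALSE]
  gene_support <- Matrix::rowSums(m2 > 0)
  keep_genes <- gene_support >= min_cells_per_gene
  if (!any(keep_genes)) stop("qc_filter removed every gene")
  report <- c(cells_low_genes = sum(low), cells_high_genes = sum(high),
              cells_high_mito = sum(mito_bad),
              genes_low_support = sum(!keep_genes))
  out <- expression_matrix(m2[keep_genes, , drop = FALSE], layer = "counts")
  cells <- data.frame(cell_id = matrix$cell_ids[keep_cells],
                      n_genes_detected = as.integer(n_detected[keep_cells]),
                      pct_mito = as.numeric(pct_mito[keep_cells]),
                      stringsAsFactors = FALSE)
  list(matrix = out, cells = cells, report = report)
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a total of 10,000 and natural-log
#' transformed: `x -> ln(1 + 1e4 * x / total)`.
#'
#' @param matrix An [expression_matrix()] with `layer = "counts"`.
#' @param scale_factor Target per-cell total before `log1p` (default 1e4).
#' @return An `ExpressionMatrix` with `layer = "lognorm"`.
#' @export
normalize_lognorm <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "counts") stop("normalize_lognorm expects the counts layer")
  m <- matrix$counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) stop("cell(s) with zero total counts; run qc_filter first")
  percell <- rep.int(totals, diff(m@p))
  m@x <- log1p(scale_factor * m@x / percell)
  expression_matrix(m, layer = "lognorm")
}

# Highly-variable gene selection: genes are binned by mean expression and
# ranked by the within-bin z-score of their log variance (a simple
# variance-stabilized dispersion).
select_hvg <- function(m, n_hvg = 2000, n_bins = 20) {
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowMeans(m^2) - mu^2
  ok <- which(v > 0)
  if (!length(ok)) return(integer(0))
  bins <- cut(rank(mu[ok], ties.method = "first"),
              breaks = min(n_bins, length(ok)), labels = FALSE)
  lv <- log(v[ok])
  z <- rep(0, length(ok))
  for (b in unique(bins)) {
    i <- which(bins == b)
    s <- stats::sd(lv[i])
    if (!is.na(s) && s > 0) z[i] <- (lv[i] - mean(lv[i])) / s
  }
  ok[head(order(z, decreasing = TRUE), min(n_hvg, length(ok)))]
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Selects highly variable genes, z-scales them, reduces to the top
#' `n_pcs` principal components, builds a k-nearest-neighbor graph with
#' Jaccard shared-neighbor edge weights, and extracts modularity-optimizing
#' (Louvain) communities. Deterministic under the supplied seed.
#'
#' @param matrix An [expression_matrix()] with `layer = "lognorm"`.
#' @param n_pcs Number of principal components (default 30; must be smaller
#'   than both matrix dimensions).
#' @param n_hvg Number of highly variable genes to use (default 2000).
#' @param resolution Louvain resolution parameter (default 1).
#' @param k Neighbors for the SNN graph (default 20, capped at n cells - 1).
#' @param prune Minimum Jaccard overlap kept as an edge (default 1/15).
#' @param seed Seed for the community detection (default 0).
#' @return Integer cluster labels (1-based) named by cell id.
#' @export
cluster_cells <- function(matrix, n_pcs = 30, n_hvg = 2000, resolution = 1,
                          k = 20, prune = 1 / 15, seed = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "lognorm") stop("cluster_cells expects the lognorm layer")
  n_cells <- length(matrix$cell_ids)
  if (n_cells < 2) stop("need at least 2 cells")
  m <- matrix$counts
  hvg <- select_hvg(m, n_hvg = n_hvg)
  if (!length(hvg)) hvg <- seq_len(nrow(m))  # all-constant input
  x <- t(as.matrix(m[hvg, , drop = FALSE]))  # cells x genes
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- scale(x, center = mu, scale = sdv)
  x[x > 10] <- 10
  if (n_pcs >= min(dim(x)) || n_pcs >= n_cells) {
    stop("n_pcs must be smaller than the number of cells and of variable genes")
  }
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  k <- min(k, n_cells - 1)
  d <- as.matrix(stats::dist(pcs))
  nn <- apply(d, 1, function(row) order(row)[2:(k + 1)])  # k x n, excludes self
  nn <- t(nn)
  # Shared-neighbor Jaccard weights over the union of directed kNN edges.
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n_cells), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n_cells, n_cells))
  shared <- Matrix::tcrossprod(adj)
  edges <- Matrix::which(shared > 0, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  sh <- shared[edges]
  jac <- sh / (2 * k - sh)
  keep <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[keep, 1], to = edges[keep, 2], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_cells)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)[as.character(seq_len(n_cells))]
  stats::setNames(as.integer(labels), matrix$cell_ids)
}

#' Marker genes of one cluster versus all remaining cells
#'
#' Per gene, a two-sided Wilcoxon rank-sum test (exact enumeration when both
#' groups have <= 8 cells, tie-corrected normal approximation otherwise)
#' compares log-normalized expression in the target cluster against all
#' other cells. The fold change is computed on de-logged means with a +1
#' pseudocount: `log_fc = ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`
#' (natural log). Rows are kept when `log_fc > min_logfc` and
#' `p < max_p`; a Benjamini-Hochberg adjusted column is reported but not
#' used for filtering.
#'
#' @param matrix An [expression_matrix()] with `layer = "lognorm"`.
#' @param labels Cluster/subgroup label per cell (aligned with
#'   `matrix$cell_ids`).
#' @param cluster The label whose markers are sought.
#' @param min_logfc Natural-log fold-change floor (default 0.25).
#' @param max_p Raw p-value ceiling (default 0.05).
#' @param filter If `FALSE`, return all genes unfiltered.
#' @return `data.frame` with columns `cluster`, `gene`, `log_fc`, `p_value`,
#'   `p_adj`, `pct_in`, `pct_out`, ordered by increasing p then decreasing
#'   fold change.
#' @export
find_markers <- function(matrix, labels, cluster, min_logfc = 0.25,
                         max_p = 0.05, filter = TRUE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "lognorm") stop("find_markers expects the lognorm layer")
  if (length(labels) != length(matrix$cell_ids)) {
    stop("labels must align with the cells of the matrix")
  }
  in_grp <- labels == cluster
  if (!any(in_grp)) stop("unknown cluster label: ", cluster)
  if (sum(in_grp) < 3 || sum(!in_grp) < 3) {
    stop("cluster and complement must each contain at least 3 cells")
  }
  m <- as.matrix(matrix$counts)
  xin <- m[, in_grp, drop = FALSE]
  xout <- m[, !in_grp, drop = FALSE]
  mean_in <- rowMeans(expm1(xin))
  mean_out <- rowMeans(expm1(xout))
  log_fc <- log(mean_in + 1) - log(mean_out + 1)
  pv <- vapply(seq_len(nrow(m)), function(i) {
    wilcoxon_rank_sum(xin[i, ], xout[i, ])$p_value
  }, numeric(1))
  out <- data.frame(cluster = cluster, gene = matrix$gene_ids,
                    log_fc = log_fc, p_value = pv,
                    p_adj = stats::p.adjust(pv, method = "BH"),
                    pct_in = rowMeans(xin > 0), pct_out = rowMeans(xout > 0),
                    stringsAsFactors = FALSE)
  if (filter) out <- out[out$log_fc > min_logfc & out$p_value < max_p, , drop = FALSE]
  out <- out[order(out$p_value, -out$log_fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker tables for every label
#'
#' Convenience wrapper running [find_markers()] once per unique label and
#' row-binding the results; labels whose group or complement has fewer than
#' 3 cells are skipped with a warning.
#'
#' @inheritParams find_markers
#' @return Combined marker `data.frame`.
#' @export
find_markers_all <- function(matrix, labels, min_logfc = 0.25, max_p = 0.05) {
  out <- lapply(sort(unique(labels)), function(cl) {
    if (sum(labels == cl) < 3 || sum(labels != cl) < 3) {
      warning("skipping label with <3 cells on one side: ", cl)
      return(NULL)
    }
    find_markers(matrix, labels, cl, min_logfc = min_logfc, max_p = max_p)
  })
  do.call(rbind, out)
}

#' Per-patient composition over cell types or subgroups
#'
#' @param cells `data.frame` with `patient_id` and the chosen `level` column
#'   (`"cell_type"` or `"subgroup"`).
#' @param level Column to tabulate.
#' @return `data.frame(patient_id, level, fraction)` where fractions sum to 1
#'   within each patient over all levels observed in the full table (absent
#'   levels reported as 0).
#' @export
subgroup_proportions <- function(cells, level = c("cell_type", "subgroup")) {
  level <- match.arg(level)
  if (!level %in% names(cells)) stop("column not found: ", level)
  tab <- table(cells$patient_id, cells[[level]])
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    warning("excluding patient(s) with zero cells")
    tab <- tab[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  fr <- sweep(unclass(tab), 1, totals, "/")
  out <- as.data.frame(as.table(fr), stringsAsFactors = FALSE)
  names(out) <- c("patient_id", level, "fraction")
  out
}
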