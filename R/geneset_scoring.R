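# Per-cell functional scores (exhaustion, activation, antigen presentation,
# immunochemotaxis, ECM, glycolysis, immunosuppression, ...) from
# user-supplied gene sets, via bin-matched control genes.

#' Bin-matched control module score
#'
#' For each cell, the score is the mean log-normalized expression over the
#' gene set minus the mean over control genes drawn (per set gene) from the
#' same average-expression bin, so cell-level offsets and the set's
#' expression stratum cancel in expectation.
#'
#' @param matrix An [expression_matrix()] with `layer = "lognorm"`.
#' @param gene_set A [gene_signature()]; member genes absent from the matrix
#'   are dropped with a warning (an entirely absent set is an error).
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes drawn per set gene (default 100; sampled with
#'   replacement when a bin is smaller).
#' @param seed Seed for the control draws (default 0).
#' @return Named numeric vector of per-cell scores, with attribute
#'   `"provenance"` recording the set, method and parameters.
#' @export
module_score <- function(matrix, gene_set, n_bins = 25, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(gene_set, "GeneSignature"))
  if (matrix$layer != "lognorm") stop("module_score expects the lognorm layer")
  present <- intersect(gene_set$genes, matrix$gene_ids)
  if (!length(present)) stop("gene set entirely absent from the matrix")
  if (length(present) < length(gene_set$genes)) {
    warning(sprintf("module_score: %d gene(s) of '%s' absent from the matrix",
                    length(gene_set$genes) - length(present), gene_set$name))
  }
  m <- matrix$counts
  avg <- Matrix::rowMeans(m)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = min(n_bins, nrow(m)), labels = FALSE)
  names(bins) <- matrix$gene_ids
  set.seed(seed)
  non_set <- setdiff(matrix$gene_ids, present)
  ctrl <- unlist(lapply(present, function(g) {
    # set genes are excluded from their own control pool; with small gene
    # universes the set could otherwise dominate its bin and cancel itself.
    # Widen to neighboring bins until enough control candidates exist.
    d <- 0
    repeat {
      pool <- non_set[abs(bins[non_set] - bins[[g]]) <= d]
      if (length(pool) >= min(10, length(non_set)) || d > max(bins)) break
      d <- d + 1
    }
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE)
  set_score <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  out <- stats::setNames(as.numeric(set_score - ctrl_score), matrix$cell_ids)
  attr(out, "provenance") <- list(gene_set = gene_set$name,
                                  genes_used = present,
                                  method = "bin_matched_control",
                                  n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' Rank subgroups by a per-cell score
#'
#' Computes subgroup means and ranks (1 = highest mean) and all pairwise
#' comparisons via [compare_groups()]. Subgroups with fewer than 3 cells
#' are excluded with a warning.
#'
#' @param scores Named numeric vector of per-cell scores.
#' @param labels Subgroup label per cell (aligned with `scores`).
#' @return List with `table` (`data.frame(subgroup, n, mean, rank)`, ordered
#'   by rank) and `pairwise` (`data.frame(a, b, test, p_value)`; `NULL` when
#'   fewer than two subgroups qualify).
#' @export
rank_subgroups_by_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("excluding subgroup(s) with < 3 cells: ", paste(small, collapse = ", "))
  }
  keep <- names(sizes)[sizes >= 3]
  if (!length(keep)) stop("no subgroup with >= 3 cells")
  means <- vapply(keep, function(s) mean(scores[labels == s]), numeric(1))
  tab <- data.frame(subgroup = keep, n = as.integer(sizes[keep]),
                    mean = means, rank = rank(-means, ties.method = "min"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  pairwise <- NULL
  if (length(keep) >= 2) {
    pairs <- utils::combn(keep, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      cmp <- compare_groups(scores[labels == a], scores[labels == b])
      data.frame(a = a, b = b, test = cmp$test, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, pairwise = pairwise)
}
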