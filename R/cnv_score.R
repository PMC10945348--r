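# Copy-number inference from positional smoothing of expression.
#
# The estimator follows the classic expression-based CNV logic: relative
# (reference-centered) log-normalized expression is smoothed along the
# genome with a moving average over neighboring genes, then re-centered per
# cell, so that chromosomal gains/losses appear as coherent positional
# shifts while gene-specific expression averages out.

#' CNV estimator configuration
#'
#' @param window Moving-average window in genes (default 100). Even values
#'   are incremented to the next odd number so the window is symmetric.
#'   Chromosomes retaining fewer than `window` genes fall back to
#'   `max(3, floor(G_chrom / 10))` (made odd).
#' @param cutoff Minimum mean log-normalized expression for a gene to enter
#'   the analysis (default 0.1).
#' @param reference_label Cell-type label of the reference population
#'   (default `"CD8T"`); reference cells define the expression baseline.
#' @param clip Symmetric bound applied to the centered values before scoring
#'   (default 3).
#' @param denoise Denoising multiplier: centered values within
#'   `denoise * sd(reference values)` of zero are set to zero before
#'   clipping and scoring (default 1.5; 0 disables). This is the standard
#'   reference-noise suppression step of expression-based CNV callers.
#' @param score_method `"meansq"` (mean of squared values, default) or
#'   `"meanabs"` (mean absolute value). Neither is a published convention;
#'   both are simple magnitude functionals of the profile.
#' @return A `CnvConfig` list.
#' @export
cnv_config <- function(window = 100, cutoff = 0.1, reference_label = "CD8T",
                       clip = 3, denoise = 1.5,
                       score_method = c("meansq", "meanabs")) {
  if (window < 1) stop("window must be >= 1")
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (denoise < 0) stop("denoise must be >= 0")
  structure(list(window = as.integer(window), cutoff = cutoff,
                 reference_label = reference_label, clip = clip,
                 denoise = denoise, score_method = match.arg(score_method)),
            class = "CnvConfig")
}

#' Select and order genes for CNV inference
#'
#' Keeps genes whose mean log-normalized expression is at least `cutoff`
#' and orders them by genomic position (chromosome in canonical order, then
#' start coordinate). Genes absent from the annotation are dropped with a
#' warning.
#'
#' @param matrix An [expression_matrix()] with `layer = "lognorm"`.
#' @param annotation Gene annotation (see [gene_annotation()]).
#' @param cutoff Mean-expression threshold (default 0.1).
#' @return `data.frame(gene_id, chromosome, start)` in genomic order.
#' @export
select_cnv_genes <- function(matrix, annotation, cutoff = 0.1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "lognorm") stop("select_cnv_genes expects the lognorm layer")
  uncovered <- setdiff(matrix$gene_ids, annotation$gene_id)
  if (length(uncovered)) {
    warning(sprintf("%d gene(s) not in annotation dropped", length(uncovered)))
  }
  mu <- Matrix::rowMeans(matrix$counts)
  keep <- matrix$gene_ids[mu >= cutoff & matrix$gene_ids %in% annotation$gene_id]
  if (!length(keep)) stop("no genes pass the expression cutoff")
  ann <- annotation[match(keep, annotation$gene_id), c("gene_id", "chromosome", "start")]
  ann <- ann[order(chromosome_rank(ann$chromosome), ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# Sparse band matrix mapping a cells x genes block to its symmetric
# truncated moving average along the gene axis.
moving_average_operator <- function(g, w) {
  half <- (w - 1) %/% 2
  lo <- pmax(1L, seq_len(g) - half)
  hi <- pmin(g, seq_len(g) + half)
  width <- hi - lo + 1L
  Matrix::sparseMatrix(
    i = unlist(lapply(seq_len(g), function(p) lo[p]:hi[p]), use.names = FALSE),
    j = rep(seq_len(g), width),
    x = rep(1 / width, width),
    dims = c(g, g))
}

#' Infer a per-cell CNV profile
#'
#' Three steps: (1) relative expression `E_k(o_j)` is the cell's
#' log-normalized value minus the mean over reference cells for that gene;
#' (2) per cell and per chromosome, a symmetric moving average over
#' `window` genes (truncated at chromosome ends, never spanning
#' chromosomes); (3) each cell's genome-wide mean of its moving averages is
#' subtracted, centering the profile at zero. Values within
#' `denoise * sd(reference values)` of zero are then suppressed and the
#' remainder clipped to `c(-clip, clip)` before scoring.
#'
#' @param matrix An [expression_matrix()] with `layer = "lognorm"`.
#' @param genes Ordered gene table from [select_cnv_genes()].
#' @param config A [cnv_config()].
#' @param reference_cells Character vector of reference cell ids (non-empty,
#'   subset of the matrix cells).
#' @return A `CnvProfile`: list with `values` (cells x positions matrix of
#'   centered moving averages), `genes` (the ordered gene table),
#'   `cell_ids`, `reference_cells`, `config` and `score` (per-cell scalar,
#'   see [cnv_cell_score()]).
#' @export
infer_cnv_profile <- function(matrix, genes, config = cnv_config(),
                              reference_cells) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(config, "CnvConfig"))
  if (matrix$layer != "lognorm") stop("infer_cnv_profile expects the lognorm layer")
  if (!length(reference_cells)) stop("reference cell set is empty")
  if (length(setdiff(reference_cells, matrix$cell_ids))) {
    stop("reference cells not present in the matrix")
  }
  gene_ids <- genes$gene_id
  if (length(setdiff(gene_ids, matrix$gene_ids))) {
    stop("ordered gene list contains genes absent from the matrix")
  }
  chroms <- genes$chromosome
  g_per_chr <- table(chroms)[unique(chroms)]
  if (all(g_per_chr < 3)) {
    stop("every chromosome retains fewer than 3 genes; cannot smooth")
  }
  expr <- t(as.matrix(matrix$counts[gene_ids, , drop = FALSE]))  # cells x genes
  ref_mean <- colMeans(expr[matrix$cell_ids %in% reference_cells, , drop = FALSE])
  e <- sweep(expr, 2, ref_mean, "-")
  ma <- matrix(0, nrow(e), ncol(e), dimnames = dimnames(e))
  for (ch in unique(chroms)) {
    cols <- which(chroms == ch)
    g <- length(cols)
    w <- config$window
    if (g < w) w <- max(3L, g %/% 10L)
    if (w %% 2 == 0) w <- w + 1L
    w <- min(w, if (g %% 2 == 0) g - 1L else g)
    if (g < 3) { ma[, cols] <- e[, cols]; next }
    ma[, cols] <- as.matrix(e[, cols, drop = FALSE] %*%
                              moving_average_operator(g, w))
  }
  centered <- ma - rowMeans(ma)
  if (config$denoise > 0) {
    ref_sd <- stats::sd(centered[matrix$cell_ids %in% reference_cells, ])
    if (is.finite(ref_sd) && ref_sd > 0) {
      centered[abs(centered) <= config$denoise * ref_sd] <- 0
    }
  }
  centered[centered > config$clip] <- config$clip
  centered[centered < -config$clip] <- -config$clip
  profile <- structure(list(values = centered, genes = genes,
                            cell_ids = matrix$cell_ids,
                            reference_cells = reference_cells,
                            config = config),
                       class = "CnvProfile")
  profile$score <- cnv_cell_score(profile)
  profile
}

#' Per-cell CNV score
#'
#' Reduces the centered profile to a non-negative per-cell scalar:
#' `"meansq"` is the mean of squared values (default), `"meanabs"` the mean
#' absolute value. Zero iff the profile is flat.
#'
#' @param profile A `CnvProfile`.
#' @param method Overrides the method recorded in the profile's config.
#' @return Named numeric vector of per-cell scores.
#' @export
cnv_cell_score <- function(profile, method = NULL) {
  stopifnot(inherits(profile, "CnvProfile"))
  method <- if (is.null(method)) profile$config$score_method else method
  v <- profile$values
  s <- switch(method,
              meansq = rowMeans(v^2),
              meanabs = rowMeans(abs(v)),
              stop("unknown score method: ", method))
  stats::setNames(as.numeric(s), profile$cell_ids)
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("CnvProfile: %d cells x %d positions (window=%d, %d reference cells)\n",
              nrow(x$values), ncol(x$values), x$config$window,
              length(x$reference_cells)))
  invisible(x)
}
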