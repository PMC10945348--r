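# Signature construction: batch adjustment of the pooled bulk cohort,
# bulk differential expression (Gx), intersection with subgroup markers,
# and the union Comprehensive signature.

#' Empirical-Bayes batch adjustment
#'
#' Parametric location/scale harmonization across batches: per-gene values
#' are standardized against the grand mean and pooled variance, per-batch
#' additive and multiplicative effects are estimated and shrunk toward
#' parametric batch priors (normal prior on locations, inverse-gamma on
#' scales, moment-matched), removed, and the grand scale restored.
#'
#' @param cohort A `BulkCohort`.
#' @param conv Convergence tolerance of the iterative posterior solution.
#' @return A `BulkCohort` with adjusted expression. A single-batch cohort is
#'   returned unchanged with a warning; a batch with fewer than 2 samples is
#'   an error.
#' @export
combat_adjust <- function(cohort, conv = 1e-4) {
  stopifnot(inherits(cohort, "BulkCohort"))
  batch <- as.character(cohort$clinical$batch)
  batches <- unique(batch)
  if (length(batches) < 2) {
    warning("single batch: returning cohort unchanged")
    return(cohort)
  }
  n_per <- table(batch)
  if (any(n_per < 2)) stop("every batch needs at least 2 samples")
  x <- t(cohort$expr)  # genes x samples
  n <- ncol(x)
  idx <- lapply(batches, function(b) which(batch == b))
  names(idx) <- batches

  batch_means <- vapply(idx, function(i) rowMeans(x[, i, drop = FALSE]),
                        numeric(nrow(x)))
  grand_mean <- as.vector(batch_means %*% (lengths(idx) / n))
  fitted <- batch_means[, match(batch, batches), drop = FALSE]
  var_pooled <- rowSums((x - fitted)^2) / n
  ok <- var_pooled > 0  # constant genes are left untouched
  z <- (x[ok, , drop = FALSE] - grand_mean[ok]) / sqrt(var_pooled[ok])

  for (b in batches) {
    cols <- idx[[b]]
    nb <- length(cols)
    g_hat <- rowMeans(z[, cols, drop = FALSE])
    d_hat <- apply(z[, cols, drop = FALSE], 1, stats::var)
    # Moment-matched hyperpriors across genes.
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_new <- g_hat; d_new <- d_hat
    repeat {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * nb * g_hat + d_old * g_bar) / (t2 * nb + d_old)
      sum2 <- rowSums((z[, cols, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      if (is.na(change) || change < conv) break
    }
    d_new[d_new <= 0] <- 1e-8
    z[, cols] <- (z[, cols, drop = FALSE] - g_new) / sqrt(d_new)
  }
  x_adj <- x
  x_adj[ok, ] <- z * sqrt(var_pooled[ok]) + grand_mean[ok]
  out <- cohort
  out$expr <- t(x_adj)
  out
}

#' Per-gene differential expression between NPD and PD (Gx)
#'
#' Welch's unequal-variance t-test per gene; `Gx` collects the genes with
#' `p < alpha` that are higher in NPD (`direction = "up"`, the default
#' responder-enriched convention) or in either direction
#' (`direction = "both"`). Genes are ordered by increasing p-value.
#'
#' @param cohort A `BulkCohort` (typically the training partition, after
#'   batch adjustment).
#' @param alpha Significance threshold (default 0.05).
#' @param direction `"up"` (NPD-up only) or `"both"`.
#' @return List with `table` (the full per-gene `data.frame`: `gene`,
#'   `mean_NPD`, `mean_PD`, `t_statistic`, `p_value`, `direction`) and
#'   `gx` (a [gene_signature()] named `"Gx"`).
#' @export
derive_gx <- function(cohort, alpha = 0.05, direction = c("up", "both")) {
  stopifnot(inherits(cohort, "BulkCohort"))
  direction <- match.arg(direction)
  resp <- cohort$clinical$response
  n1 <- sum(resp == "NPD"); n2 <- sum(resp == "PD")
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per response class")
  x1 <- cohort$expr[resp == "NPD", , drop = FALSE]
  x2 <- cohort$expr[resp == "PD", , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  tab <- data.frame(gene = colnames(cohort$expr), mean_NPD = m1, mean_PD = m2,
                    t_statistic = tstat, p_value = p,
                    direction = sign(m1 - m2), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sel <- tab$p_value < alpha &
    (if (direction == "up") tab$direction > 0 else tab$direction != 0)
  gx_genes <- tab$gene[sel][order(tab$p_value[sel])]
  list(table = tab,
       gx = gene_signature("Gx", gx_genes,
                           provenance = list(alpha = alpha, direction = direction,
                                             n_NPD = n1, n_PD = n2)))
}

#' Intersect the bulk DEG list with a subgroup marker list
#'
#' @param gx The `Gx` [gene_signature()].
#' @param subgroup_markers A [gene_signature()] of subgroup marker genes.
#' @param name Name of the resulting signature (e.g. `"MM.sig"`).
#' @return A [gene_signature()] containing the intersection, ordered by the
#'   `Gx` order; an empty intersection yields an empty signature with a
#'   warning.
#' @export
intersect_signature <- function(gx, subgroup_markers, name) {
  stopifnot(inherits(gx, "GeneSignature"), inherits(subgroup_markers, "GeneSignature"))
  genes <- gx$genes[gx$genes %in% subgroup_markers$genes]
  if (!length(genes)) warning(sprintf("signature '%s' is empty", name))
  gene_signature(name, genes,
                 provenance = list(parents = c(gx$name, subgroup_markers$name),
                                   n_gx = length(gx$genes),
                                   n_markers = length(subgroup_markers$genes)))
}

#' Merge component signatures into a comprehensive signature
#'
#' @param signatures List of [gene_signature()] objects (e.g. MM.sig, B.sig,
#'   DC.sig, CAF.sig); at least one must be non-empty.
#' @param name Name of the union signature (default `"Comprehensive.sig"`).
#' @return A [gene_signature()] whose membership is exactly the
#'   de-duplicated union of the inputs (first-appearance order).
#' @export
combine_signatures <- function(signatures, name = "Comprehensive.sig") {
  stopifnot(length(signatures) >= 1)
  lapply(signatures, function(s) stopifnot(inherits(s, "GeneSignature")))
  genes <- unique(unlist(lapply(signatures, `[[`, "genes"), use.names = FALSE))
  if (!length(genes)) stop("all component signatures are empty")
  gene_signature(name, genes,
                 provenance = list(parents = vapply(signatures, `[[`, "",
                                                    "name")))
}

#' Build the five response signatures from markers and a training cohort
#'
#' Convenience wrapper for the full construction: derive `Gx` on the
#' (batch-adjusted) training cohort, intersect it with the four subgroup
#' marker lists, and merge the four intersections into the comprehensive
#' signature.
#'
#' @param train A `BulkCohort` training partition.
#' @param marker_signatures Named list of four [gene_signature()] objects
#'   (names are used to derive `<name>.sig` labels).
#' @param alpha Gx significance threshold.
#' @return Named list of five `GeneSignature`s (four intersections plus
#'   `Comprehensive.sig`), with the `Gx` result attached as attribute `"gx"`.
#' @export
build_signatures <- function(train, marker_signatures, alpha = 0.05) {
  gx <- derive_gx(train, alpha = alpha)
  sigs <- lapply(names(marker_signatures), function(nm) {
    intersect_signature(gx$gx, marker_signatures[[nm]], paste0(nm, ".sig"))
  })
  names(sigs) <- paste0(names(marker_signatures), ".sig")
  sigs$Comprehensive.sig <- combine_signatures(sigs)
  attr(sigs, "gx") <- gx
  sigs
}
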