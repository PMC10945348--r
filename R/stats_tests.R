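# Rank-sum machinery for marker derivation and the decision-tree group
# comparison used throughout the proportion / score analyses.

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses exact enumeration of all rank assignments when both groups have at
#' most `exact_max` observations (tie-safe: the permutation distribution of
#' the rank sum is computed on the observed midranks), and the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return List with `statistic` (rank sum of `x` minus its null mean),
#'   `p_value`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs - mu, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = 0, p_value = 1, method = "normal"))
  }
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w_obs - mu,
       p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Decision-tree comparison of two samples
#'
#' Implements the test-selection procedure used for all group comparisons:
#' for unpaired samples, Shapiro-Wilk normality is assessed on each group;
#' if both are normal, an F-test checks variance homogeneity, routing to
#' Student's t (homogeneous) or Welch's t (heterogeneous); non-normal data
#' are compared with the Mann-Whitney rank-sum test. For paired samples the
#' normality of the within-pair differences routes to the paired t-test or
#' the Wilcoxon signed-rank test. (The ratio-paired-t branch used by some
#' workflows is deliberately not auto-selected.)
#'
#' @param x,y Numeric vectors (equal length when `paired = TRUE`).
#' @param paired Whether the samples are paired.
#' @param alpha_normality Significance level for the normality (and variance
#'   homogeneity) pre-tests.
#' @return A `GroupComparisonResult` list: `test`, `statistic`, `p_value`,
#'   and `decision_trail` (character vector of the choices taken).
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha_normality = 0.05) {
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 observations per group")
  if (paired && length(x) != length(y)) stop("paired samples must have equal length")
  trail <- character(0)
  sw_p <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)  # Shapiro undefined on constants
    stats::shapiro.test(v)$p.value
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate input: all observations identical, no test is defined")
  }
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0 && all(d == 0)) {
      stop("degenerate input: all paired differences are zero")
    }
    pn <- sw_p(d)
    normal <- !is.na(pn) && pn > alpha_normality
    trail <- c(trail, sprintf("shapiro(differences) p=%.3g -> %s",
                              pn, if (normal) "normal" else "non-normal"))
    if (normal) {
      tt <- stats::t.test(x, y, paired = TRUE)
      trail <- c(trail, "paired t-test")
      res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
      trail <- c(trail, "wilcoxon signed-rank")
      res <- list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
                  p_value = wt$p.value)
    }
  } else {
    px <- sw_p(x); py <- sw_p(y)
    normal <- !is.na(px) && !is.na(py) && px > alpha_normality && py > alpha_normality
    trail <- c(trail, sprintf("shapiro x p=%.3g, y p=%.3g -> %s",
                              px, py, if (normal) "normal" else "non-normal"))
    if (normal) {
      fv <- stats::var.test(x, y)
      homo <- fv$p.value > alpha_normality
      trail <- c(trail, sprintf("F-test p=%.3g -> %s variances", fv$p.value,
                                if (homo) "homogeneous" else "heterogeneous"))
      tt <- stats::t.test(x, y, var.equal = homo)
      nm <- if (homo) "student t-test" else "welch t-test"
      trail <- c(trail, nm)
      res <- list(test = nm, statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      wr <- wilcoxon_rank_sum(x, y)
      trail <- c(trail, "mann-whitney")
      res <- list(test = "mann-whitney", statistic = wr$statistic,
                  p_value = wr$p_value)
    }
  }
  res$decision_trail <- trail
  class(res) <- "GroupComparisonResult"
  res
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p_value))
  cat("  trail:", paste(x$decision_trail, collapse = " | "), "\n")
  invisible(x)
}
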