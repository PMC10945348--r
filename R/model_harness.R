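# Model grid: stratified train/test split, repeated stratified k-fold
# cross-validated hyperparameter tuning per algorithm, held-out AUC
# evaluation, and argmax model selection over the algorithm x signature grid.

#' Declared hyperparameter grids
#'
#' Small, conventional grids per algorithm (the parameter-free nearest
#' centroid has none). Each element is a list of vectors expanded to a full
#' factorial grid during tuning.
#'
#' @return Named list, one entry per [learner_algorithms()].
#' @export
default_grids <- function() {
  list(svm = list(C = c(0.1, 1, 10)),
       nb = list(eps = 1e-9),
       rf = list(ntree = c(100, 500), max_depth = c(0, 5)),
       knn = list(k = c(3, 5, 7, 9)),
       adaboost = list(rounds = c(50, 100, 200)),
       logitboost = list(rounds = c(50, 100, 200)),
       centroid = list())
}

#' Stratified train/test split of a bulk cohort
#'
#' The training partition receives `floor(train_frac * n)` samples,
#' allocated per response class by floor with largest-remainder rounding,
#' so class proportions carry over; both partitions are guaranteed to
#' contain both classes.
#'
#' @param cohort A `BulkCohort` with >= 10 samples and both classes.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Seed for the random assignment.
#' @return List with `train` and `test` `BulkCohort`s.
#' @export
split_cohort <- function(cohort, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(cohort, "BulkCohort"))
  resp <- cohort$clinical$response
  n <- length(resp)
  if (n < 10) stop("need at least 10 samples")
  if (length(unique(resp)) < 2) stop("both response classes must be present")
  target <- floor(train_frac * n)
  set.seed(seed)
  classes <- sort(unique(resp))
  n_c <- table(resp)[classes]
  base <- floor(train_frac * n_c)
  rem <- train_frac * n_c - base
  extra <- target - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  # Both partitions must contain both classes.
  base <- pmin(pmax(base, 1), n_c - 1)
  if (any(base < 1) || any(n_c - base < 1)) {
    stop("cannot form a split with both classes in both partitions")
  }
  train_idx <- unlist(lapply(classes, function(cl) {
    sample(which(resp == cl), base[[cl]])
  }), use.names = FALSE)
  subset_cohort <- function(idx) {
    out <- cohort
    out$expr <- cohort$expr[idx, , drop = FALSE]
    out$clinical <- cohort$clinical[idx, , drop = FALSE]
    rownames(out$clinical) <- NULL
    out
  }
  list(train = subset_cohort(sort(train_idx)),
       test = subset_cohort(sort(setdiff(seq_len(n), train_idx))))
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# to folds round-robin. Redraws (up to 10 times) if any fold misses a class.
make_folds <- function(y01, folds, seed) {
  set.seed(seed)
  for (attempt in 1:10) {
    f <- integer(length(y01))
    for (cl in c(0, 1)) {
      idx <- sample(which(y01 == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(k) {
      length(unique(y01[f == k])) == 2 && length(unique(y01[f != k])) == 2
    }, logical(1)))
    if (ok) return(f)
  }
  stop("could not form stratified folds containing both classes")
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling; equals the
#' trapezoidal integral of the ROC curve and the probability that a random
#' NPD sample scores above a random PD sample (ties counting 1/2).
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels; `positive` marks the positive class.
#' @param positive Positive class label (default `"NPD"`).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels, positive = "NPD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grade an AUC into the conventional quality bands
#'
#' Half-open bands: `[0.9, 1.0]` excellent, `[0.8, 0.9)` very good,
#' `[0.7, 0.8)` good, `[0.6, 0.7)` sufficient, `[0.5, 0.6)` bad,
#' below 0.5 not useful.
#'
#' @param auc AUC value in `[0, 1]`.
#' @return Character grade.
#' @export
auc_grade <- function(auc) {
  if (!is.finite(auc) || auc < 0 || auc > 1) stop("auc must be in [0, 1]")
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "very good"
  else if (auc >= 0.7) "good"
  else if (auc >= 0.6) "sufficient"
  else if (auc >= 0.5) "bad"
  else "not useful"
}

cohort_features <- function(cohort, genes, impute = NULL, warn = TRUE) {
  present <- intersect(genes, colnames(cohort$expr))
  X <- cohort$expr[, present, drop = FALSE]
  missing <- setdiff(genes, present)
  if (length(missing)) {
    if (is.null(impute)) stop("signature genes absent from cohort: ",
                              paste(missing, collapse = ", "))
    if (warn) warning(sprintf("%d signature gene(s) absent; imputed with training means",
                              length(missing)))
    fill <- matrix(rep(impute[missing], each = nrow(X)), nrow = nrow(X),
                   dimnames = list(rownames(X), missing))
    X <- cbind(X, fill)[, genes, drop = FALSE]
  }
  X
}

#' Tune and train one algorithm on one gene signature
#'
#' Each point of the declared hyperparameter grid is evaluated by the mean
#' AUC over `repeats` x `folds` stratified cross-validation on the training
#' cohort; the best point (ties to the earlier grid row) is refit on the
#' full training set. The parameter-free nearest-centroid learner is fit
#' directly on the whole training set (its CV row is still evaluated so the
#' grid report carries a CV summary for every cell).
#'
#' @param train A `BulkCohort` training partition.
#' @param gene_set A [gene_signature()]; its intersection with the cohort's
#'   genes forms the feature set (empty intersection is an error).
#' @param algorithm One of [learner_algorithms()].
#' @param repeats,folds Cross-validation design (default 10 x 5).
#' @param seed Seed controlling fold draws and stochastic fits.
#' @param grids Hyperparameter grids (default [default_grids()]).
#' @return A `ModelRecord`: list with `algorithm`, `gene_set`, `genes`,
#'   `best_params`, `cv_mean`, `cv_sd`, `cv_table`, `learner`,
#'   `train_means`, `seed` (no `test_auc` yet).
#' @export
tune_and_train <- function(train, gene_set, algorithm, repeats = 10, folds = 5,
                           seed = 1, grids = default_grids()) {
  stopifnot(inherits(train, "BulkCohort"), inherits(gene_set, "GeneSignature"))
  algorithm <- match.arg(algorithm, learner_algorithms())
  genes <- intersect(gene_set$genes, colnames(train$expr))
  if (!length(genes)) stop("gene set shares no genes with the cohort")
  X <- train$expr[, genes, drop = FALSE]
  y01 <- as.integer(train$clinical$response == "NPD")
  grid <- grids[[algorithm]]
  points <- if (length(grid)) do.call(expand.grid, c(grid, KEEP.OUT.ATTRS = FALSE))
            else data.frame(row.names = "1")
  fold_sets <- lapply(seq_len(repeats), function(r) {
    make_folds(y01, folds, seed = substream_seed(seed, paste0("folds", r)))
  })
  cv <- lapply(seq_len(nrow(points)), function(pi) {
    params <- as.list(points[pi, , drop = FALSE])
    aucs <- unlist(lapply(seq_len(repeats), function(r) {
      f <- fold_sets[[r]]
      vapply(seq_len(folds), function(k) {
        tr <- f != k
        set.seed(substream_seed(seed, sprintf("fit-%d-%d-%d", pi, r, k)))
        fit <- fit_learner(algorithm, X[tr, , drop = FALSE], y01[tr], params)
        p <- predict_learner(fit, X[!tr, , drop = FALSE])
        evaluate_auc(p, ifelse(y01[!tr] == 1, "NPD", "PD"))
      }, numeric(1))
    }))
    c(mean = mean(aucs), sd = stats::sd(aucs))
  })
  cv_mean <- vapply(cv, `[[`, numeric(1), "mean")
  best <- which.max(cv_mean)
  best_params <- as.list(points[best, , drop = FALSE])
  set.seed(substream_seed(seed, "final-fit"))
  learner <- fit_learner(algorithm, X, y01, best_params)
  cv_table <- cbind(points, cv_mean = cv_mean,
                    cv_sd = vapply(cv, `[[`, numeric(1), "sd"))
  structure(list(algorithm = algorithm, gene_set = gene_set$name, genes = genes,
                 best_params = best_params, cv_mean = cv_mean[best],
                 cv_sd = cv_table$cv_sd[best], cv_table = cv_table,
                 learner = learner, train_means = colMeans(X), seed = seed),
            class = "ModelRecord")
}

#' Predict response scores and hard labels for a cohort
#'
#' @param record A `ModelRecord`.
#' @param cohort A `BulkCohort`; signature genes missing from it are imputed
#'   with the training means (with a warning).
#' @return `data.frame(sample_id, score, label)` where `score` is the NPD
#'   probability and `label` applies the 0.5 threshold (`>= 0.5` is NPD).
#' @export
predict_response_score <- function(record, cohort) {
  stopifnot(inherits(record, "ModelRecord"), inherits(cohort, "BulkCohort"))
  X <- cohort_features(cohort, record$genes, impute = record$train_means)
  p <- predict_learner(record$learner, X)
  data.frame(sample_id = cohort$clinical$sample_id, score = p,
             label = ifelse(p >= 0.5, "NPD", "PD"), stringsAsFactors = FALSE)
}

#' Run the full algorithm x signature model grid
#'
#' Tunes and trains one model per (algorithm, signature) cell, evaluates
#' each on the held-out test cohort, and selects the record with the
#' highest test AUC (ties broken by higher CV mean, then by the declared
#' algorithm order).
#'
#' @param train,test `BulkCohort` partitions from [split_cohort()].
#' @param signatures Named list of [gene_signature()] objects.
#' @param algorithms Algorithm names (default all seven).
#' @param repeats,folds Cross-validation design (default 10 x 5).
#' @param seed Master seed; each grid cell derives its own sub-stream.
#' @return A `GridReport`: list with `records` (all `ModelRecord`s, each
#'   with `test_auc` and `grade`), `summary` (`data.frame`), and `selected`
#'   (the winning record).
#' @export
run_grid <- function(train, test, signatures, algorithms = learner_algorithms(),
                     repeats = 10, folds = 5, seed = 1) {
  stopifnot(length(signatures) >= 1)
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  }
  records <- list()
  for (sig_name in names(signatures)) {
    for (alg in algorithms) {
      rec <- tryCatch(
        tune_and_train(train, signatures[[sig_name]], alg,
                       repeats = repeats, folds = folds,
                       seed = substream_seed(seed, paste(alg, sig_name))),
        error = function(e) stop(sprintf("grid cell (%s, %s): %s",
                                         alg, sig_name, conditionMessage(e))))
      pred <- predict_response_score(rec, test)
      rec$test_auc <- evaluate_auc(pred$score, test$clinical$response)
      rec$grade <- auc_grade(rec$test_auc)
      records[[paste(alg, sig_name, sep = "|")]] <- rec
    }
  }
  summary <- do.call(rbind, lapply(records, function(r) {
    data.frame(algorithm = r$algorithm, gene_set = r$gene_set,
               n_genes = length(r$genes), cv_mean = r$cv_mean,
               cv_sd = r$cv_sd, test_auc = r$test_auc, grade = r$grade,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  alg_rank <- match(summary$algorithm, learner_algorithms())
  sel <- order(-summary$test_auc, -summary$cv_mean, alg_rank)[1]
  structure(list(records = records, summary = summary,
                 selected = records[[sel]], seed = seed),
            class = "GridReport")
}

#' @export
print.GridReport <- function(x, ...) {
  cat(sprintf("GridReport: %d models; selected %s on %s (test AUC %.3f, %s)\n",
              nrow(x$summary), x$selected$algorithm, x$selected$gene_set,
              x$selected$test_auc, x$selected$grade))
  invisible(x)
}
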