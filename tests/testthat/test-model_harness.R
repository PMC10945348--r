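separable_cohort <- function(n = 60, seed = 70) {
  set.seed(seed)
  response <- rep(c("NPD", "PD"), each = n / 2)
  x1 <- ifelse(response == "NPD", 2, -2) + rnorm(n, sd = 0.1)
  expr <- cbind(g1 = x1, g2 = rnorm(n), g3 = rnorm(n))
  rownames(expr) <- sprintf("s%02d", seq_len(n))
  clin <- data.frame(sample_id = rownames(expr), response = response,
                     batch = "A", os_time = rexp(n, 0.1), os_event = 1)
  bulk_cohort(expr, clin)
}

test_that("stratified split arithmetic and partition properties", {
  co <- gen_bulk_cohort(synth_config(seed = 71))
  sp <- split_cohort(co, 0.8, seed = 1)
  expect_equal(nrow(sp$train$expr), 195)
  expect_equal(nrow(sp$test$expr), 49)
  ids <- c(sp$train$clinical$sample_id, sp$test$clinical$sample_id)
  expect_setequal(ids, co$clinical$sample_id)
  expect_equal(anyDuplicated(ids), 0)
  # class proportions carry over approximately
  p_all <- mean(co$clinical$response == "NPD")
  expect_lt(abs(mean(sp$train$clinical$response == "NPD") - p_all), 0.02)
  # small-n floor arithmetic
  small <- co
  small$expr <- co$expr[1:10, ]; small$clinical <- co$clinical[1:10, ]
  sp2 <- split_cohort(small, 0.8, seed = 2)
  expect_equal(nrow(sp2$train$expr), 8)
  expect_equal(nrow(sp2$test$expr), 2)
})

test_that("AUC equals brute-force pairwise concordance (n <= 12)", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- sample(c(rep("NPD", 2), rep("PD", 2),
                       sample(c("NPD", "PD"), n - 4, replace = TRUE)))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    expect_equal(evaluate_auc(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(evaluate_auc(c(3, 2.5, 2, 1, 0.5, 0),
                            c("NPD", "NPD", "NPD", "PD", "PD", "PD")), 1)
  expect_equal(evaluate_auc(rep(0.5, 8), rep(c("NPD", "PD"), 4)), 0.5)
  expect_equal(evaluate_auc(c(0.9, 0.4, 0.6, 0.1), c("NPD", "NPD", "PD", "PD")),
               0.75)
  expect_error(evaluate_auc(1:3, rep("PD", 3)), "both classes")
})

test_that("AUC grading bands", {
  expect_equal(auc_grade(0.95), "excellent")
  expect_equal(auc_grade(0.9), "excellent")
  expect_equal(auc_grade(0.85), "very good")
  expect_equal(auc_grade(0.75), "good")
  expect_equal(auc_grade(0.65), "sufficient")
  expect_equal(auc_grade(0.55), "bad")
  expect_equal(auc_grade(0.49), "not useful")
  expect_error(auc_grade(1.2), "0, 1")
})

test_that("cross-validation folds form a stratified partition", {
  y01 <- rep(c(0L, 1L), c(40, 60))
  for (r in 1:5) {
    f <- immunosig:::make_folds(y01, folds = 5, seed = r)
    expect_equal(sort(unique(f)), 1:5)
    expect_equal(length(f), 100)
    for (k in 1:5) {
      expect_true(all(table(y01[f == k]) >= 1))
    }
    # stratification: fold class balance close to global
    for (k in 1:5) expect_lt(abs(mean(y01[f == k]) - 0.6), 0.11)
  }
})

test_that("every algorithm reaches CV AUC >= 0.99 on separable data", {
  co <- separable_cohort()
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  for (alg in learner_algorithms()) {
    rec <- tune_and_train(co, sig, alg, repeats = 2, folds = 5, seed = 5)
    expect_gte(rec$cv_mean, 0.99)
  }
})

test_that("tuning is deterministic under a fixed seed", {
  co <- separable_cohort(seed = 73)
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  a <- tune_and_train(co, sig, "rf", repeats = 1, folds = 3, seed = 9)
  b <- tune_and_train(co, sig, "rf", repeats = 1, folds = 3, seed = 9)
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$cv_table, b$cv_table)
  expect_identical(predict_response_score(a, co)$score,
                   predict_response_score(b, co)$score)
})

test_that("predictions are probabilities, reproducible, and accurate when separable", {
  co <- separable_cohort(seed = 74)
  test <- separable_cohort(n = 40, seed = 75)
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  rec <- tune_and_train(co, sig, "svm", repeats = 1, folds = 3, seed = 2)
  p <- predict_response_score(rec, test)
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_gte(mean(p$label == test$clinical$response), 0.95)
  expect_identical(p$score, predict_response_score(rec, test)$score)
})

test_that("missing signature genes are imputed with a warning", {
  co <- separable_cohort(seed = 76)
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  rec <- tune_and_train(co, sig, "nb", repeats = 1, folds = 3, seed = 2)
  test <- co
  test$expr <- co$expr[, c("g1", "g2")]
  expect_warning(p <- predict_response_score(rec, test), "imputed")
  expect_true(all(is.finite(p$score)))
})

test_that("grid cardinality and selection invariants on a small grid", {
  co <- separable_cohort(n = 80, seed = 77)
  sp <- split_cohort(co, 0.75, seed = 1)
  sigs <- list(A = gene_signature("A", c("g1", "g2")),
               B = gene_signature("B", c("g2", "g3")))
  g <- run_grid(sp$train, sp$test, sigs, repeats = 1, folds = 3, seed = 4)
  expect_equal(nrow(g$summary), 7 * length(sigs))
  expect_equal(g$selected$test_auc, max(g$summary$test_auc))
  expect_s3_class(g$records[[1]], "ModelRecord")
})

test_that("shuffled test labels change AUC but not the trained model", {
  co <- separable_cohort(n = 80, seed = 78)
  sp <- split_cohort(co, 0.75, seed = 2)
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  rec <- tune_and_train(sp$train, sig, "logitboost", repeats = 1, folds = 3,
                        seed = 3)
  p1 <- predict_response_score(rec, sp$test)
  set.seed(79)
  shuffled <- sp$test
  shuffled$clinical$response <- sample(shuffled$clinical$response)
  p2 <- predict_response_score(rec, shuffled)
  expect_identical(p1$score, p2$score)  # model untouched by test labels
  expect_false(isTRUE(all.equal(evaluate_auc(p1$score, sp$test$clinical$response),
                                evaluate_auc(p2$score, shuffled$clinical$response))))
})
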