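test_that("qc_filter applies the printed thresholds at their boundaries", {
  n_genes <- 7000
  ids <- sprintf("g%05d", seq_len(n_genes))
  ann <- gene_annotation(data.frame(gene_id = ids, chromosome = "1",
                                    start = seq_len(n_genes),
                                    is_mito = rep(FALSE, n_genes)))
  make_cell <- function(k) { v <- numeric(n_genes); v[seq_len(k)] <- 1; v }
  m <- cbind(low = make_cell(150), ok = make_cell(500), high = make_cell(6500))
  rownames(m) <- ids
  em <- expression_matrix(m)
  res <- qc_filter(em, ann, min_cells_per_gene = 1)
  expect_equal(res$cells$cell_id, "ok")
  expect_equal(unname(res$report[c("cells_low_genes", "cells_high_genes")]),
               c(1L, 1L))
})

test_that("qc_filter removes high-mito cells and low-support genes", {
  ids <- c(sprintf("g%03d", 1:300), "MT-1")
  ann <- gene_annotation(data.frame(gene_id = ids, chromosome = c(rep("1", 300), "MT"),
                                    start = seq_along(ids)))
  base <- c(rep(1, 300), 0)
  m <- cbind(mito12 = c(rep(1, 300), 41),   # 41/341 ~= 0.120 > 0.10
             mito08 = c(rep(1, 300), 26),   # 26/326 ~= 0.080
             plain = base)
  rownames(m) <- ids
  res <- qc_filter(expression_matrix(m), ann, min_genes = 100,
                   min_cells_per_gene = 1)
  expect_false("mito12" %in% res$cells$cell_id)
  expect_true("mito08" %in% res$cells$cell_id)
  # gene support boundary: >= 3 cells kept, 2 cells dropped
  m2 <- matrix(0, 4, 3, dimnames = list(c("a", "b", "c", "d"), c("x", "y", "z")))
  m2["a", ] <- 1          # 3 cells -> kept
  m2["b", 1:2] <- 1       # 2 cells -> dropped
  m2["c", ] <- 1; m2["d", ] <- 1
  ann2 <- gene_annotation(data.frame(gene_id = rownames(m2), chromosome = "1",
                                     start = 1:4, is_mito = FALSE))
  res2 <- qc_filter(expression_matrix(m2), ann2, min_genes = 1)
  expect_true("a" %in% res2$matrix$gene_ids)
  expect_false("b" %in% res2$matrix$gene_ids)
})

test_that("qc_filter is idempotent on the synthetic fixture", {
  sc <- small_sc()
  once <- qc_filter(sc$matrix, sc$annotation)
  twice <- qc_filter(once$matrix, sc$annotation)
  expect_identical(as.matrix(twice$matrix$counts), as.matrix(once$matrix$counts))
  expect_equal(sum(twice$report), 0)  # second pass removes nothing
})

test_that("log-normalization matches its closed form and invariances", {
  m <- matrix(c(100, 0, 0, 50, 0, 50), 3, 2,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  ln <- normalize_lognorm(expression_matrix(m))
  expect_equal(ln$counts["a", "c1"], log(1 + 1e4), tolerance = 1e-12)
  expect_equal(unname(as.vector(ln$counts["b", ])), c(0, 0))  # all-zero gene
  # scale invariance: doubling a cell's counts leaves its profile unchanged
  m2 <- m; m2[, 1] <- m[, 1] * 2
  ln2 <- normalize_lognorm(expression_matrix(m2))
  expect_equal(as.vector(ln2$counts[, 1]), as.vector(ln$counts[, 1]))
  # zero-total cell is an error
  m3 <- m; m3[, 2] <- 0
  expect_error(normalize_lognorm(expression_matrix(m3)), "zero total")
})

test_that("clustering recovers two well-separated blobs and is seeded", {
  set.seed(100)
  n_per <- 80; n_genes <- 40
  truth <- rep(1:2, each = n_per)
  means <- rbind(matrix(1, n_per, n_genes),
                 cbind(matrix(1 + 4 * 0.5, n_per, n_genes / 2),
                       matrix(1, n_per, n_genes / 2)))
  vals <- means + matrix(rnorm(2 * n_per * n_genes, sd = 0.5), 2 * n_per)
  m <- t(pmax(vals, 0))
  dimnames(m) <- list(sprintf("g%02d", 1:n_genes), sprintf("c%03d", 1:(2 * n_per)))
  em <- lognorm_matrix(m)
  cl <- cluster_cells(em, n_pcs = 10, n_hvg = 40, k = 15, seed = 3)
  expect_equal(length(unique(cl)), 2)
  expect_gt(adjusted_rand_index(cl, truth), 0.95)
  cl2 <- cluster_cells(em, n_pcs = 10, n_hvg = 40, k = 15, seed = 3)
  expect_identical(cl, cl2)
})

test_that("identical duplicated cells land in one cluster; n_pcs validated", {
  m <- matrix(rep(c(1, 2, 0.5, 3), 25), 4, 25,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:25)))
  em <- lognorm_matrix(m)
  cl <- cluster_cells(em, n_pcs = 2, k = 5, seed = 1)
  expect_equal(length(unique(cl)), 1)
  expect_error(cluster_cells(em, n_pcs = 50, seed = 1), "n_pcs")
})

test_that("subgroup proportions sum to one and match counts", {
  cells <- data.frame(
    patient_id = rep(c("p1", "p2"), c(10, 5)),
    cell_type = c(rep("T", 4), rep("B", 6), rep("T", 5)))
  pr <- subgroup_proportions(cells, "cell_type")
  expect_equal(pr$fraction[pr$patient_id == "p1" & pr$cell_type == "T"], 0.4)
  sums <- tapply(pr$fraction, pr$patient_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # absent level reported as zero fraction
  expect_equal(pr$fraction[pr$patient_id == "p2" & pr$cell_type == "B"], 0)
})

test_that("proportions from the generator reproduce configured absences", {
  sc <- small_sc()
  pr <- subgroup_proportions(sc$cells, "subgroup")
  pd_patients <- unique(sc$cells$patient_id[sc$cells$group == "PD-pre"])
  zero <- pr$fraction[pr$patient_id %in% pd_patients & pr$subgroup == "B_CD74"]
  expect_true(all(zero == 0))
})
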