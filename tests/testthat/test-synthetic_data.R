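test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_sc_config(seed = 7)
  a <- gen_single_cell(cfg)
  b <- gen_single_cell(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$cells, b$cells)
  sig <- gene_signature("s", sprintf("G%04d", 1:10))
  x <- gen_bulk_cohort(cfg, sig)
  y <- gen_bulk_cohort(cfg, sig)
  expect_identical(x$expr, y$expr)
  expect_identical(x$clinical, y$clinical)
})

test_that("config validation rejects inconsistent fractions and effects", {
  bad_fr <- default_cell_type_fractions()
  bad_fr[["PD-pre"]]["B"] <- 0.5
  expect_error(synth_config(cell_type_fractions = bad_fr), "sum to")
  expect_error(synth_config(bulk_effect = -1), "NPD-up")
  expect_error(synth_config(cnv_segments = data.frame(
    chromosome = "1", start_gene_index = 1, n_genes = 5, copy_ratio = -2)),
    "copy_ratio")
})

test_that("subgroups with zero fraction are absent from that group", {
  sc <- small_sc()
  pd_pre <- sc$cells[sc$cells$group == "PD-pre", ]
  expect_equal(sum(pd_pre$subgroup == "B_CD74"), 0)
  expect_equal(sum(pd_pre$subgroup == "iCAF_CCL21"), 0)
  # and present where configured positive
  npd_pre <- sc$cells[sc$cells$group == "NPD-pre", ]
  expect_gt(sum(npd_pre$subgroup == "B_CD74"), 0)
})

test_that("label marginals match configured fractions within binomial error", {
  sc <- small_sc()
  cfg <- small_sc_config()
  for (g in names(cfg$n_patients)) {
    sub <- sc$cells[sc$cells$group == g, ]
    fr <- cfg$cell_type_fractions[[g]]
    n <- nrow(sub)
    for (ct in names(fr)) {
      se <- sqrt(fr[[ct]] * (1 - fr[[ct]]) / n)
      expect_lt(abs(mean(sub$cell_type == ct) - fr[[ct]]), 4 * se + 1e-9)
    }
  }
})

test_that("planted subgroup markers carry the configured log2 fold change", {
  sc <- cached("marker_fc_sc", {
    cfg <- synth_config(seed = 21, cells_per_patient = 70L, n_genes = 1200L,
                        cnv_segments = data.frame(chromosome = "7",
                                                  start_gene_index = 1L,
                                                  n_genes = 20L, copy_ratio = 1.5))
    gen_single_cell(cfg)
  })
  counts <- as.matrix(sc$matrix$counts)
  sf <- colSums(counts)
  norm <- sweep(counts, 2, sf / mean(sf), "/")  # undo library size
  for (sg in c("B_CD74", "MM_Immune")) {
    mk <- sc$marker_truth$gene[sc$marker_truth$subgroup == sg]
    ct <- sc$cells$cell_type[match(sg, sc$cells$subgroup)]
    in_cells <- sc$cells$subgroup == sg
    out_cells <- sc$cells$cell_type == ct & !in_cells
    fc <- log2(rowMeans(norm[mk, in_cells, drop = FALSE]) /
                 rowMeans(norm[mk, out_cells, drop = FALSE]))
    expect_lt(abs(mean(fc) - 2), 0.3)
  }
})

test_that("null bulk cohort gives uniform per-gene t-test p-values", {
  cfg <- synth_config(seed = 31, bulk_n_samples = 200, bulk_n_genes = 2000,
                      batch_sizes = c(A = 200), bulk_effect = 0)
  co <- gen_bulk_cohort(cfg)
  deg <- derive_gx(co)
  expect_true(mean(deg$table$p_value < 0.05) > 0.03)
  expect_true(mean(deg$table$p_value < 0.05) < 0.07)
})

test_that("batch offsets appear in raw per-batch grand means", {
  cfg <- synth_config(seed = 5, bulk_n_samples = 120, bulk_n_genes = 400,
                      batch_sizes = c(A = 60, B = 60),
                      batch_offsets = c(A = 0, B = 1),
                      batch_scales = c(A = 1, B = 1))
  co <- gen_bulk_cohort(cfg)
  mA <- mean(co$expr[co$clinical$batch == "A", ])
  mB <- mean(co$expr[co$clinical$batch == "B", ])
  expect_lt(abs((mB - mA) - 1), 0.1)
})

test_that("censoring rate zero means every event is observed", {
  cfg <- synth_config(seed = 9, bulk_n_samples = 50, bulk_n_genes = 20,
                      batch_sizes = c(A = 50), censoring_rate = 0)
  co <- gen_bulk_cohort(cfg)
  expect_true(all(co$clinical$os_event == 1))
})

test_that("planted bulk effect is recovered within 3 standard errors", {
  sig <- gene_signature("s", sprintf("G%04d", 1:25))
  cfg <- synth_config(seed = 13, bulk_n_samples = 300, bulk_n_genes = 500,
                      batch_sizes = c(A = 300), bulk_effect = 1)
  co <- gen_bulk_cohort(cfg, sig)
  npd <- co$clinical$response == "NPD"
  d <- colMeans(co$expr[npd, sig$genes]) - colMeans(co$expr[!npd, sig$genes])
  se <- sqrt(1 / sum(npd) + 1 / sum(!npd)) / sqrt(length(sig$genes))
  expect_lt(abs(mean(d) - 1), 3 * se)
})
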