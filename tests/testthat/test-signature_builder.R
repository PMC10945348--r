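test_that("batch adjustment: identity on one batch, removes a planted offset", {
  cfg1 <- synth_config(seed = 60, bulk_n_samples = 80, bulk_n_genes = 200,
                       batch_sizes = c(A = 80))
  co1 <- gen_bulk_cohort(cfg1)
  expect_warning(adj1 <- combat_adjust(co1), "single batch")
  expect_identical(adj1$expr, co1$expr)

  cfg2 <- synth_config(seed = 61, bulk_n_samples = 600, bulk_n_genes = 300,
                       batch_sizes = c(A = 300, B = 300),
                       batch_offsets = c(A = 0, B = 1),
                       batch_scales = c(A = 1, B = 1))
  co2 <- gen_bulk_cohort(cfg2)
  adj2 <- combat_adjust(co2)
  isA <- adj2$clinical$batch == "A"
  gap <- colMeans(adj2$expr[!isA, ]) - colMeans(adj2$expr[isA, ])
  expect_lt(mean(abs(gap)), 0.05)
  # raw gap was ~1
  raw_gap <- colMeans(co2$expr[!isA, ]) - colMeans(co2$expr[isA, ])
  expect_gt(mean(raw_gap), 0.9)
})

test_that("batch adjustment is monotone within batch for every gene", {
  cfg <- synth_config(seed = 62, bulk_n_samples = 60, bulk_n_genes = 40,
                      batch_sizes = c(A = 30, B = 30),
                      batch_offsets = c(A = 0, B = 2),
                      batch_scales = c(A = 1, B = 1.5))
  co <- gen_bulk_cohort(cfg)
  adj <- combat_adjust(co)
  for (b in c("A", "B")) {
    rows <- co$clinical$batch == b
    rho <- vapply(seq_len(ncol(co$expr)), function(j) {
      stats::cor(co$expr[rows, j], adj$expr[rows, j], method = "spearman")
    }, numeric(1))
    expect_true(all(rho == 1))
  }
  # batch with a single sample is an error
  co_bad <- co
  co_bad$clinical$batch[1] <- "C"
  expect_error(combat_adjust(co_bad), "at least 2")
})

test_that("Gx recovers planted NPD-up genes and honors the direction filter", {
  sig <- gene_signature("planted", sprintf("G%04d", 1:40))
  cfg <- synth_config(seed = 63, bulk_n_samples = 200, bulk_n_genes = 2000,
                      batch_sizes = c(A = 200), bulk_effect = 1)
  co <- gen_bulk_cohort(cfg, sig)
  res <- derive_gx(co)
  expect_gte(mean(sig$genes %in% res$gx$genes), 0.9)
  # genes higher in PD are excluded even when significant
  flipped <- co
  flipped$expr[co$clinical$response == "PD", sig$genes] <-
    flipped$expr[co$clinical$response == "PD", sig$genes] + 3
  res2 <- derive_gx(flipped)
  expect_false(any(sig$genes %in% res2$gx$genes))
  # class with < 2 samples errors
  tiny <- co
  tiny$expr <- co$expr[1:3, ]; tiny$clinical <- co$clinical[1:3, ]
  tiny$clinical$response <- c("NPD", "PD", "PD")
  expect_error(derive_gx(tiny), "at least 2")
})

test_that("null Gx size is calibrated to the one-sided alpha", {
  cfg <- synth_config(seed = 64, bulk_n_samples = 200, bulk_n_genes = 2000,
                      batch_sizes = c(A = 200), bulk_effect = 0)
  co <- gen_bulk_cohort(cfg)
  res <- derive_gx(co)
  # expect ~ 0.025 * 2000 = 50 one-sided false positives
  expect_gt(length(res$gx$genes), 25)
  expect_lt(length(res$gx$genes), 75)
})

test_that("intersection and union contracts", {
  gx <- gene_signature("Gx", c("A", "B", "C"))
  gmm <- gene_signature("G_MM", c("B", "C", "D"))
  mm <- intersect_signature(gx, gmm, "MM.sig")
  expect_equal(mm$genes, c("B", "C"))
  expect_warning(empty <- intersect_signature(gx, gene_signature("x", "Z"), "E.sig"),
                 "empty")
  expect_length(empty$genes, 0)
  comp <- combine_signatures(list(gene_signature("a", c("A", "B")),
                                  gene_signature("b", c("B", "C")),
                                  empty,
                                  gene_signature("d", "D")))
  expect_setequal(comp$genes, c("A", "B", "C", "D"))
  expect_lte(length(comp$genes), 2 + 2 + 0 + 1)
  expect_error(combine_signatures(list(empty)), "empty")
})

test_that("signature construction is deterministic", {
  sig <- gene_signature("planted", sprintf("G%04d", 1:30))
  cfg <- synth_config(seed = 65, bulk_n_samples = 150, bulk_n_genes = 400,
                      batch_sizes = c(A = 75, B = 75))
  co <- combat_adjust(gen_bulk_cohort(cfg, sig))
  markers <- list(MM = gene_signature("G_MM", sprintf("G%04d", 1:15)),
                  B = gene_signature("G_B", sprintf("G%04d", 16:30)))
  a <- build_signatures(co, markers)
  b <- build_signatures(co, markers)
  expect_identical(lapply(a, `[[`, "genes"), lapply(b, `[[`, "genes"))
  expect_setequal(a$Comprehensive.sig$genes,
                  union(a$MM.sig$genes, a$B.sig$genes))
})
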