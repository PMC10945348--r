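# End-to-end orchestration: simulate -> subgroup markers -> CNV -> batch
# adjustment -> signature construction -> model grid -> survival
# stratification. Deterministic for a fixed seed.

#' Run the full pipeline on synthetic data
#'
#' Generates a single-cell dataset and a pooled bulk cohort from one
#' [synth_config()], derives marker genes for the four immune-activation
#' subgroups (melanoma MM_Immune, follicular B `B_CD74`, conventional
#' dendritic `cDC2_RTN1`, inflammatory fibroblast `iCAF_CCL21`), infers CNV
#' profiles against the CD8+ T reference, batch-adjusts and splits the bulk
#' cohort, builds the four intersection signatures plus the comprehensive
#' union, trains the 7 x 5 model grid, and stratifies test-set survival by
#' the selected model's predictions.
#'
#' @param seed Master seed driving every stage.
#' @param config Optional [synth_config()]; defaults to a desk-scale
#'   configuration derived from `seed`.
#' @param repeats,folds Cross-validation design for the grid (defaults kept
#'   small here for runtime; the harness default is 10 x 5).
#' @return List with `markers`, `marker_signatures`, `cnv`, `signatures`,
#'   `grid`, `predictions`, `risk`, `km` (curves per risk group), and
#'   `logrank`.
#' @export
run_pipeline <- function(seed = 1, config = NULL, repeats = 2, folds = 5) {
  if (is.null(config)) {
    config <- synth_config(seed = seed, cells_per_patient = 60L,
                           n_genes = 1500L, bulk_n_genes = 1500L)
  }
  sc <- gen_single_cell(config)
  qc <- qc_filter(sc$matrix, sc$annotation)
  keep <- qc$matrix$cell_ids
  cells <- sc$cells[match(keep, sc$cells$cell_id), ]
  lognorm <- normalize_lognorm(qc$matrix)

  subgroups <- c(MM = "MM_Immune", B = "B_CD74", DC = "cDC2_RTN1",
                 CAF = "iCAF_CCL21")
  markers <- lapply(subgroups, function(sg) {
    find_markers(lognorm, cells$subgroup, sg)
  })
  marker_sigs <- lapply(names(subgroups), function(nm) {
    gene_signature(paste0("G_", nm), markers[[nm]]$gene)
  })
  names(marker_sigs) <- names(subgroups)

  cnv_genes <- select_cnv_genes(lognorm, sc$annotation)
  ref_cells <- cells$cell_id[cells$cell_type == "CD8T"]
  cnv <- infer_cnv_profile(lognorm, cnv_genes, cnv_config(), ref_cells)

  planted <- intersect(unique(sc$marker_truth$gene),
                       sprintf("G%04d", seq_len(config$bulk_n_genes)))
  bulk <- gen_bulk_cohort(config, gene_signature("planted", planted))
  bulk <- combat_adjust(bulk)
  parts <- split_cohort(bulk, 0.8, seed = substream_seed(seed, "split"))
  sigs <- build_signatures(parts$train, marker_sigs)
  nonempty <- sigs[vapply(sigs, function(s) length(s$genes) > 0, logical(1))]
  grid <- run_grid(parts$train, parts$test, nonempty,
                   repeats = repeats, folds = folds,
                   seed = substream_seed(seed, "grid"))
  pred <- predict_response_score(grid$selected, parts$test)
  risk <- stratify_by_prediction(stats::setNames(pred$label, pred$sample_id))
  clin <- parts$test$clinical
  km <- lapply(c(High = "High-risk", Low = "Low-risk"), function(r) {
    i <- risk == r
    if (!any(i)) return(NULL)
    km_estimate(clin$os_time[i], clin$os_event[i])
  })
  lr <- NULL
  if (length(unique(risk)) == 2) {
    hi <- risk == "High-risk"
    lr <- logrank_test(list(time = clin$os_time[hi], event = clin$os_event[hi]),
                       list(time = clin$os_time[!hi], event = clin$os_event[!hi]))
  }
  list(markers = markers, marker_signatures = marker_sigs, cnv = cnv,
       signatures = sigs, grid = grid, predictions = pred, risk = risk,
       km = km, logrank = lr)
}
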