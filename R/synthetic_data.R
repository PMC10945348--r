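# Synthetic single-cell and bulk cohort generators.
#
# The single-cell generator emulates a multi-patient single-nucleus study of
# melanoma under neoadjuvant anti-PD-1: three patient groups (PD-pre,
# NPD-pre, NPD-post), planted cell-type and subgroup markers, mitochondrial
# genes, and chromosomal gain/loss segments confined to malignant cells.
# The bulk generator emulates a pooled pre-treatment ICI cohort (four
# batches, n = 244) with response labels, batch effects and censored
# survival. Both are seeded and bit-reproducible.

# Derive a per-stage seed from the global seed so adding a stage does not
# perturb draws in earlier stages. Kept below 2^31.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Default per-group cell-type fractions of the single-cell generator
#'
#' PD-pre tumors are malignant-cell and stroma heavy with few lymphocytes;
#' NPD tumors carry more CD8+ T and B cells, further shifted toward CD8+ T
#' after treatment.
#' @return Named list of per-group fraction vectors.
#' @export
default_cell_type_fractions <- function() {
  list(
    "PD-pre"   = c(Malignant = 0.60, CD8T = 0.10, B = 0.04, DC = 0.06, CAF = 0.20),
    "NPD-pre"  = c(Malignant = 0.45, CD8T = 0.20, B = 0.12, DC = 0.08, CAF = 0.15),
    "NPD-post" = c(Malignant = 0.35, CD8T = 0.30, B = 0.12, DC = 0.08, CAF = 0.15)
  )
}

#' Default subgroup composition of the single-cell generator
#'
#' Within-cell-type subgroup fractions per patient group. The four
#' immune-activation subgroups (MM_Immune, B_CD74, cDC2_RTN1, iCAF_CCL21)
#' are scarce or absent in PD-pre, mirroring the biology the pipeline is
#' designed to detect; each carries 20 planted markers at log2FC 2.
#' @return `data.frame`; see the `subgroup_spec` argument of [synth_config()].
#' @export
default_subgroup_spec <- function() {
  data.frame(
    subgroup  = c("MM_Immune", "MM_Other", "CD8T", "B_CD74", "B_Other",
                  "cDC2_RTN1", "DC_Other", "iCAF_CCL21", "CAF_Other"),
    cell_type = c("Malignant", "Malignant", "CD8T", "B", "B",
                  "DC", "DC", "CAF", "CAF"),
    frac_PD_pre   = c(0.05, 0.95, 1, 0.00, 1.00, 0.00, 1.00, 0.00, 1.00),
    frac_NPD_pre  = c(0.35, 0.65, 1, 0.30, 0.70, 0.40, 0.60, 0.35, 0.65),
    frac_NPD_post = c(0.35, 0.65, 1, 0.30, 0.70, 0.40, 0.60, 0.35, 0.65),
    n_markers = c(20L, 0L, 20L, 20L, 0L, 20L, 0L, 20L, 0L),
    log2fc    = c(2, 0, 2, 2, 0, 2, 0, 2, 0),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-data configuration
#'
#' Collects every knob of the single-cell and bulk generators with defaults
#' chosen to emulate the study design the pipeline targets: 3 PD-pre and
#' 8 NPD-pre patients (the NPD patients contribute paired post-treatment
#' samples), four immune-activation subgroups depleted or absent in PD-pre,
#' a pooled 244-sample four-batch bulk cohort, and exponential survival
#' with a worse hazard for predicted progressors.
#'
#' @param seed Integer master seed; all stages derive sub-stream seeds from it.
#' @param n_patients Named integer vector of patients per group
#'   (`PD-pre`, `NPD-pre`, `NPD-post`).
#' @param cells_per_patient Cells drawn per patient.
#' @param n_genes Total genes (including mitochondrial).
#' @param n_mito_genes Number of `MT-` genes (13 = human mtDNA protein genes).
#' @param n_chromosomes Autosomes the non-mitochondrial genes are spread over
#'   (default 22; fewer chromosomes give longer per-chromosome gene runs for
#'   hosting long CNV segments).
#' @param mito_fraction Expected fraction of counts from mitochondrial genes.
#' @param cell_type_fractions Per-group named fractions over cell types
#'   (each group must sum to 1).
#' @param subgroup_spec `data.frame` describing subgroups: columns
#'   `subgroup`, `cell_type`, `frac_PD_pre`, `frac_NPD_pre`, `frac_NPD_post`
#'   (within-cell-type fractions, summing to 1 per cell type and group),
#'   `n_markers`, `log2fc` (planted marker up-shift on the log2 scale).
#' @param cnv_segments `data.frame(chromosome, start_gene_index, n_genes,
#'   copy_ratio)`: contiguous gene runs whose negative-binomial means are
#'   multiplied by `copy_ratio` in malignant cells only.
#' @param mean_log_mu,sd_log_mu Log-normal parameters of baseline gene means.
#' @param dispersion Negative-binomial `size` parameter shared by all genes.
#' @param libsize_sd Log-normal sd of per-cell library size factors.
#' @param bulk_n_samples,bulk_n_genes Bulk cohort dimensions.
#' @param bulk_npd_fraction Fraction of NPD (responder) samples.
#' @param bulk_effect Mean shift (in within-gene SD units) added to signature
#'   genes in NPD samples; must be >= 0 (NPD-up convention).
#' @param batch_sizes Named sample counts per batch (must sum to
#'   `bulk_n_samples`).
#' @param batch_offsets,batch_scales Additive offset and multiplicative scale
#'   applied per batch after effect injection.
#' @param surv_median_npd,surv_median_pd Median overall survival (months) of
#'   the exponential survival model per response class.
#' @param censoring_rate Fraction of samples right-censored.
#' @return A validated list of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = c("PD-pre" = 3L, "NPD-pre" = 8L, "NPD-post" = 8L),
                         cells_per_patient = 200L,
                         n_genes = 2000L,
                         n_mito_genes = 13L,
                         n_chromosomes = 22L,
                         mito_fraction = 0.05,
                         cell_type_fractions = default_cell_type_fractions(),
                         subgroup_spec = default_subgroup_spec(),
                         cnv_segments = data.frame(
                           chromosome = c("7", "10"),
                           start_gene_index = c(1L, 1L),
                           n_genes = c(60L, 60L),
                           copy_ratio = c(1.5, 0.5)),
                         mean_log_mu = log(0.3), sd_log_mu = 1,
                         dispersion = 2,
                         libsize_sd = 0.3,
                         bulk_n_samples = 244L,
                         bulk_n_genes = 2000L,
                         bulk_npd_fraction = 0.5,
                         bulk_effect = 1,
                         batch_sizes = c(Hugo2016 = 26L, Liu2019 = 121L,
                                         Gide2019 = 73L, Riaz2017 = 24L),
                         batch_offsets = c(Hugo2016 = 0, Liu2019 = 0.5,
                                           Gide2019 = 1, Riaz2017 = -0.5),
                         batch_scales = c(Hugo2016 = 1, Liu2019 = 1.2,
                                          Gide2019 = 0.9, Riaz2017 = 1.1),
                         surv_median_npd = 30,
                         surv_median_pd = 10,
                         censoring_rate = 0.3) {
  align_batches <- function(v, default) {
    out <- stats::setNames(rep(default, length(batch_sizes)), names(batch_sizes))
    common <- intersect(names(v), names(batch_sizes))
    out[common] <- v[common]
    out
  }
  batch_offsets <- align_batches(batch_offsets, 0)
  batch_scales <- align_batches(batch_scales, 1)
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes),
              n_mito_genes = as.integer(n_mito_genes),
              n_chromosomes = as.integer(n_chromosomes),
              mito_fraction = mito_fraction,
              cell_type_fractions = cell_type_fractions,
              subgroup_spec = subgroup_spec,
              cnv_segments = cnv_segments,
              mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
              dispersion = dispersion, libsize_sd = libsize_sd,
              bulk_n_samples = as.integer(bulk_n_samples),
              bulk_n_genes = as.integer(bulk_n_genes),
              bulk_npd_fraction = bulk_npd_fraction,
              bulk_effect = bulk_effect,
              batch_sizes = batch_sizes,
              batch_offsets = batch_offsets, batch_scales = batch_scales,
              surv_median_npd = surv_median_npd, surv_median_pd = surv_median_pd,
              censoring_rate = censoring_rate)
  validate_synth_config(cfg)
  structure(cfg, class = "SynthConfig")
}

validate_synth_config <- function(cfg) {
  for (g in names(cfg$cell_type_fractions)) {
    s <- sum(cfg$cell_type_fractions[[g]])
    if (abs(s - 1) > 1e-9) {
      stop(sprintf("cell type fractions for group '%s' sum to %.6f, not 1", g, s))
    }
  }
  ss <- cfg$subgroup_spec
  for (ct in unique(ss$cell_type)) {
    for (col in c("frac_PD_pre", "frac_NPD_pre", "frac_NPD_post")) {
      s <- sum(ss[[col]][ss$cell_type == ct])
      if (abs(s - 1) > 1e-9) {
        stop(sprintf("subgroup fractions of cell type '%s' (%s) sum to %.6f, not 1",
                     ct, col, s))
      }
    }
  }
  if (any(cfg$n_patients <= 0) || cfg$cells_per_patient <= 0 || cfg$n_genes <= 0) {
    stop("patient, cell and gene counts must be positive")
  }
  if (nrow(cfg$cnv_segments) && any(cfg$cnv_segments$copy_ratio <= 0)) {
    stop("cnv copy_ratio must be > 0")
  }
  if (cfg$bulk_effect < 0) {
    stop("bulk_effect must be >= 0 (NPD-up direction convention)")
  }
  if (abs(sum(cfg$batch_sizes) - cfg$bulk_n_samples) > 0) {
    stop("batch_sizes must sum to bulk_n_samples")
  }
  invisible(cfg)
}

subgroup_frac_col <- function(group) {
  switch(group,
         "PD-pre" = "frac_PD_pre",
         "NPD-pre" = "frac_NPD_pre",
         "NPD-post" = "frac_NPD_post",
         stop("unknown group: ", group))
}

# Genome layout for the synthetic gene universe: non-mito genes split into
# contiguous blocks over chromosomes 1..22 (annotation order = genomic order),
# mito genes on MT.
synth_gene_annotation <- function(n_genes, n_mito_genes, n_chromosomes = 22L) {
  n_reg <- n_genes - n_mito_genes
  chroms <- as.character(seq_len(n_chromosomes))
  sizes <- diff(floor(seq(0, n_reg, length.out = n_chromosomes + 1)))
  chr <- rep(chroms, sizes)
  start <- unlist(lapply(sizes, function(k) seq_len(k) * 100000L), use.names = FALSE)
  ids <- sprintf("G%04d", seq_len(n_reg))
  ann <- data.frame(gene_id = c(ids, sprintf("MT-G%02d", seq_len(n_mito_genes))),
                    chromosome = c(chr, rep("MT", n_mito_genes)),
                    start = c(start, seq_len(n_mito_genes) * 1000L),
                    stringsAsFactors = FALSE)
  gene_annotation(ann)
}

#' Generate a synthetic single-cell dataset
#'
#' Draws a gene x cell UMI count matrix from a negative-binomial model with
#' log-normal baseline gene means and a common dispersion. Subgroup marker
#' genes are up-shifted by the configured log2 fold change in their
#' subgroup's cells, genes inside `cnv_segments` have their means multiplied
#' by `copy_ratio` in malignant cells, and mitochondrial genes carry the
#' configured expected count fraction. True labels are returned alongside.
#'
#' @param config A [synth_config()].
#' @return A list with components `matrix` (an [expression_matrix()], raw
#'   counts), `cells` (`data.frame` of true labels: `cell_id`, `patient_id`,
#'   `group`, `cell_type`, `subgroup`), `annotation` (gene annotation),
#'   `marker_truth` (`data.frame(subgroup, gene, log2fc)` of planted markers)
#'   and `cnv_truth` (the realized segment gene lists).
#' @export
gen_single_cell <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  validate_synth_config(config)
  ann <- synth_gene_annotation(config$n_genes, config$n_mito_genes,
                               config$n_chromosomes)
  n_genes <- nrow(ann)
  ss <- config$subgroup_spec

  # Stage 1: baseline gene means and marker assignment.
  set.seed(substream_seed(config$seed, "sc-genes"))
  mu <- stats::rlnorm(n_genes, meanlog = config$mean_log_mu, sdlog = config$sd_log_mu)
  names(mu) <- ann$gene_id
  # Calibrate mito genes to the configured expected count fraction.
  mito <- ann$is_mito
  if (any(mito) && config$mito_fraction > 0) {
    mu[mito] <- mu[mito] * (config$mito_fraction / (1 - config$mito_fraction)) *
      sum(mu[!mito]) / sum(mu[mito])
  }
  marker_pool <- sample(ann$gene_id[!mito])
  takes <- ss$n_markers[ss$n_markers > 0]
  who <- ss$subgroup[ss$n_markers > 0]
  if (sum(takes) > length(marker_pool)) stop("not enough genes for requested markers")
  idx_end <- cumsum(takes)
  marker_truth <- do.call(rbind, lapply(seq_along(takes), function(i) {
    data.frame(subgroup = who[i],
               gene = marker_pool[(idx_end[i] - takes[i] + 1):idx_end[i]],
               log2fc = ss$log2fc[match(who[i], ss$subgroup)],
               stringsAsFactors = FALSE)
  }))

  # Realize CNV segments as concrete gene lists (annotation order within
  # chromosome).
  cnv_truth <- NULL
  if (nrow(config$cnv_segments)) {
    cnv_truth <- do.call(rbind, lapply(seq_len(nrow(config$cnv_segments)), function(i) {
      seg <- config$cnv_segments[i, ]
      on_chr <- ann$gene_id[ann$chromosome == as.character(seg$chromosome)]
      on_chr <- on_chr[order(ann$start[match(on_chr, ann$gene_id)])]
      idx <- seq(seg$start_gene_index, length.out = seg$n_genes)
      if (max(idx) > length(on_chr)) {
        stop(sprintf("cnv segment %d exceeds chromosome %s (%d genes)",
                     i, seg$chromosome, length(on_chr)))
      }
      data.frame(segment = i, gene = on_chr[idx], copy_ratio = seg$copy_ratio,
                 stringsAsFactors = FALSE)
    }))
  }

  # Stage 2: cell labels.
  set.seed(substream_seed(config$seed, "sc-labels"))
  groups <- names(config$n_patients)
  cells <- do.call(rbind, lapply(groups, function(g) {
    fr <- config$cell_type_fractions[[g]]
    col <- subgroup_frac_col(g)
    do.call(rbind, lapply(seq_len(config$n_patients[[g]]), function(p) {
      pid <- sprintf("%s_P%d", g, p)
      ct <- sample(names(fr), config$cells_per_patient, replace = TRUE, prob = fr)
      sg <- vapply(ct, function(tt) {
        rows <- ss[ss$cell_type == tt, ]
        if (!nrow(rows)) return(tt)
        sample(rows$subgroup, 1, prob = rows[[col]])
      }, character(1))
      data.frame(patient_id = pid, group = g, cell_type = ct, subgroup = sg,
                 stringsAsFactors = FALSE)
    }))
  }))
  cells$cell_id <- sprintf("C%05d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "patient_id", "group", "cell_type", "subgroup")]
  rownames(cells) <- NULL

  # Stage 3: counts, generated subgroup-block-wise (the mean vector depends
  # only on the subgroup).
  set.seed(substream_seed(config$seed, "sc-counts"))
  sf <- stats::rlnorm(nrow(cells), meanlog = 0, sdlog = config$libsize_sd)
  counts <- matrix(0, nrow = n_genes, ncol = nrow(cells))
  for (sg in sort(unique(cells$subgroup))) {
    cols <- which(cells$subgroup == sg)
    mu_sg <- mu
    mk <- marker_truth[marker_truth$subgroup == sg, ]
    if (nrow(mk)) {
      mu_sg[mk$gene] <- mu_sg[mk$gene] * 2^mk$log2fc
    }
    ct <- ss$cell_type[match(sg, ss$subgroup)]
    if (!is.na(ct) && ct == "Malignant" && !is.null(cnv_truth)) {
      mu_sg[cnv_truth$gene] <- mu_sg[cnv_truth$gene] * cnv_truth$copy_ratio
    }
    mu_block <- outer(mu_sg, sf[cols])
    counts[, cols] <- matrix(
      stats::rnbinom(length(mu_block), mu = as.vector(mu_block),
                     size = config$dispersion),
      nrow = n_genes)
  }
  dimnames(counts) <- list(ann$gene_id, cells$cell_id)
  em <- expression_matrix(counts, layer = "counts")
  list(matrix = em, cells = cells, annotation = ann,
       marker_truth = marker_truth, cnv_truth = cnv_truth)
}

#' Generate a synthetic pooled ICI bulk cohort
#'
#' Samples x genes log-scale expression with unit within-gene noise SD, a
#' `bulk_effect`-SD up-shift on the supplied signature genes in NPD samples,
#' per-batch location/scale distortion applied after effect injection, and
#' exponential overall survival with class-specific medians, right-censored
#' at the configured rate.
#'
#' @param config A [synth_config()].
#' @param signature A [gene_signature()] whose genes receive the NPD up-shift;
#'   must be a subset of the bulk gene universe `G0001..`. May be `NULL` or
#'   empty for a pure-null cohort.
#' @return A `BulkCohort`; attribute `"effect_genes"` carries the truth.
#' @export
gen_bulk_cohort <- function(config, signature = NULL) {
  stopifnot(inherits(config, "SynthConfig"))
  validate_synth_config(config)
  genes <- sprintf("G%04d", seq_len(config$bulk_n_genes))
  eff_genes <- character(0)
  if (!is.null(signature)) {
    stopifnot(inherits(signature, "GeneSignature"))
    if (length(setdiff(signature$genes, genes))) {
      stop("signature genes outside the bulk gene universe")
    }
    eff_genes <- signature$genes
  }
  n <- config$bulk_n_samples

  set.seed(substream_seed(config$seed, "bulk-expr"))
  base_means <- stats::rnorm(config$bulk_n_genes, mean = 5, sd = 1)
  response <- sample(c("NPD", "PD"), n, replace = TRUE,
                     prob = c(config$bulk_npd_fraction, 1 - config$bulk_npd_fraction))
  expr <- matrix(stats::rnorm(n * config$bulk_n_genes, sd = 1),
                 nrow = n, ncol = config$bulk_n_genes)
  expr <- sweep(expr, 2, base_means, "+")
  if (length(eff_genes)) {
    idx <- match(eff_genes, genes)
    expr[response == "NPD", idx] <- expr[response == "NPD", idx] + config$bulk_effect
  }

  batch <- rep(names(config$batch_sizes), config$batch_sizes)
  set.seed(substream_seed(config$seed, "bulk-batch"))
  batch <- sample(batch)  # batch independent of response
  for (b in names(config$batch_sizes)) {
    rows <- batch == b
    expr[rows, ] <- expr[rows, ] * config$batch_scales[[b]] + config$batch_offsets[[b]]
  }

  set.seed(substream_seed(config$seed, "bulk-surv"))
  rate <- ifelse(response == "NPD", log(2) / config$surv_median_npd,
                 log(2) / config$surv_median_pd)
  os_time <- stats::rexp(n, rate = rate)
  censored <- stats::runif(n) < config$censoring_rate
  os_time[censored] <- os_time[censored] * stats::runif(sum(censored))
  clin <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     response = response, batch = batch,
                     os_time = os_time, os_event = as.integer(!censored),
                     stringsAsFactors = FALSE)
  dimnames(expr) <- list(clin$sample_id, genes)
  cohort <- bulk_cohort(expr, clin)
  attr(cohort, "effect_genes") <- eff_genes
  cohort
}
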