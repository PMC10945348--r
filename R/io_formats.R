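# Readers/writers for the external artifacts the pipeline touches:
# Matrix Market expression triplets + TSV sidecars, GMT gene sets,
# samples x genes CSV with a clinical TSV, and gene annotation tables.

#' Construct an ExpressionMatrix
#'
#' A thin validated container around a sparse genes x cells count (or
#' log-normalized) matrix with unique gene and cell identifiers.
#'
#' @param counts A matrix or `Matrix::sparseMatrix` of non-negative values,
#'   genes in rows and cells in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames of `counts`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   colnames of `counts`).
#' @param layer Either `"counts"` (raw UMI counts) or `"lognorm"`
#'   (log-normalized expression).
#' @return An object of class `ExpressionMatrix` with fields `gene_ids`,
#'   `cell_ids`, `counts` (a `dgCMatrix`) and `layer`.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_ids = colnames(counts),
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.matrix(counts)) {
    counts <- Matrix::Matrix(counts * 1.0, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids must be supplied (or present as dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stop("dimension mismatch between matrix and gene/cell identifiers")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids are not allowed")
  if (length(counts@x) && min(counts@x) < 0) {
    stop("expression values must be non-negative")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(gene_ids = gene_ids, cell_ids = cell_ids,
                 counts = counts, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [layer=%s, %.1f%% nonzero]\n",
              length(x$gene_ids), length(x$cell_ids), x$layer,
              100 * length(x$counts@x) /
                max(1, length(x$gene_ids) * length(x$cell_ids))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a sparse expression matrix in Matrix Market format
#'
#' Reads a coordinate-format `.mtx` file together with one-column gene and
#' cell identifier sidecar files (one identifier per line, genes = rows,
#' cells = columns; the Cell Ranger style triplet layout).
#'
#' @param matrix_path Path to the Matrix Market coordinate file.
#' @param genes_path Path to the gene identifier file (first column used).
#' @param cells_path Path to the cell identifier file (first column used).
#' @param layer Layer tag for the loaded values, see [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression_mtx <- function(matrix_path, genes_path, cells_path,
                                layer = "counts") {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf("matrix is %d x %d but sidecars list %d genes and %d cells",
                 nrow(m), ncol(m), length(genes), length(cells)))
  }
  expression_matrix(m, genes, cells, layer = layer)
}

#' Write an ExpressionMatrix as Matrix Market triplets with sidecars
#'
#' @param x An `ExpressionMatrix`.
#' @param dir Output directory (created if absent). Writes `matrix.mtx`,
#'   `genes.tsv` and `barcodes.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  writeLines(x$gene_ids, paths[2])
  writeLines(x$cell_ids, paths[3])
  invisible(paths)
}

#' Construct a GeneSignature
#'
#' @param name Signature name.
#' @param genes Character vector of member genes; duplicates are collapsed.
#' @param provenance Optional named list recording how the signature was built.
#' @param warn_dup Emit a warning when duplicates are collapsed.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(name, genes, provenance = list(), warn_dup = FALSE) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    if (warn_dup) warning(sprintf("signature '%s': duplicate genes collapsed", name))
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines of the form `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a line are collapsed with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_signature()] objects (empty list for an
#'   empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line (need >= 3 tab-separated fields): %s",
                   substr(ln, 1, 60)))
    }
    sig <- gene_signature(fields[1], fields[-(1:2)],
                          provenance = list(source = path,
                                            description = fields[2]),
                          warn_dup = TRUE)
    out[[fields[1]]] <- sig
  }
  out
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A `GeneSignature` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    desc <- s$provenance$description
    if (is.null(desc)) desc <- "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a BulkCohort
#'
#' Couples a samples x genes expression matrix (log-scale values) with a
#' clinical table carrying anti-PD-1 response labels (PD = progressive
#' disease, NPD = non-progressive disease), cohort-of-origin batch labels
#' and right-censored overall survival.
#'
#' @param expr Numeric matrix, samples in rows, genes in columns, with
#'   dimnames set.
#' @param clinical `data.frame` with columns `sample_id`, `response`
#'   (`"PD"`/`"NPD"`), `batch`, `os_time` (months, >= 0), `os_event` (0/1).
#' @return An object of class `BulkCohort`; samples are aligned between the
#'   two components.
#' @export
bulk_cohort <- function(expr, clinical) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  req <- c("sample_id", "response", "batch", "os_time", "os_event")
  missing_cols <- setdiff(req, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(rownames(expr))) stop("duplicate sample ids in expression")
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample ids in clinical table")
  bad <- setdiff(unique(clinical$response), c("PD", "NPD"))
  if (length(bad)) {
    stop("response labels must be PD or NPD; found: ", paste(bad, collapse = ", "))
  }
  if (!all(clinical$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  if (any(clinical$os_time < 0)) stop("os_time must be non-negative")
  shared <- intersect(rownames(expr), clinical$sample_id)
  if (!length(shared)) stop("no overlapping samples between expression and clinical")
  dropped <- setdiff(union(rownames(expr), clinical$sample_id), shared)
  if (length(dropped)) {
    message(sprintf("bulk_cohort: dropped %d sample(s) absent from one input", length(dropped)))
  }
  expr <- expr[shared, , drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(expr = expr, clinical = clinical, dropped = dropped),
            class = "BulkCohort")
}

#' @export
print.BulkCohort <- function(x, ...) {
  cat(sprintf("BulkCohort: %d samples x %d genes; %d NPD / %d PD; batches: %s\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$clinical$response == "NPD"), sum(x$clinical$response == "PD"),
              paste(unique(x$clinical$batch), collapse = ", ")))
  invisible(x)
}

#' Read a bulk cohort from an expression CSV and a clinical TSV
#'
#' @param expr_csv CSV with a header row of gene ids and the first column
#'   holding sample ids (samples x genes).
#' @param clinical_tsv TSV with columns `sample_id`, `response`, `batch`,
#'   `os_time`, `os_event`.
#' @param log1p_transform If `TRUE`, the expression is treated as raw linear
#'   values and `log1p` is applied on load. Default `FALSE`: values are
#'   already on a log scale.
#' @return A `BulkCohort` restricted to samples present in both files.
#' @export
read_bulk_cohort <- function(expr_csv, clinical_tsv, log1p_transform = FALSE) {
  ex <- utils::read.csv(expr_csv, row.names = 1, check.names = FALSE)
  expr <- as.matrix(ex)
  if (log1p_transform) expr <- log1p(expr)
  clin <- utils::read.delim(clinical_tsv, stringsAsFactors = FALSE)
  bulk_cohort(expr, clin)
}

#' Write a bulk cohort to an expression CSV and a clinical TSV
#'
#' @param cohort A `BulkCohort`.
#' @param expr_csv,clinical_tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bulk_cohort <- function(cohort, expr_csv, clinical_tsv) {
  stopifnot(inherits(cohort, "BulkCohort"))
  utils::write.csv(as.data.frame(cohort$expr), expr_csv)
  utils::write.table(cohort$clinical, clinical_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expr_csv, clinical_tsv))
}

#' Canonical chromosome ordering
#'
#' Natural order 1..22, X, Y, MT; chromosomes outside this set are appended
#' alphabetically. Accepts `"chr"`-prefixed names.
#'
#' @param chroms Character vector of chromosome names.
#' @return Integer ranks usable for sorting.
#' @export
chromosome_rank <- function(chroms) {
  canon <- c(as.character(1:22), "X", "Y", "MT")
  stripped <- sub("^chr", "", as.character(chroms))
  stripped[stripped == "M"] <- "MT"
  r <- match(stripped, canon)
  extra <- sort(unique(stripped[is.na(r)]))
  r[is.na(r)] <- length(canon) + match(stripped[is.na(r)], extra)
  r
}

#' Construct / validate a gene annotation table
#'
#' @param df `data.frame` with columns `gene_id`, `chromosome`, `start`
#'   (1-based bp) and optionally `is_mito`. When `is_mito` is absent it is
#'   derived from the `"MT-"` gene-id prefix (and the MT chromosome).
#' @return A validated `data.frame` with all four columns.
#' @export
gene_annotation <- function(df) {
  req <- c("gene_id", "chromosome", "start")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("gene annotation missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df$start <- as.integer(df$start)
  if (any(df$start < 1, na.rm = TRUE)) stop("start positions must be >= 1")
  if (is.null(df$is_mito)) {
    df$is_mito <- startsWith(df$gene_id, "MT-") |
      sub("^chr", "", as.character(df$chromosome)) %in% c("MT", "M")
  }
  df[, c("gene_id", "chromosome", "start", "is_mito")]
}

#' Read a gene annotation TSV
#'
#' @param path TSV with header columns `gene_id`, `chromosome`, `start`
#'   and optionally `is_mito`.
#' @return See [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a gene annotation TSV
#' @param annotation A gene annotation `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
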