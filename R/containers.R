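#' Count matrix with feature annotation
#'
#' Container for a nonnegative integer feature-by-sample matrix, the basic
#' currency of the bulk pipeline, together with a per-feature annotation
#' table (chromosome, biotype).
#'
#' @param counts integer matrix, features as rows, samples as columns; both
#'   dimnames must be set.
#' @param annotation data.frame with columns `feature_id`, `chromosome`,
#'   `biotype`; one row per feature of `counts`.  Missing annotation rows are
#'   filled with `"unknown"`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `annotation`.
#' @export
count_matrix <- function(counts, annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have feature (row) names")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) stop("counts must have sample (column) names")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "double"   # keeps large counts exact, avoids int overflow
  if (is.null(annotation)) {
    annotation <- data.frame(feature_id = rownames(counts),
                             chromosome = "unknown", biotype = "unknown",
                             stringsAsFactors = FALSE)
  } else {
    annotation <- as.data.frame(annotation)
    need <- c("feature_id", "chromosome", "biotype")
    miss <- setdiff(need, names(annotation))
    if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
    idx <- match(rownames(counts), annotation$feature_id)
    annotation <- data.frame(
      feature_id = rownames(counts),
      chromosome = ifelse(is.na(idx), "unknown", as.character(annotation$chromosome)[idx]),
      biotype    = ifelse(is.na(idx), "unknown", as.character(annotation$biotype)[idx]),
      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, annotation = annotation),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x a [count_matrix()].
#' @param i feature index (ids, logical or integer).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  cts <- x$counts
  if (!missing(i)) cts <- cts[i, , drop = FALSE]
  if (!missing(j)) cts <- cts[, j, drop = FALSE]
  count_matrix(cts, x$annotation)
}

as_count_input <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Validate a sample sheet
#'
#' Checks the clinical sample table used throughout the pipeline: unique
#' sample ids, sex in {male, female}, tissue in {tumor, normal}, nonnegative
#' overall-survival time where present.
#'
#' @param samples data.frame with at least `sample_id`, `sex`, `tissue`;
#'   optionally `age`, `stage`, `grade`, `os_time`, `os_status`.
#' @return the validated data.frame (character columns normalized).
#' @export
validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "sex", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  samples$sex <- as.character(samples$sex)
  samples$tissue <- as.character(samples$tissue)
  if (!all(samples$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if ("os_time" %in% names(samples)) {
    bad <- !is.na(samples$os_time) & samples$os_time < 0
    if (any(bad)) stop("os_time must be >= 0")
  }
  if ("os_status" %in% names(samples)) {
    ok <- is.na(samples$os_status) | samples$os_status %in% c(0, 1)
    if (!all(ok)) stop("os_status must be 0 (censored) or 1 (deceased)")
  }
  samples
}

#' Single-cell UMI matrix with per-cell metadata
#'
#' Wraps a sparse genes-by-cells UMI count matrix.  Per-cell totals
#' (`n_umi`), detected feature counts (`n_features`) and mitochondrial
#' fraction are derived from the matrix itself, so they can never disagree
#' with it; `sample_id`, `sex` and `cell_type` come from `cell_meta`.
#'
#' @param counts genes x cells matrix (dense or `Matrix::dgCMatrix`), with
#'   gene row names and barcode column names.
#' @param cell_meta data.frame with `barcode`, `sample_id`, `sex`,
#'   `cell_type` (one row per cell).
#' @param mito_prefix prefix identifying mitochondrial genes (default
#'   `"MT-"`).
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, mito_prefix = "MT-") {
  if (!inherits(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(rownames(counts)) || (is.null(colnames(counts)) && ncol(counts) > 0))
    stop("counts must have gene and barcode names")
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  cell_meta <- as.data.frame(cell_meta)
  need <- c("barcode", "sample_id", "sex", "cell_type")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stop("cell_meta lacks columns: ", paste(miss, collapse = ", "))
  idx <- match(colnames(counts), cell_meta$barcode)
  if (anyNA(idx)) stop("cell_meta is missing barcodes present in the matrix")
  cell_meta <- cell_meta[idx, , drop = FALSE]
  n_umi <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  meta <- data.frame(
    barcode = colnames(counts),
    sample_id = as.character(cell_meta$sample_id),
    sex = as.character(cell_meta$sex),
    cell_type = as.character(cell_meta$cell_type),
    n_umi = as.numeric(n_umi),
    n_features = as.integer(n_features),
    mito_fraction = ifelse(n_umi > 0, mito_umi / n_umi, 0),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, cell_meta = meta, mito_prefix = mito_prefix),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%d cell types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)
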