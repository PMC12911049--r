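#' Read a count matrix from TSV
#'
#' Expects features as rows (first column = feature id) and a header of
#' sample ids, the layout written by [write_counts()].
#'
#' @param path TSV file of counts.
#' @param annotation_path optional TSV with `feature_id`, `chromosome`,
#'   `biotype` columns.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, annotation_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ann <- if (!is.null(annotation_path))
    utils::read.delim(annotation_path, stringsAsFactors = FALSE) else NULL
  count_matrix(m, ann)
}

#' Write a count matrix (and its annotation) to TSV
#'
#' @param x a [count_matrix()].
#' @param path output TSV for counts.
#' @param annotation_path optional output TSV for the feature annotation.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, annotation_path = NULL) {
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(x$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' @param path TSV file.
#' @return data.frame validated by [validate_samples()].
#' @export
read_samples <- function(path) {
  validate_samples(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_samples
#' @param samples sample sheet data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a single-cell matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `barcodes.tsv`, `features.tsv` and `cell_meta.tsv`
#' under `dir` (CellRanger-style layout, uncompressed).
#'
#' @param x a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sc
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @export
read_sc <- function(dir, mito_prefix = "MT-") {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"),
                            stringsAsFactors = FALSE)
  cell_matrix(m, meta, mito_prefix = mito_prefix)
}

# run an expression with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# deterministic substream seeds derived from one master seed; keeps values
# inside the 32-bit integer range R requires
substream <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483629)
}
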