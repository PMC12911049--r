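#' Single-cell QC filtering
#'
#' Removes low-quality cells and putative doublets by the standard
#' threshold rule: a cell is dropped when its mitochondrial UMI fraction
#' exceeds `max_mito`, its total UMI count falls below `min_umi`, or its
#' detected feature count lies outside `[min_features, max_features]`.
#' Filtering is idempotent.
#'
#' @param cells a [cell_matrix()].
#' @param max_mito maximum mitochondrial fraction (default 0.10; cells
#'   strictly above are removed).
#' @param min_umi minimum total UMI count (default 1000; cells strictly
#'   below are removed).
#' @param min_features,max_features detected-feature bounds (defaults 300
#'   and 6000; cells strictly below/above are removed).
#' @return filtered [cell_matrix()].
#' @export
qc_filter <- function(cells, max_mito = 0.10, min_umi = 1000,
                      min_features = 300, max_features = 6000) {
  meta <- cells$cell_meta
  keep <- meta$mito_fraction <= max_mito &
    meta$n_umi >= min_umi &
    meta$n_features >= min_features &
    meta$n_features <= max_features
  cell_matrix(cells$counts[, keep, drop = FALSE],
              meta[keep, c("barcode", "sample_id", "sex", "cell_type")],
              mito_prefix = cells$mito_prefix)
}

#' Log-normalize single-cell counts
#'
#' `ln(1 + count / cell_total * scale)` per entry (counts-per-`scale`
#' followed by `log1p`), the standard single-cell normalization.
#'
#' @param cells a [cell_matrix()] or sparse genes x cells matrix.
#' @param scale library-size target (default 1e4).
#' @return sparse genes x cells matrix of normalized values.
#' @export
log_normalize <- function(cells, scale = 1e4) {
  m <- if (inherits(cells, "cell_matrix")) cells$counts else cells
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Per-cell-type sex-biased differential expression
#'
#' Within each cell type, compares male versus female cells for each gene
#' of a prioritized panel with the Wilcoxon rank-sum test on log-normalized
#' expression.  The fold change is computed on the de-logged
#' counts-per-`scale` means with a pseudocount of 1,
#' `log2((mean_male + 1) / (mean_female + 1))`, so it reads on the count
#' scale.  Benjamini-Hochberg correction is applied within each cell type
#' across the panel; significance uses the usual `padj < alpha`,
#' `|log2fc| > lfc` rule.  Cell types with fewer than `min_cells` cells in
#' either sex are skipped with a warning.
#'
#' @param cells a [cell_matrix()] (after [qc_filter()]).
#' @param panel character vector of genes to test.
#' @param alpha,lfc significance thresholds (defaults 0.05 and 0.58).
#' @param min_cells minimum cells per sex within a type (default 10).
#' @param scale normalization target passed to [log_normalize()].
#' @return data.frame with one row per (gene, cell type): `log2fc` (male vs
#'   female), `p`, `padj`, `significant`, `direction`, cell counts.
#' @export
per_celltype_sex_de <- function(cells, panel, alpha = 0.05, lfc = 0.58,
                                min_cells = 10, scale = 1e4) {
  meta <- cells$cell_meta
  panel <- intersect(panel, rownames(cells$counts))
  if (!length(panel)) stop("no panel gene found in the matrix")
  norm <- log_normalize(cells, scale = scale)
  rows <- list()
  for (ct in sort(unique(meta$cell_type))) {
    male <- meta$barcode[meta$cell_type == ct & meta$sex == "male"]
    female <- meta$barcode[meta$cell_type == ct & meta$sex == "female"]
    if (length(male) < min_cells || length(female) < min_cells) {
      warning("cell type '", ct, "' has fewer than ", min_cells,
              " cells in one sex; skipped")
      next
    }
    sub <- data.frame(gene = panel, cell_type = ct,
                      n_male = length(male), n_female = length(female),
                      log2fc = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(panel)) {
      xm <- norm[panel[i], male]
      xf <- norm[panel[i], female]
      sub$log2fc[i] <- log2((mean(expm1(xm)) + 1) / (mean(expm1(xf)) + 1))
      sub$p[i] <- if (stats::sd(c(xm, xf)) == 0) 1 else
        suppressWarnings(stats::wilcox.test(xm, xf)$p.value)
    }
    sub$padj <- bh_adjust(sub$p)
    rows[[length(rows) + 1]] <- sub
  }
  if (!length(rows))
    return(data.frame(gene = character(), cell_type = character()))
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$padj) & res$padj < alpha & abs(res$log2fc) > lfc
  res$direction <- ifelse(!res$significant, "none",
                          ifelse(res$log2fc > 0, "male_biased", "female_biased"))
  rownames(res) <- NULL
  res
}

#' Dot-plot data export for panel genes by cell type and sex
#'
#' For each (gene, cell type, sex): the fraction of cells expressing the
#' gene and its mean log-normalized expression.
#'
#' @inheritParams per_celltype_sex_de
#' @return data.frame with `gene`, `cell_type`, `sex`, `frac_expressing`,
#'   `mean_expression`, `n_cells`.
#' @export
dotplot_data <- function(cells, panel, scale = 1e4) {
  meta <- cells$cell_meta
  panel <- intersect(panel, rownames(cells$counts))
  norm <- log_normalize(cells, scale = scale)
  grid <- expand.grid(gene = panel, cell_type = sort(unique(meta$cell_type)),
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  grid$frac_expressing <- grid$mean_expression <- NA_real_
  grid$n_cells <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    bc <- meta$barcode[meta$cell_type == grid$cell_type[i] &
                         meta$sex == grid$sex[i]]
    grid$n_cells[i] <- length(bc)
    if (!length(bc)) next
    v <- norm[grid$gene[i], bc]
    grid$frac_expressing[i] <- mean(v > 0)
    grid$mean_expression[i] <- mean(v)
  }
  grid
}
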