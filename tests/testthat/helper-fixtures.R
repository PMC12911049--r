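# build a cell with prescribed QC attributes on a large gene universe:
# `mito` fraction of `umi` total UMIs over `feat` distinct genes
make_qc_cells <- function(specs, n_genes = 8000, n_mito = 10) {
  genes <- c(sprintf("MT-G%02d", seq_len(n_mito)),
             sprintf("G%05d", seq_len(n_genes - n_mito)))
  cols <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    mito_umi <- round(sp$mito * sp$umi)
    body_umi <- sp$umi - mito_umi
    n_body <- sp$feat - (mito_umi > 0)
    idx <- n_mito + seq_len(n_body)
    val <- rep(1, n_body)
    val[1] <- val[1] + (body_umi - n_body)
    list(i = c(if (mito_umi > 0) 1L, idx),
         x = c(if (mito_umi > 0) mito_umi, val))
  })
  trip <- do.call(rbind, lapply(seq_along(cols), function(j)
    cbind(i = cols[[j]]$i, j = j, x = cols[[j]]$x)))
  m <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                            dims = c(n_genes, length(specs)),
                            dimnames = list(genes, sprintf("c%03d", seq_along(specs))))
  cell_matrix(m, data.frame(barcode = colnames(m), sample_id = "s1",
                            sex = "male", cell_type = "t"))
}
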