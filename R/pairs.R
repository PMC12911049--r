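#' Load a validated miRNA-mRNA interaction table
#'
#' Reads a miRTarBase-style TSV with columns `mirna`, `gene`, `evidence`
#' (`direct` or `prediction_only`) and `source_id`.  Prediction-only rows
#' are dropped by default and duplicate (mirna, gene) pairs collapsed to one
#' record.
#'
#' @param path TSV file.
#' @param evidence_filter evidence classes to keep (default `"direct"`).
#' @return data.frame with one row per retained unique pair.
#' @export
load_interactions <- function(path, evidence_filter = "direct") {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(mirna = character(), gene = character(),
                      evidence = character(), source_id = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(fields[[1]][1], "mirna")
  start <- if (has_header) 2L else 1L
  if (start > length(lines))
    return(data.frame(mirna = character(), gene = character(),
                      evidence = character(), source_id = character()))
  rows <- lapply(start:length(lines), function(i) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop("malformed interaction row at line ", i, ": ", lines[i])
    data.frame(mirna = f[1], gene = f[2], evidence = f[3],
               source_id = if (length(f) >= 4) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$evidence %in% evidence_filter, , drop = FALSE]
  df <- df[!duplicated(df[, c("mirna", "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Variance-stabilizing transform (log substitute)
#'
#' `log2(count / size factor + 1)` per entry.  This is a declared substitute
#' for a fitted mean-dispersion VST: the values feed Pearson correlation
#' only, where a monotone log-scale stabilization suffices.  The transform
#' is pluggable via the `sf` argument.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param sf optional precomputed size factors (default median-of-ratios).
#' @return numeric matrix, same dimensions as the counts.
#' @export
vst_transform <- function(counts, sf = NULL) {
  m <- as_count_input(counts)
  if (is.null(sf)) sf <- size_factors(m)
  log2(sweep(m, 2, sf, "/") + 1)
}

pearson_with_p <- function(x, y) {
  n <- sum(stats::complete.cases(x, y))
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Sex-stratified correlation filter for validated pairs
#'
#' For each interaction, Pearson r and its two-sided p (t reference, n - 2
#' df) are computed separately within male and female tumor samples on
#' variance-stabilized expression.  A pair is retained when it shows a
#' significant negative correlation (`r < 0` and `p < alpha`) in at least
#' one sex.  Raw p-values are used by default, matching the stated
#' retention rule; `adjust = TRUE` applies Benjamini-Hochberg per sex as a
#' sensitivity analysis.
#'
#' @param pairs interaction data.frame (`mirna`, `gene` columns), typically
#'   already restricted to TSSB features.
#' @param mrna_vst,mirna_vst transformed expression matrices
#'   (features x samples) covering the tumor samples.
#' @param samples sample sheet; only `tissue == "tumor"` rows are used.
#' @param alpha per-sex significance threshold on the correlation p-value.
#' @param adjust BH-adjust correlation p-values within each sex first.
#' @return data.frame of pair records: per-sex r and p, `retained`,
#'   `retained_in` (`male_only`, `female_only`, `both`, `none`).
#' @export
sex_stratified_correlation <- function(pairs, mrna_vst, mirna_vst, samples,
                                       alpha = 0.05, adjust = FALSE) {
  samples <- validate_samples(samples)
  tum <- samples[samples$tissue == "tumor", , drop = FALSE]
  common <- intersect(tum$sample_id, intersect(colnames(mrna_vst), colnames(mirna_vst)))
  tum <- tum[tum$sample_id %in% common, , drop = FALSE]
  strata <- split(tum$sample_id, tum$sex)
  for (sx in c("male", "female"))
    if (length(strata[[sx]] %||% character()) < 3)
      stop("need at least 3 tumor samples per sex stratum")
  ok <- pairs$mirna %in% rownames(mirna_vst) & pairs$gene %in% rownames(mrna_vst)
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) dropped: feature absent from an expression matrix")
    pairs <- pairs[ok, , drop = FALSE]
  }
  res <- data.frame(mirna = pairs$mirna, gene = pairs$gene,
                    r_male = NA_real_, p_male = NA_real_,
                    r_female = NA_real_, p_female = NA_real_,
                    n_male = NA_integer_, n_female = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    for (sx in c("male", "female")) {
      ids <- strata[[sx]]
      st <- pearson_with_p(mirna_vst[pairs$mirna[i], ids],
                           mrna_vst[pairs$gene[i], ids])
      res[[paste0("r_", sx)]][i] <- st["r"]
      res[[paste0("p_", sx)]][i] <- st["p"]
      res[[paste0("n_", sx)]][i] <- st["n"]
    }
  }
  pm <- res$p_male; pf <- res$p_female
  if (adjust) { pm <- bh_adjust(pm); pf <- bh_adjust(pf) }
  hit_m <- !is.na(res$r_male) & res$r_male < 0 & !is.na(pm) & pm < alpha
  hit_f <- !is.na(res$r_female) & res$r_female < 0 & !is.na(pf) & pf < alpha
  res$retained <- hit_m | hit_f
  res$retained_in <- ifelse(hit_m & hit_f, "both",
                     ifelse(hit_m, "male_only",
                     ifelse(hit_f, "female_only", "none")))
  res
}

#' Classify retained pairs by direction of sex bias
#'
#' Annotates each pair with the tumor male-vs-female log2 fold changes of
#' its miRNA and gene and assigns one of four categories from the two
#' signs; pairs whose miRNA and target are biased toward opposite sexes are
#' flagged `discordant`.
#'
#' @param records pair data.frame (from [sex_stratified_correlation()]).
#' @param mirna_de,gene_de tumor DE tables with `feature` and `log2fc`.
#' @return `records` with `mirna_log2fc`, `gene_log2fc`, `category`
#'   (`F_mirna_F_gene`, `F_mirna_M_gene`, `M_mirna_F_gene`,
#'   `M_mirna_M_gene`) and `discordant` columns.
#' @export
classify_direction <- function(records, mirna_de, gene_de) {
  lfc_m <- stats::setNames(mirna_de$log2fc, mirna_de$feature)
  lfc_g <- stats::setNames(gene_de$log2fc, gene_de$feature)
  records$mirna_log2fc <- unname(lfc_m[records$mirna])
  records$gene_log2fc <- unname(lfc_g[records$gene])
  if (any(is.na(records$mirna_log2fc)) || any(is.na(records$gene_log2fc)))
    stop("pair references a feature absent from the DE tables")
  stopifnot(all(records$mirna_log2fc != 0), all(records$gene_log2fc != 0))
  msign <- ifelse(records$mirna_log2fc > 0, "M", "F")
  gsign <- ifelse(records$gene_log2fc > 0, "M", "F")
  records$category <- paste0(msign, "_mirna_", gsign, "_gene")
  records$discordant <- msign != gsign
  records
}

#' Export the miRNA-mRNA regulatory network
#'
#' Writes a SIF edge list (`mirna represses gene`), node and edge attribute
#' tables, and a GraphML file.  Node sex class comes from the fold-change
#' sign (`male`, `female`); edge class from the stratum in which the
#' negative correlation was significant.
#'
#' @param records classified pair records (retained pairs are exported).
#' @param dir output directory.
#' @param prefix file-name prefix (default `"network"`).
#' @param retained_only export only retained pairs (default TRUE).
#' @return paths of the written files, invisibly.
#' @export
export_network <- function(records, dir, prefix = "network",
                           retained_only = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (retained_only && "retained" %in% names(records))
    records <- records[records$retained, , drop = FALSE]
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(if (nrow(records))
    paste(records$mirna, "represses", records$gene, sep = "\t")
    else character(), sif)
  um <- unique(records$mirna); ug <- unique(records$gene)
  nodes <- data.frame(node = c(um, ug),
                      role = rep(c("miRNA", "gene"), c(length(um), length(ug))),
                      stringsAsFactors = FALSE)
  if ("mirna_log2fc" %in% names(records) && nrow(records)) {
    lfc <- c(stats::setNames(records$mirna_log2fc, records$mirna),
             stats::setNames(records$gene_log2fc, records$gene))
    nodes$sex_class <- ifelse(lfc[nodes$node] > 0, "male", "female")
  }
  nodes_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  edges_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(records, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  g <- if (nrow(records))
    igraph::graph_from_data_frame(records[, c("mirna", "gene")],
                                  directed = TRUE, vertices = nodes)
  else igraph::make_empty_graph(directed = TRUE)
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif = sif, nodes = nodes_path, edges = edges_path, graphml = gml))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
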