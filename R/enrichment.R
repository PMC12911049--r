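#' Read a GMT gene-set file
#'
#' Tab-separated dialect: term id, description, then member genes.  Lines
#' with fewer than three fields are rejected with the line number; genes
#' are deduplicated within a term; empty terms are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors (term id -> gene set), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) next
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each term, within a stated universe: `p = P(X >= k)` with `X ~
#' Hypergeometric(N, K, n)` where N is the universe size, K the term size
#' in the universe, n the query size in the universe and k the overlap.
#' Benjamini-Hochberg correction is applied over the tested terms; the
#' conventional reporting filter is `padj < alpha` with overlap `k >=
#' min_count`.
#'
#' @param query character vector of genes of interest.  Genes outside the
#'   universe are dropped with a warning.
#' @param sets named list of term gene sets (see [read_gmt()]).
#' @param universe background gene set (e.g. all features surviving the
#'   low-expression filter).
#' @param alpha adjusted-p threshold for the `significant` flag.
#' @param min_count minimum overlap for the `significant` flag (default 2).
#' @return data.frame sorted by `padj` with `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p`, `padj`, `overlap_genes`, `significant`.
#' @export
ora <- function(query, sets, universe, alpha = 0.05, min_count = 2) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  desc <- attr(sets, "descriptions") %||% character()
  rows <- lapply(names(sets), function(term) {
    K_genes <- intersect(sets[[term]], universe)
    K <- length(K_genes)
    if (K == 0) return(NULL)
    ov <- intersect(K_genes, query)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = if (term %in% names(desc)) desc[[term]] else term,
               k = k, K = K, n = n, N = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), padj = numeric(),
                      overlap_genes = character(), significant = logical()))
  df <- do.call(rbind, rows)
  df$padj <- bh_adjust(df$p)
  df$significant <- df$padj < alpha & df$k >= min_count
  df <- df[order(df$padj, df$p), , drop = FALSE]
  rownames(df) <- NULL
  df
}
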