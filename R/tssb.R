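#' Tumor-specific sex-biased (TSSB) feature sets
#'
#' Combines sex-DE results from tumor and normal tissue into four disjoint
#' partitions and the TSSB set.  Significant features found only in tumor
#' are `tumor_specific`; only in normal, `normal_specific`; significant in
#' both, split by agreement of the male-vs-female fold-change sign into
#' `shared_concordant` and `shared_reversed`.  The TSSB set is
#' `tumor_specific` plus `shared_reversed`: a shared feature whose sex bias
#' merely carries over from normal tissue (concordant sign) is excluded,
#' while a reversal of the normal-tissue bias is treated as tumor-intrinsic.
#'
#' @param tumor_de,normal_de DE data.frames (as from [nb_wald()]) with
#'   `feature`, `log2fc` and `significant` columns.
#' @param mode `"genes"` or `"mirnas"`; the rule is identical, the label is
#'   carried through to summaries.
#' @return object of class `tssb_set`: list with the four partitions,
#'   `tssb`, `mode`, and the input significant sets.
#' @export
build_tssb <- function(tumor_de, normal_de, mode = c("genes", "mirnas")) {
  mode <- match.arg(mode)
  for (nm in list(tumor_de, normal_de)) {
    if (!all(c("feature", "log2fc", "significant") %in% names(nm)))
      stop("DE inputs need feature, log2fc and significant columns")
    if (anyDuplicated(nm$feature)) stop("feature appears twice in a DE input")
  }
  t_sig <- tumor_de[tumor_de$significant, , drop = FALSE]
  n_sig <- normal_de[normal_de$significant, , drop = FALSE]
  shared <- intersect(t_sig$feature, n_sig$feature)
  lfc_t <- stats::setNames(t_sig$log2fc, t_sig$feature)[shared]
  lfc_n <- stats::setNames(n_sig$log2fc, n_sig$feature)[shared]
  # a significant feature always has |log2fc| > threshold > 0
  stopifnot(all(lfc_t != 0), all(lfc_n != 0))
  concord <- shared[sign(lfc_t) == sign(lfc_n)]
  reversed <- setdiff(shared, concord)
  tumor_specific <- setdiff(t_sig$feature, shared)
  normal_specific <- setdiff(n_sig$feature, shared)
  structure(list(
    tumor_specific = tumor_specific,
    normal_specific = normal_specific,
    shared_concordant = concord,
    shared_reversed = reversed,
    tssb = c(tumor_specific, reversed),
    tumor_significant = t_sig$feature,
    normal_significant = n_sig$feature,
    mode = mode), class = "tssb_set")
}

#' @export
print.tssb_set <- function(x, ...) {
  cat(sprintf(
    "tssb_set (%s): %d tumor-specific, %d normal-specific, %d shared (%d concordant / %d reversed) -> %d TSSB\n",
    x$mode, length(x$tumor_specific), length(x$normal_specific),
    length(x$shared_concordant) + length(x$shared_reversed),
    length(x$shared_concordant), length(x$shared_reversed), length(x$tssb)))
  invisible(x)
}

#' Chromosome distribution of TSSB partitions
#'
#' Cross-tabulates each partition of a [build_tssb()] result against
#' chromosome labels.  Unannotated features are counted under `"unknown"`
#' with a warning.
#'
#' @param tssb a `tssb_set`.
#' @param annotation data.frame with `feature_id` and `chromosome`, or a
#'   named character vector feature -> chromosome.
#' @return list with `counts` (partition x chromosome table) and helpers
#'   `fraction(partition, chromosomes)`.
#' @export
chromosome_distribution <- function(tssb, annotation) {
  if (is.data.frame(annotation))
    annotation <- stats::setNames(as.character(annotation$chromosome),
                                  annotation$feature_id)
  parts <- c("tumor_specific", "normal_specific",
             "shared_concordant", "shared_reversed", "tssb")
  rows <- lapply(parts, function(p) {
    f <- tssb[[p]]
    if (!length(f)) return(NULL)
    chr <- annotation[f]
    if (anyNA(chr)) {
      warning(sum(is.na(chr)), " unannotated feature(s) in ", p,
              " counted as 'unknown'")
      chr[is.na(chr)] <- "unknown"
    }
    data.frame(partition = p, chromosome = chr, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(partition = character(), chromosome = character())
  counts <- table(df$partition, df$chromosome)
  fraction <- function(partition, chromosomes) {
    sub <- df[df$partition == partition, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    mean(sub$chromosome %in% chromosomes)
  }
  list(counts = counts, fraction = fraction)
}

#' Export TSSB membership and cardinality summary
#'
#' @param tssb a `tssb_set`.
#' @param path output TSV of (feature, partition, in_tssb).
#' @param summary_path optional JSON of the partition cardinalities.
#' @return the membership data.frame, invisibly.
#' @export
write_tssb <- function(tssb, path, summary_path = NULL) {
  parts <- c("tumor_specific", "normal_specific",
             "shared_concordant", "shared_reversed")
  df <- do.call(rbind, lapply(parts, function(p)
    if (length(tssb[[p]]))
      data.frame(feature = tssb[[p]], partition = p,
                 in_tssb = tssb[[p]] %in% tssb$tssb,
                 stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(feature = character(), partition = character(),
                                    in_tssb = logical())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    card <- lapply(c(parts, "tssb"), function(p) length(tssb[[p]]))
    names(card) <- c(parts, "tssb")
    jsonlite::write_json(card, summary_path, auto_unbox = TRUE)
  }
  invisible(df)
}

#' Build DE tables with prescribed overlap cardinalities
#'
#' Constructs a pair of labeled DE tables (tumor, normal) containing the
#' requested numbers of significant features, shared features and
#' sign-concordant shared features, with arbitrary feature ids.  Used to
#' exercise the set logic at the cardinalities a cohort analysis reports.
#'
#' @param n_tumor,n_normal numbers of significant features per tissue.
#' @param n_shared number of features significant in both.
#' @param n_shared_concordant how many shared features keep the same
#'   fold-change sign in both tissues (the rest are reversed).
#' @param prefix feature-id prefix.
#' @return list with `tumor` and `normal` DE data.frames.
#' @export
tssb_cardinality_fixture <- function(n_tumor, n_normal, n_shared,
                                     n_shared_concordant, prefix = "F") {
  stopifnot(n_shared <= n_tumor, n_shared <= n_normal,
            n_shared_concordant <= n_shared)
  n_total <- n_tumor + n_normal - n_shared
  ids <- sprintf("%s%05d", prefix, seq_len(n_total))
  shared <- ids[seq_len(n_shared)]
  tumor_only <- ids[n_shared + seq_len(n_tumor - n_shared)]
  normal_only <- ids[n_tumor + seq_len(n_normal - n_shared)]
  mk <- function(features, lfc) data.frame(
    feature = features, log2fc = lfc, padj = 0.01, significant = TRUE,
    stringsAsFactors = FALSE)
  conc <- seq_len(n_shared) <= n_shared_concordant
  tumor <- mk(c(shared, tumor_only), c(rep(1, n_shared), rep(1, length(tumor_only))))
  normal <- mk(c(shared, normal_only), c(ifelse(conc, 1, -1), rep(1, length(normal_only))))
  list(tumor = tumor, normal = normal)
}
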