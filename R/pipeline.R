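#' Default run configuration
#'
#' All stage toggles, thresholds and paths of [run_pipeline()] with their
#' defaults; thresholds carry the conventional values (adjusted p 0.05,
#' |log2FC| 0.58, correlation p 0.05, enrichment minimum overlap 2).
#'
#' @param outdir output directory for every stage.
#' @param seed master seed (drives the simulate stage).
#' @param ... overrides of any default entry.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = "sexbias_run", seed = 1, ...) {
  cfg <- list(
    outdir = outdir, seed = seed,
    stages = c("simulate", "de", "tssb", "pairs", "survival", "enrichment", "sc"),
    alpha = 0.05, lfc = 0.58, correlation_alpha = 0.05,
    enrichment_min_count = 2,
    min_count = 10, min_fraction = 0.2,
    covariates_tumor = c("age", "stage", "grade"),
    covariates_normal = "age",
    # when NULL the simulate stage provides these inputs
    mrna_counts = NULL, mirna_counts = NULL, samples = NULL,
    mrna_annotation = NULL, mirna_annotation = NULL,
    interactions = NULL, gmt = NULL, sc_dir = NULL,
    cohort = list())
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$alpha <= 0 || cfg$lfc <= 0 || cfg$correlation_alpha <= 0)
    stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys mirror [run_config()] arguments.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

stage_error <- function(stage, msg) {
  stop(sprintf("[stage %s] %s (rerun from this stage after fixing inputs)",
               stage, msg), call. = FALSE)
}

#' Run the integrated sex-bias pipeline
#'
#' Executes the enabled stages in dependency order - simulate, four DE runs
#' (tumor/normal x mRNA/miRNA), TSSB set construction, pair filtering,
#' survival screening, enrichment, single-cell DE - logging the feature
#' counts surviving each filter, and writes a JSON run manifest recording
#' inputs, parameter values, output checksums, package version and seed.
#' Rerunning with an unchanged configuration reproduces every primary
#' output byte for byte.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  add_out <- function(...) outputs <<- c(outputs, ...)
  path <- function(f) file.path(config$outdir, f)
  on <- function(s) s %in% config$stages

  mrna <- mirna <- samples <- truth <- sc <- NULL
  if (on("simulate")) {
    say("simulate: building synthetic cohort (seed %d)", config$seed)
    cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
    bulk <- generate_bulk(cc)
    sv <- generate_survival(bulk$samples, bulk$mrna, bulk$truth, cc)
    bulk$samples <- sv$samples; bulk$truth <- sv$truth
    sc <- generate_sc(cc)
    write_cohort(bulk, config$outdir, sc = sc)
    add_out(path(c("mrna_counts.tsv", "mirna_counts.tsv", "samples.tsv",
                   "truth_sex_biased.tsv", "truth_pairs.tsv", "truth_risk.tsv")))
    mrna <- bulk$mrna; mirna <- bulk$mirna; samples <- bulk$samples
    truth <- bulk$truth
  } else {
    for (nm in c("mrna_counts", "mirna_counts", "samples"))
      if (is.null(config[[nm]]) || !file.exists(config[[nm]]))
        stage_error("inputs", paste0("missing ", nm, " (enable the simulate ",
                                     "stage or point ", nm, " at a file)"))
    mrna <- read_counts(config$mrna_counts, config$mrna_annotation)
    mirna <- read_counts(config$mirna_counts, config$mirna_annotation)
    samples <- read_samples(config$samples)
  }

  de <- list()
  if (on("de")) {
    for (assay in c("mrna", "mirna")) for (tis in c("tumor", "normal")) {
      cm <- if (assay == "mrna") mrna else mirna
      sub <- samples[samples$tissue == tis, , drop = FALSE]
      cm <- cm[, colnames(cm$counts) %in% sub$sample_id]
      cm <- filter_low_expression(cm, config$min_count, config$min_fraction)
      # clinical covariates enter the tumor mRNA model only: miRNA models
      # and the small normal cohort are fit without them
      cov <- if (assay == "mrna" && tis == "tumor") config$covariates_tumor
             else if (assay == "mrna") config$covariates_normal else NULL
      res <- nb_wald(cm, sub, covariates = cov,
                     alpha = config$alpha, lfc = config$lfc)
      key <- paste(assay, tis, sep = "_")
      de[[key]] <- res
      f <- path(paste0("de_", key, ".tsv"))
      utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add_out(f)
      say("de: %s %s - %d/%d features significant", assay, tis,
          sum(res$significant), nrow(res))
    }
  }

  tssb_g <- tssb_m <- NULL
  if (on("tssb")) {
    if (is.null(de$mrna_tumor)) stage_error("tssb", "missing DE results")
    tssb_g <- build_tssb(de$mrna_tumor, de$mrna_normal, "genes")
    tssb_m <- build_tssb(de$mirna_tumor, de$mirna_normal, "mirnas")
    write_tssb(tssb_g, path("tssb_genes.tsv"), path("tssb_genes_summary.json"))
    write_tssb(tssb_m, path("tssb_mirnas.tsv"), path("tssb_mirnas_summary.json"))
    add_out(path(c("tssb_genes.tsv", "tssb_mirnas.tsv")))
    say("tssb: %d TSSB genes, %d TSSB miRNAs",
        length(tssb_g$tssb), length(tssb_m$tssb))
  }

  pair_records <- NULL
  if (on("pairs")) {
    if (is.null(tssb_g)) stage_error("pairs", "missing TSSB sets")
    inter <- if (!is.null(config$interactions)) {
      load_interactions(config$interactions)
    } else if (!is.null(truth) && nrow(truth$planted_pairs)) {
      data.frame(mirna = truth$planted_pairs$mirna,
                 gene = truth$planted_pairs$gene,
                 evidence = "direct", source_id = "planted",
                 stringsAsFactors = FALSE)
    } else data.frame(mirna = character(), gene = character())
    cand <- inter[inter$mirna %in% tssb_m$tssb & inter$gene %in% tssb_g$tssb, ,
                  drop = FALSE]
    say("pairs: %d validated interactions, %d among TSSB features",
        nrow(inter), nrow(cand))
    if (nrow(cand)) {
      tum_ids <- samples$sample_id[samples$tissue == "tumor"]
      g_vst <- vst_transform(mrna[, colnames(mrna$counts) %in% tum_ids])
      m_vst <- vst_transform(mirna[, colnames(mirna$counts) %in% tum_ids])
      pair_records <- sex_stratified_correlation(cand, g_vst, m_vst, samples,
                                                 alpha = config$correlation_alpha)
      pair_records <- classify_direction(pair_records, de$mirna_tumor,
                                         de$mrna_tumor)
      f <- path("pairs.tsv")
      utils::write.table(pair_records, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_out(f)
      export_network(pair_records, config$outdir, "network")
      say("pairs: %d retained (%d discordant)", sum(pair_records$retained),
          sum(pair_records$retained & pair_records$discordant))
    }
  }

  if (on("survival")) {
    if (is.null(tssb_g)) stage_error("survival", "missing TSSB sets")
    if (!all(c("os_time", "os_status") %in% names(samples)) ||
        all(is.na(samples$os_time)))
      stage_error("survival", "sample sheet carries no survival columns")
    tum_ids <- samples$sample_id[samples$tissue == "tumor"]
    expr <- vst_transform(mrna[, colnames(mrna$counts) %in% tum_ids])
    scr <- survival_screen(tssb_g$tssb, expr, samples, alpha = config$alpha)
    f <- path("survival_calls.tsv")
    utils::write.table(scr$calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(f)
    say("survival: %d male-only, %d female-only, %d both",
        length(scr$summary$male_only), length(scr$summary$female_only),
        length(scr$summary$both))
  }

  if (on("enrichment") && !is.null(config$gmt)) {
    if (is.null(tssb_g)) stage_error("enrichment", "missing TSSB gene set")
    sets <- read_gmt(config$gmt)
    universe <- de$mrna_tumor$feature
    enr <- ora(tssb_g$tssb, sets, universe, alpha = config$alpha,
               min_count = config$enrichment_min_count)
    f <- path("enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(f)
    say("enrichment: %d/%d terms significant", sum(enr$significant), nrow(enr))
  }

  if (on("sc")) {
    cells <- if (!is.null(sc)) sc$cells
             else if (!is.null(config$sc_dir)) read_sc(config$sc_dir)
             else NULL
    if (!is.null(cells)) {
      kept <- qc_filter(cells)
      say("sc: %d/%d cells pass QC", ncol(kept$counts), ncol(cells$counts))
      panel <- if (!is.null(sc)) sc$truth$panel
               else grep("^PANEL", rownames(cells$counts), value = TRUE)
      if (length(panel)) {
        scde <- per_celltype_sex_de(kept, panel, alpha = config$alpha,
                                    lfc = config$lfc)
        f <- path("sc_de.tsv")
        utils::write.table(scde, f, sep = "\t", quote = FALSE, row.names = FALSE)
        add_out(f)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sexbias")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("alpha", "lfc", "correlation_alpha",
                          "enrichment_min_count", "min_count", "min_fraction")],
    stages = config$stages,
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
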