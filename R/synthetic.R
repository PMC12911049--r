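#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic two-sex tumor/normal cohort.  The
#' defaults state one fixed world: a cohort of 293 male and 106 female
#' tumors with 10 male and 9 female adjacent normals (the sample-size
#' asymmetry typical of bladder-cancer series), negative-binomial counts
#' with dispersion 0.1, planted sex effects of |log2FC| 1.5, miRNA-mediated
#' repression of slope -1 on the log2 scale, and exponential survival with
#' a per-day baseline hazard of 1/1000.
#'
#' @param n_male_tumor,n_female_tumor,n_male_normal,n_female_normal cohort
#'   arm sizes.
#' @param n_genes,n_mirnas numbers of bulk features.
#' @param frac_sex_biased_tumor,frac_sex_biased_normal fractions of
#'   features with a planted sex effect in each tissue.
#' @param effect_log2fc planted |log2 fold change| (male vs female).
#' @param nb_dispersion negative-binomial dispersion (variance = m +
#'   dispersion * m^2).
#' @param n_planted_pairs number of miRNA-gene pairs with planted
#'   repression.
#' @param repression_strength slope (<= 0) of the target's log2 mean on the
#'   standardized miRNA log abundance.
#' @param baseline_hazard,survival_beta,censor_rate exponential survival
#'   model: per-day baseline hazard, per-SD log-hazard of a risk feature,
#'   independent exponential censoring rate.
#' @param confounded if TRUE, age/stage/grade are generated sex-dependent
#'   (to exercise covariate adjustment); independent of sex by default.
#' @param chromosome_probs probabilities of autosome / X / Y assignment.
#' @param baseline_meanlog,baseline_sdlog log-normal feature baselines.
#' @param depth_sdlog log-normal spread of per-sample depth factors.
#' @param sc_n_male,sc_n_female,sc_cells_per_sample,sc_n_genes,sc_n_mito,
#'   sc_panel_size,sc_cell_types,sc_effect_log2fc,sc_qc_violation_frac
#'   single-cell generator: samples per sex, cells and genes, number of
#'   mitochondrial genes, size of the sex-biased gene panel, cell-type
#'   labels, planted per-type |log2FC| and fraction of cells built to
#'   violate QC thresholds.
#' @param seed master integer seed; each generator draws from its own
#'   substream so adding one never perturbs another.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_male_tumor = 293, n_female_tumor = 106,
                          n_male_normal = 10, n_female_normal = 9,
                          n_genes = 1000, n_mirnas = 200,
                          frac_sex_biased_tumor = 0.05,
                          frac_sex_biased_normal = 0.02,
                          effect_log2fc = 1.5, nb_dispersion = 0.1,
                          n_planted_pairs = 20, repression_strength = -1,
                          baseline_hazard = 1 / 1000, survival_beta = 0.8,
                          censor_rate = 1 / 2000,
                          confounded = FALSE,
                          chromosome_probs = c(autosome = 0.90, X = 0.07, Y = 0.03),
                          baseline_meanlog = log(100), baseline_sdlog = 1.5,
                          depth_sdlog = 0.3,
                          sc_n_male = 4, sc_n_female = 2,
                          sc_cells_per_sample = 250, sc_n_genes = 400,
                          sc_n_mito = 10, sc_panel_size = 13,
                          sc_cell_types = c("Epithelial", "T cells", "B cells",
                                            "Endothelial", "iCAF", "mCAF"),
                          sc_effect_log2fc = NULL,
                          sc_qc_violation_frac = 0.05,
                          seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$sc_effect_log2fc)) cfg$sc_effect_log2fc <- cfg$effect_log2fc
  counts <- c("n_male_tumor", "n_female_tumor", "n_male_normal",
              "n_female_normal", "n_genes", "n_mirnas",
              "sc_n_male", "sc_n_female", "sc_cells_per_sample", "sc_n_genes")
  for (nm in counts)
    if (cfg[[nm]] <= 0 || cfg[[nm]] != round(cfg[[nm]]))
      stop(nm, " must be a positive integer")
  for (nm in c("frac_sex_biased_tumor", "frac_sex_biased_normal",
               "sc_qc_violation_frac"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$effect_log2fc <= 0) stop("effect_log2fc must be > 0")
  if (cfg$repression_strength > 0) stop("repression_strength must be <= 0")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$censor_rate < 0) stop("censor_rate must be >= 0")
  if (abs(sum(cfg$chromosome_probs) - 1) > 1e-8)
    stop("chromosome_probs must sum to 1")
  if (abs(cfg$seed) >= 2^30) stop("seed must be below 2^30 in magnitude")
  structure(cfg, class = "cohort_config")
}

draw_chromosomes <- function(n, probs) {
  cls <- sample(c("autosome", "X", "Y"), n, replace = TRUE, prob = probs)
  out <- character(n)
  out[cls == "autosome"] <- paste0("chr", sample(1:22, sum(cls == "autosome"),
                                                 replace = TRUE))
  out[cls == "X"] <- "chrX"
  out[cls == "Y"] <- "chrY"
  out
}

# sample sheet for the bulk cohort; clinical covariates independent of sex
# unless confounded mode is requested
make_sample_table <- function(cfg) {
  n <- c(cfg$n_male_tumor, cfg$n_female_tumor, cfg$n_male_normal,
         cfg$n_female_normal)
  sex <- rep(c("male", "female", "male", "female"), n)
  tissue <- rep(c("tumor", "tumor", "normal", "normal"), n)
  ntot <- sum(n)
  age_shift <- if (cfg$confounded) ifelse(sex == "male", 5, 0) else 0
  age <- round(pmin(pmax(stats::rnorm(ntot, 67 + age_shift, 10), 30), 95))
  stage_probs <- c(0.15, 0.3, 0.35, 0.2)
  stage <- sample(1:4, ntot, replace = TRUE, prob = stage_probs)
  if (cfg$confounded)
    stage <- pmin(stage + ifelse(sex == "male", stats::rbinom(ntot, 1, 0.3), 0), 4)
  grade <- sample(1:3, ntot, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  stage[tissue == "normal"] <- NA
  grade[tissue == "normal"] <- NA
  data.frame(sample_id = sprintf("S%04d", seq_len(ntot)), sex = sex,
             tissue = tissue, age = age, stage = stage, grade = grade,
             os_time = NA_real_, os_status = NA_integer_,
             stringsAsFactors = FALSE)
}

# NB count block for one feature class: log2 mean = baseline + sex effect
# (tissue-restricted) + optional repression term; returns counts and truth
simulate_counts <- function(ids, chrom, biotype, samples, cfg, frac_tumor,
                            frac_normal, depth) {
  nf <- length(ids); ns <- nrow(samples)
  base <- stats::rlnorm(nf, cfg$baseline_meanlog, cfg$baseline_sdlog)
  n_bt <- round(frac_tumor * nf); n_bn <- round(frac_normal * nf)
  bt <- sample(nf, n_bt)
  bn <- sample(nf, n_bn)
  sgn_t <- sample(c(-1, 1), n_bt, replace = TRUE)
  sgn_n <- sample(c(-1, 1), n_bn, replace = TRUE)
  male <- samples$sex == "male"
  tumor <- samples$tissue == "tumor"
  l2 <- matrix(rep(log2(base), ns), nf, ns)   # feature x sample log2 mean
  half <- cfg$effect_log2fc / 2
  if (n_bt) {
    eff <- matrix(0, n_bt, ns)
    eff[, male & tumor] <- half * sgn_t
    eff[, !male & tumor] <- -half * sgn_t
    l2[bt, ] <- l2[bt, ] + eff
  }
  if (n_bn) {
    eff <- matrix(0, n_bn, ns)
    eff[, male & !tumor] <- half * sgn_n
    eff[, !male & !tumor] <- -half * sgn_n
    l2[bn, ] <- l2[bn, ] + eff
  }
  truth <- rbind(
    if (n_bt) data.frame(feature = ids[bt], tissue = "tumor",
                         log2fc = sgn_t * cfg$effect_log2fc),
    if (n_bn) data.frame(feature = ids[bn], tissue = "normal",
                         log2fc = sgn_n * cfg$effect_log2fc))
  if (is.null(truth)) truth <- data.frame(feature = character(),
                                          tissue = character(),
                                          log2fc = numeric())
  ann <- data.frame(feature_id = ids, chromosome = chrom, biotype = biotype,
                    stringsAsFactors = FALSE)
  list(log2_mean = l2, truth = truth, annotation = ann, depth = depth)
}

finalize_counts <- function(ids, samples, log2_mean, depth, cfg, annotation) {
  mu <- sweep(2^log2_mean, 2, depth, "*")
  cts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                nrow(mu), ncol(mu))
  dimnames(cts) <- list(ids, samples$sample_id)
  count_matrix(cts, annotation)
}

#' Generate a bulk synthetic cohort with planted ground truth
#'
#' Draws mRNA and miRNA counts from a negative binomial whose mean is
#' `depth x baseline x 2^(sex effect)`, with sex effects planted in the
#' designated tissue only.  For each planted miRNA-gene pair the target's
#' log2 mean in tumor samples is shifted by `repression_strength` times the
#' standardized miRNA log abundance, inducing the negative expression
#' correlation that miRNA-mediated repression leaves in real data.  A fixed
#' seed reproduces the matrices bit for bit.
#'
#' @param config a [cohort_config()].
#' @return list with `mrna`, `mirna` ([count_matrix()]), `samples`
#'   (sample sheet) and `truth` (list: `sex_biased`, `planted_pairs`,
#'   `risk_features`, `chromosome_map`).
#' @export
generate_bulk <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(substream(config$seed, 1), {
    samples <- make_sample_table(config)
    ns <- nrow(samples)
    depth <- stats::rlnorm(ns, 0, config$depth_sdlog)
    gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))
    mir_ids <- sprintf("hsa-mir-%04d", seq_len(config$n_mirnas))
    gene_chr <- draw_chromosomes(config$n_genes, config$chromosome_probs)
    mir_chr <- draw_chromosomes(config$n_mirnas, config$chromosome_probs)

    gsim <- simulate_counts(gene_ids, gene_chr, "protein_coding", samples,
                            config, config$frac_sex_biased_tumor,
                            config$frac_sex_biased_normal, depth)
    msim <- simulate_counts(mir_ids, mir_chr, "miRNA", samples, config,
                            config$frac_sex_biased_tumor,
                            config$frac_sex_biased_normal, depth)
    # miRNA counts are realized first so the repression term can condition
    # on the actual miRNA abundance seen by each sample
    mirna <- finalize_counts(mir_ids, samples, msim$log2_mean, depth, config,
                             msim$annotation)
    n_pairs <- min(config$n_planted_pairs, config$n_genes, config$n_mirnas)
    planted <- data.frame(mirna = character(), gene = character(),
                          repression_strength = numeric())
    if (n_pairs > 0 && config$repression_strength < 0) {
      pg <- sample(config$n_genes, n_pairs)
      pm <- sample(config$n_mirnas, n_pairs, replace = n_pairs > config$n_mirnas)
      tumor <- samples$tissue == "tumor"
      for (k in seq_len(n_pairs)) {
        la <- log2(mirna$counts[pm[k], tumor] / depth[tumor] + 1)
        z <- if (stats::sd(la) > 0) (la - mean(la)) / stats::sd(la) else la * 0
        gsim$log2_mean[pg[k], tumor] <- gsim$log2_mean[pg[k], tumor] +
          config$repression_strength * z
      }
      planted <- data.frame(mirna = mir_ids[pm], gene = gene_ids[pg],
                            repression_strength = config$repression_strength,
                            stringsAsFactors = FALSE)
    }
    mrna <- finalize_counts(gene_ids, samples, gsim$log2_mean, depth, config,
                            gsim$annotation)
    gsim$truth$assay <- rep("mrna", nrow(gsim$truth))
    msim$truth$assay <- rep("mirna", nrow(msim$truth))
    truth <- list(
      sex_biased = rbind(gsim$truth, msim$truth),
      planted_pairs = planted,
      risk_features = data.frame(feature = character(), stratum = character(),
                                 survival_beta = numeric()),
      chromosome_map = stats::setNames(c(gene_chr, mir_chr),
                                       c(gene_ids, mir_ids)))
    list(mrna = mrna, mirna = mirna, samples = samples, truth = truth)
  })
}

#' Plant sex-specific survival on a generated cohort
#'
#' Fills `os_time` / `os_status` of the tumor samples: event times are
#' exponential with log hazard `log(baseline_hazard) + sum(beta_f * z_f)`
#' where `z_f` is the standardized log2 expression of risk feature `f`, the
#' sum running only over features whose designated sex stratum matches the
#' sample; censoring is an independent exponential.  Normal samples keep
#' missing survival (adjacent tissue carries no follow-up of its own).
#'
#' @param samples sample sheet from [generate_bulk()].
#' @param expression a [count_matrix()] carrying the risk features.
#' @param truth truth list; its `risk_features` slot is replaced.
#' @param risk_features data.frame (`feature`, `stratum`, `survival_beta`);
#'   default draws `n_risk` features with the config-style beta.
#' @param config the [cohort_config()] (hazard, censoring, beta, seed).
#' @param n_risk number of risk features drawn when `risk_features` is
#'   missing (default 5, male stratum).
#' @return list with the updated `samples` and `truth`.
#' @export
generate_survival <- function(samples, expression, truth, config,
                              risk_features = NULL, n_risk = 5) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  with_seed(substream(config$seed, 2), {
    if (is.null(risk_features)) {
      feats <- sample(rownames(expression$counts), n_risk)
      risk_features <- data.frame(feature = feats, stratum = "male",
                                  survival_beta = config$survival_beta,
                                  stringsAsFactors = FALSE)
    }
    missing_f <- setdiff(risk_features$feature, rownames(expression$counts))
    if (length(missing_f))
      stop("risk feature(s) absent from expression: ",
           paste(missing_f, collapse = ", "))
    tumor <- which(samples$tissue == "tumor")
    lp <- numeric(length(tumor))
    lexpr <- log2(expression$counts[, samples$sample_id[tumor], drop = FALSE] + 1)
    for (i in seq_len(nrow(risk_features))) {
      v <- lexpr[risk_features$feature[i], ]
      z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
      in_stratum <- samples$sex[tumor] == risk_features$stratum[i]
      lp <- lp + risk_features$survival_beta[i] * z * in_stratum
    }
    rate <- config$baseline_hazard * exp(lp)
    event <- stats::rexp(length(tumor), rate)
    cens <- if (config$censor_rate > 0)
      stats::rexp(length(tumor), config$censor_rate) else rep(Inf, length(tumor))
    samples$os_time[tumor] <- round(pmin(event, cens), 2)
    samples$os_status[tumor] <- as.integer(event <= cens)
    truth$risk_features <- risk_features
    list(samples = samples, truth = truth)
  })
}

#' Generate a synthetic single-cell cohort
#'
#' Builds a genes x cells UMI matrix over a handful of named cell types for
#' `sc_n_male` male and `sc_n_female` female tumor samples.  Per-cell
#' depths are log-normal around 3000 UMIs; mitochondrial genes carry about
#' 5% of each healthy cell's mass.  Sex effects of `sc_effect_log2fc` are
#' planted on the panel genes within a drawn subset of cell types.  A
#' fraction `sc_qc_violation_frac` of cells is built to violate one QC
#' threshold each (high mitochondrial load, shallow depth, or collapsed
#' feature support).
#'
#' @param config a [cohort_config()].
#' @return list with `cells` (a [cell_matrix()]) and `truth`
#'   (`panel`, `biased_types`, `violators`).
#' @export
generate_sc <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(substream(config$seed, 3), {
    ng <- config$sc_n_genes
    n_mito <- config$sc_n_mito
    genes <- c(sprintf("MT-G%02d", seq_len(n_mito)),
               sprintf("PANEL%02d", seq_len(config$sc_panel_size)),
               sprintf("SCG%04d", seq_len(ng - n_mito - config$sc_panel_size)))
    panel <- genes[startsWith(genes, "PANEL")]
    types <- config$sc_cell_types
    n_samples <- config$sc_n_male + config$sc_n_female
    sample_ids <- sprintf("SC%02d", seq_len(n_samples))
    sample_sex <- rep(c("male", "female"), c(config$sc_n_male, config$sc_n_female))

    base <- stats::rlnorm(ng, 0, 1)
    base[seq_len(n_mito)] <- sum(base) * 0.05 / n_mito / (1 - 0.05)
    # mild cell-type structure: each type overexpresses a random gene block
    type_mult <- sapply(types, function(t) {
      m <- rep(1, ng); m[sample(ng, 40)] <- 4; m
    })
    biased_types <- sample(types, max(1, ceiling(length(types) / 2)))
    eff <- config$sc_effect_log2fc

    n_cells_total <- n_samples * config$sc_cells_per_sample
    counts <- matrix(0L, ng, 0)
    bc <- character(0); meta <- list()
    depths <- round(stats::rlnorm(n_cells_total, log(3000), 0.3))
    cell_type <- sample(types, n_cells_total, replace = TRUE)
    cell_sample <- rep(sample_ids, each = config$sc_cells_per_sample)
    cell_sex <- rep(sample_sex, each = config$sc_cells_per_sample)
    n_viol <- round(config$sc_qc_violation_frac * n_cells_total)
    violators <- if (n_viol) sample(n_cells_total, n_viol) else integer(0)
    viol_kind <- sample(c("mito", "depth", "features"), n_viol, replace = TRUE)

    cols <- vector("list", n_cells_total)
    for (i in seq_len(n_cells_total)) {
      p <- base * type_mult[, cell_type[i]]
      if (cell_type[i] %in% biased_types && eff > 0) {
        shift <- 2^(ifelse(cell_sex[i] == "male", eff / 2, -eff / 2))
        p[match(panel, genes)] <- p[match(panel, genes)] * shift
      }
      d <- depths[i]
      k <- match(i, violators)
      if (!is.na(k)) {
        if (viol_kind[k] == "mito") {
          mfrac <- stats::runif(1, 0.12, 0.35)
          p[seq_len(n_mito)] <- sum(p[-seq_len(n_mito)]) * mfrac / (1 - mfrac) / n_mito
        } else if (viol_kind[k] == "depth") {
          d <- sample(200:900, 1)
        } else {
          keep <- sample(ng, 50)   # support of 50 genes caps n_features < 300
          p[-keep] <- 0
        }
      }
      cols[[i]] <- stats::rmultinom(1, d, p)[, 1]
    }
    m <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    rownames(m) <- genes
    colnames(m) <- sprintf("CELL%05d", seq_len(n_cells_total))
    cm <- cell_matrix(m, data.frame(barcode = colnames(m),
                                    sample_id = cell_sample, sex = cell_sex,
                                    cell_type = cell_type,
                                    stringsAsFactors = FALSE))
    viol_df <- data.frame(barcode = colnames(m)[violators],
                          kind = viol_kind, stringsAsFactors = FALSE)
    list(cells = cm,
         truth = list(panel = panel, biased_types = biased_types,
                      violators = viol_df))
  })
}

#' Write all artifacts of a simulated cohort to disk
#'
#' Count TSVs, annotation TSVs, sample sheet, truth tables and (optionally)
#' the single-cell MTX triplet.
#'
#' @param bulk result of [generate_bulk()] (possibly after
#'   [generate_survival()] updated `samples`/`truth`).
#' @param outdir output directory.
#' @param sc optional result of [generate_sc()].
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(bulk, outdir, sc = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_counts(bulk$mrna, file.path(outdir, "mrna_counts.tsv"),
               file.path(outdir, "mrna_annotation.tsv"))
  write_counts(bulk$mirna, file.path(outdir, "mirna_counts.tsv"),
               file.path(outdir, "mirna_annotation.tsv"))
  write_samples(bulk$samples, file.path(outdir, "samples.tsv"))
  utils::write.table(bulk$truth$sex_biased,
                     file.path(outdir, "truth_sex_biased.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bulk$truth$planted_pairs,
                     file.path(outdir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bulk$truth$risk_features,
                     file.path(outdir, "truth_risk.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sc)) write_sc(sc$cells, file.path(outdir, "sc"))
  invisible(outdir)
}
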