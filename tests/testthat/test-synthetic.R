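test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(n_genes = 0), "positive integer")
  expect_error(cohort_config(frac_sex_biased_tumor = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cohort_config(repression_strength = 0.5), "repression_strength")
  expect_error(cohort_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(cohort_config(seed = 2^31), "2\\^30")
})

test_that("all three generators are bit-identical under a fixed seed", {
  cc <- cohort_config(n_male_tumor = 15, n_female_tumor = 15,
                      n_male_normal = 4, n_female_normal = 4,
                      n_genes = 40, n_mirnas = 10, sc_cells_per_sample = 30,
                      sc_n_genes = 60, seed = 123)
  b1 <- generate_bulk(cc); b2 <- generate_bulk(cc)
  expect_identical(b1$mrna$counts, b2$mrna$counts)
  expect_identical(b1$mirna$counts, b2$mirna$counts)
  expect_identical(b1$truth, b2$truth)
  s1 <- generate_survival(b1$samples, b1$mrna, b1$truth, cc)
  s2 <- generate_survival(b2$samples, b2$mrna, b2$truth, cc)
  expect_identical(s1$samples, s2$samples)
  sc1 <- generate_sc(cc); sc2 <- generate_sc(cc)
  expect_identical(sc1$cells$counts, sc2$cells$counts)
  # a different seed changes the data
  b3 <- generate_bulk(cohort_config(n_male_tumor = 15, n_female_tumor = 15,
                                    n_male_normal = 4, n_female_normal = 4,
                                    n_genes = 40, n_mirnas = 10, seed = 124))
  expect_false(identical(b1$mrna$counts, b3$mrna$counts))
})

test_that("generated counts match negative-binomial moments", {
  cc <- cohort_config(n_male_tumor = 60, n_female_tumor = 60,
                      n_male_normal = 2, n_female_normal = 2,
                      n_genes = 150, n_mirnas = 5,
                      frac_sex_biased_tumor = 0, frac_sex_biased_normal = 0,
                      n_planted_pairs = 0, nb_dispersion = 0.1,
                      baseline_meanlog = log(200), baseline_sdlog = 0,
                      depth_sdlog = 0, seed = 6)
  b <- generate_bulk(cc)
  x <- as.numeric(b$mrna$counts)   # > 1.8e4 iid NB(mu = 200, phi = 0.1) draws
  m <- mean(x); v <- var(x)
  expect_equal(m, 200, tolerance = 0.02)
  expect_equal(v, 200 + 0.1 * 200^2, tolerance = 0.1)
})

test_that("planted repression induces negative pair correlations", {
  neg <- 0; tot <- 0
  for (s in 1:10) {
    cc <- cohort_config(n_male_tumor = 60, n_female_tumor = 60,
                        n_male_normal = 2, n_female_normal = 2,
                        n_genes = 60, n_mirnas = 20, n_planted_pairs = 8,
                        repression_strength = -1, nb_dispersion = 0.05,
                        frac_sex_biased_tumor = 0, frac_sex_biased_normal = 0,
                        seed = 200 + s)
    b <- generate_bulk(cc)
    tum <- b$samples$sample_id[b$samples$tissue == "tumor"]
    gv <- vst_transform(b$mrna[, tum]); mv <- vst_transform(b$mirna[, tum])
    pp <- b$truth$planted_pairs
    r <- vapply(seq_len(nrow(pp)), function(i)
      cor(gv[pp$gene[i], ], mv[pp$mirna[i], ]), numeric(1))
    neg <- neg + sum(r < 0); tot <- tot + length(r)
  }
  expect_gte(neg / tot, 0.9)
})

test_that("survival generation follows its limit cases and recovers beta", {
  cc <- cohort_config(n_male_tumor = 150, n_female_tumor = 150,
                      n_male_normal = 2, n_female_normal = 2,
                      n_genes = 30, n_mirnas = 5, n_planted_pairs = 0,
                      censor_rate = 1e6, seed = 17)
  b <- generate_bulk(cc)
  sv <- generate_survival(b$samples, b$mrna, b$truth, cc)
  # censor rate >> hazard: everyone censored
  expect_true(all(sv$samples$os_status[sv$samples$tissue == "tumor"] == 0))
  expect_true(all(is.na(sv$samples$os_status[sv$samples$tissue == "normal"])))
  expect_error(
    generate_survival(b$samples, b$mrna, b$truth, cc,
                      risk_features = data.frame(feature = "NOPE",
                                                 stratum = "male",
                                                 survival_beta = 1)),
    "absent")

  # null effect: Cox recovers beta ~ 0; planted 0.8 recovered within +-0.25
  betas_null <- betas <- numeric(0)
  for (s in 1:20) {
    cc2 <- cohort_config(n_male_tumor = 300, n_female_tumor = 2,
                         n_male_normal = 2, n_female_normal = 2,
                         n_genes = 10, n_mirnas = 5, n_planted_pairs = 0,
                         frac_sex_biased_tumor = 0, censor_rate = 1 / 4000,
                         seed = 300 + s)
    b2 <- generate_bulk(cc2)
    rf <- data.frame(feature = "GENE00003", stratum = "male",
                     survival_beta = 0.8)
    sv2 <- generate_survival(b2$samples, b2$mrna, b2$truth, cc2,
                             risk_features = rf)
    males <- sv2$samples[sv2$samples$tissue == "tumor" &
                           sv2$samples$sex == "male", ]
    lx <- log2(b2$mrna$counts["GENE00003", males$sample_id] + 1)
    z <- (lx - mean(lx)) / sd(lx)
    fit <- cox_univariate(males$os_time, males$os_status, z)
    betas <- c(betas, fit$beta)
    # an all-null hazard (beta = 0) must be recovered as beta ~ 0
    sv0 <- generate_survival(b2$samples, b2$mrna, b2$truth, cc2,
                             risk_features = transform(rf, survival_beta = 0))
    males0 <- sv0$samples[sv0$samples$tissue == "tumor" &
                            sv0$samples$sex == "male", ]
    betas_null <- c(betas_null, cox_univariate(males0$os_time,
                                               males0$os_status, z)$beta)
  }
  expect_lt(abs(mean(betas) - 0.8), 0.25)
  expect_gt(mean(abs(betas - 0.8) <= 0.25), 0.8)
  expect_lt(abs(mean(betas_null)), 0.1)
})

test_that("cohort round-trips through the on-disk layout", {
  cc <- cohort_config(n_male_tumor = 8, n_female_tumor = 8,
                      n_male_normal = 3, n_female_normal = 3,
                      n_genes = 25, n_mirnas = 8, sc_cells_per_sample = 20,
                      sc_n_genes = 50, seed = 55)
  b <- generate_bulk(cc)
  sv <- generate_survival(b$samples, b$mrna, b$truth, cc)
  b$samples <- sv$samples
  dir <- withr::local_tempdir()
  write_cohort(b, dir, sc = generate_sc(cc))
  m2 <- read_counts(file.path(dir, "mrna_counts.tsv"),
                    file.path(dir, "mrna_annotation.tsv"))
  expect_equal(m2$counts, b$mrna$counts)
  expect_equal(m2$annotation, b$mrna$annotation)
  s2 <- read_samples(file.path(dir, "samples.tsv"))
  expect_equal(s2$os_time, b$samples$os_time)
  sc <- generate_sc(cc)
  sc2 <- read_sc(file.path(dir, "sc"))
  expect_equal(dim(sc2$counts), c(50, 6 * 20))
  expect_equal(as.matrix(sc2$counts), as.matrix(sc$cells$counts))
  expect_equal(sc2$cell_meta$mito_fraction, sc$cells$cell_meta$mito_fraction,
               tolerance = 1e-9)
})
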