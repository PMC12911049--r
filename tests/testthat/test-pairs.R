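write_interactions <- function(rows, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- vapply(rows, paste, character(1), collapse = "\t")
  if (header) lines <- c("mirna\tgene\tevidence\tsource_id", lines)
  writeLines(lines, path)
  path
}

test_that("interaction loading filters evidence and collapses duplicates", {
  p <- write_interactions(list(
    c("miR-1", "G1", "direct", "MIRT1"),
    c("miR-1", "G1", "direct", "MIRT1b"),
    c("miR-2", "G2", "prediction_only", "MIRT2"),
    c("miR-3", "G3", "direct", "MIRT3")))
  tab <- load_interactions(p)
  expect_equal(nrow(tab), 2)
  expect_false("miR-2" %in% tab$mirna)
  expect_error(load_interactions(write_interactions(list(c("miR-9", "G9")))),
               "line 2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_interactions(empty)), 0)
})

test_that("the VST substitute satisfies its closed forms and monotonicity", {
  m <- matrix(c(0, 7, 3, 15), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  v <- vst_transform(m, sf = c(1, 1))
  expect_equal(v["g1", "s1"], 0)
  expect_equal(v["g2", "s1"], 3)   # log2(7 + 1)
  set.seed(1)
  r <- matrix(rpois(200, 30), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  v <- vst_transform(r)
  for (s in 1:10) expect_true(all(diff(v[order(r[, s]), s]) >= -1e-12))
})

make_corr_fixture <- function() {
  # male stratum carries the hand-computable 4-point profile, female a flat one
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    sex = rep(c("male", "female"), each = 4),
    tissue = "tumor", stringsAsFactors = FALSE)
  mir <- rbind(m1 = c(1, 2, 3, 4, 1, 2, 3, 4))
  gene <- rbind(g1 = c(2, 1, 4, 3, 5, 5, 5, 5))
  colnames(mir) <- colnames(gene) <- samples$sample_id
  list(samples = samples, mir = mir, gene = gene)
}

test_that("sex-stratified Pearson matches hand computation and retention rule", {
  fx <- make_corr_fixture()
  pairs <- data.frame(mirna = "m1", gene = "g1")
  rec <- sex_stratified_correlation(pairs, fx$gene, fx$mir, fx$samples)
  expect_equal(rec$r_male, 0.6)                 # hand Pearson on the 4 points
  expect_true(is.na(rec$r_female))              # zero variance stratum
  expect_false(rec$retained)                    # r > 0 never retained
  # perfect anticorrelation in one stratum retains the pair there
  fx$gene["g1", 1:4] <- c(6, 4, 2, 0)
  rec2 <- sex_stratified_correlation(pairs, fx$gene, fx$mir, fx$samples)
  expect_equal(rec2$r_male, -1)
  expect_true(rec2$retained)
  expect_equal(rec2$retained_in, "male_only")
})

test_that("retention requires a significant negative correlation in >= 1 sex", {
  set.seed(77)
  samples <- data.frame(sample_id = paste0("s", 1:60),
                        sex = rep(c("male", "female"), each = 30),
                        tissue = "tumor")
  x <- rnorm(60)
  mir <- rbind(m1 = x)
  gene <- rbind(g1 = c(-0.9 * x[1:30] + rnorm(30, 0, 0.3), rnorm(30)))
  colnames(mir) <- colnames(gene) <- samples$sample_id
  rec <- sex_stratified_correlation(data.frame(mirna = "m1", gene = "g1"),
                                    gene, mir, samples)
  expect_true(rec$retained)
  expect_equal(rec$retained_in, "male_only")
  expect_lt(rec$p_male, 0.05)
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(5)
  samples <- data.frame(sample_id = paste0("s", 1:24),
                        sex = rep(c("male", "female"), each = 12),
                        tissue = "tumor")
  for (rep_i in 1:20) {
    x <- rnorm(12); y <- 0.4 * x + rnorm(12)
    mir <- rbind(m1 = c(x, rnorm(12)))
    gene <- rbind(g1 = c(y, rnorm(12)))
    colnames(mir) <- colnames(gene) <- samples$sample_id
    rec <- sex_stratified_correlation(data.frame(mirna = "m1", gene = "g1"),
                                      gene, mir, samples)
    r_obs <- abs(rec$r_male)
    perm <- replicate(1e4, abs(cor(x, sample(y))))
    p_perm <- mean(perm >= r_obs - 1e-12)
    expect_lt(abs(rec$p_male - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 1e4) + 5e-3)
  }
})

test_that("direction classification is exhaustive over sign combinations", {
  rec <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                    gene = c("g1", "g2", "g3", "g4"),
                    retained = TRUE, stringsAsFactors = FALSE)
  mirna_de <- data.frame(feature = paste0("m", 1:4),
                         log2fc = c(1.2, 0.8, -0.7, -1.1))
  gene_de <- data.frame(feature = paste0("g", 1:4),
                        log2fc = c(-0.9, 1.0, 0.8, -0.6))
  out <- classify_direction(rec, mirna_de, gene_de)
  expect_equal(out$category, c("M_mirna_F_gene", "M_mirna_M_gene",
                               "F_mirna_M_gene", "F_mirna_F_gene"))
  expect_equal(out$discordant, c(TRUE, FALSE, TRUE, FALSE))
  expect_length(unique(out$category), 4)
  expect_error(classify_direction(
    data.frame(mirna = "mX", gene = "g1"), mirna_de, gene_de), "absent")
})

test_that("network export writes consistent SIF, attribute and GraphML files", {
  dir <- withr::local_tempdir()
  empty <- data.frame(mirna = character(), gene = character(),
                      retained = logical())
  files <- export_network(empty, dir, "empty")
  expect_identical(readLines(files["sif"]), character(0))

  set.seed(12)
  n <- 82
  rec <- data.frame(mirna = sprintf("miR-%02d", sample(30, n, replace = TRUE)),
                    gene = sprintf("G%03d", 1:n), retained = TRUE,
                    mirna_log2fc = rnorm(n), gene_log2fc = rnorm(n),
                    stringsAsFactors = FALSE)
  files <- export_network(rec, dir, "net")
  sif <- readLines(files["sif"])
  expect_length(sif, 82)
  nodes <- read.delim(files["nodes"])
  expect_equal(nrow(nodes), length(unique(rec$mirna)) + length(unique(rec$gene)))
  g <- igraph::read_graph(files["graphml"], format = "graphml")
  expect_equal(igraph::ecount(g), 82)
  expect_equal(igraph::vcount(g), nrow(nodes))
})
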