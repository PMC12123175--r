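# small dense fixture: two conditions, one planted fold change
toy_sce <- function(n_genes = 60, n_cells = 400, planted_gene = 1,
                    effect = 2, seed = 1, mu = 1) {
  set.seed(seed)
  conds <- rep(c("t", "c"), each = n_cells / 2)
  mu_mat <- matrix(mu, n_genes, n_cells)
  mu_mat[planted_gene, conds == "t"] <- mu * effect
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu_mat, size = 2),
                   n_genes, n_cells)
  make_cell_matrix(counts, data.frame(
    cell_id = sprintf("c%04d", seq_len(n_cells)),
    sample_id = paste0("s_", conds), condition = conds,
    percent_mito = 1, percent_ribo = 1, stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
               symbol = sprintf("g%03d", seq_len(n_genes)),
               stringsAsFactors = FALSE))
}

test_that("QC removes rule violators and keeps boundary cells", {
  set.seed(61)
  counts <- matrix(rpois(50 * 300, 5), 50, 300)
  counts[counts == 0] <- 1  # every gene detected: n_features = 50
  meta <- data.frame(cell_id = sprintf("c%03d", 1:300), sample_id = "s1",
                     condition = "t", percent_mito = 1, percent_ribo = 1,
                     stringsAsFactors = FALSE)
  sce <- make_cell_matrix(counts, meta,
                          data.frame(gene_id = sprintf("g%02d", 1:50),
                                     symbol = sprintf("g%02d", 1:50)))
  # absolute rules: mito 6 out, ribo 5 exactly stays ("above 5" is strict)
  cd <- SummarizedExperiment::colData(sce)
  cd$percent_mito[1] <- 6; cd$percent_ribo[2] <- 5
  SummarizedExperiment::colData(sce) <- cd
  out <- qc_filter(sce, min_features = 10, nfeat_sd = Inf)
  expect_false("c001" %in% colnames(out))
  expect_true("c002" %in% colnames(out))
  # feature floor: exactly min_features is retained ("below" is strict)
  out2 <- qc_filter(sce[, 3:300], min_features = 50, nfeat_sd = Inf)
  expect_equal(ncol(out2), 298)
  # sample-relative upper rule on a constructed high-feature outlier
  counts2 <- matrix(0L, 100, 60)
  for (j in 1:59) counts2[sample(100, 50), j] <- 3L
  counts2[, 60] <- 3L  # detects all 100 genes
  meta2 <- data.frame(cell_id = sprintf("h%03d", 1:60), sample_id = "s1",
                      condition = "t", percent_mito = 1, percent_ribo = 1,
                      stringsAsFactors = FALSE)
  sce2 <- make_cell_matrix(counts2, meta2,
                           data.frame(gene_id = sprintf("G%03d", 1:100),
                                      symbol = sprintf("G%03d", 1:100)))
  out3 <- qc_filter(sce2, min_features = 10, nfeat_sd = 2)
  expect_false("h060" %in% colnames(out3))
  expect_true("h060" %in%
                S4Vectors::metadata(out3)$qc_report$by_rule$high_features)
})

test_that("QC recovers exactly the planted violators of the absolute rules", {
  g <- gen_sc_counts(sim_config(seed = 67, sc = list(
    n_cells_per_condition = 200, n_genes = 400,
    conditions = c("overexpression", "oe_control"))))
  out <- qc_filter(g$sce, min_features = 50, nfeat_sd = Inf)
  report <- S4Vectors::metadata(out)$qc_report
  expect_setequal(report$removed, unlist(g$truth$qc_violators))
  expect_setequal(report$by_rule$percent_mito,
                  g$truth$qc_violators$percent_mito)
  expect_setequal(report$by_rule$low_features,
                  g$truth$qc_violators$low_features)
})

test_that("normalization is depth-invariant and drops constant genes", {
  counts <- cbind(c(2, 4, 6, 8, 5), c(1, 2, 3, 4, 5), c(3, 6, 9, 12, 5))
  counts[, 3] <- counts[, 1] * 5  # cell 3 proportional to cell 1
  sce <- make_cell_matrix(counts, data.frame(
    cell_id = c("a", "b", "d"), sample_id = "s", condition = "x",
    percent_mito = 1, percent_ribo = 1),
    data.frame(gene_id = sprintf("g%d", 1:5), symbol = sprintf("g%d", 1:5)))
  sce <- sc_normalize(sce, n_variable = 5)
  ln <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  expect_equal(ln[, "a"], ln[, "d"], tolerance = 1e-12)
  # gene 5 is constant across cells pre-depth: not informative for ranking
  set.seed(71)
  counts2 <- matrix(rpois(30 * 100, 4), 30, 100)
  counts2[7, ] <- 4  # strictly constant gene
  sce2 <- make_cell_matrix(counts2, data.frame(
    cell_id = sprintf("c%03d", 1:100), sample_id = "s", condition = "x",
    percent_mito = 1, percent_ribo = 1),
    data.frame(gene_id = sprintf("g%02d", 1:30), symbol = sprintf("g%02d", 1:30)))
  sce2 <- sc_normalize(sce2, n_variable = 30)
  expect_false("g07" %in% S4Vectors::metadata(sce2)$variable_genes)
  # an overdispersed gene tops the standardized-variance ranking
  counts3 <- counts2
  counts3[3, ] <- rpois(100, 4) * sample(c(0, 8), 100, TRUE)
  sce3 <- make_cell_matrix(counts3, data.frame(
    cell_id = sprintf("c%03d", 1:100), sample_id = "s", condition = "x",
    percent_mito = 1, percent_ribo = 1),
    data.frame(gene_id = sprintf("g%02d", 1:30), symbol = sprintf("g%02d", 1:30)))
  sce3 <- sc_normalize(sce3, n_variable = 10)
  expect_true("g03" %in% S4Vectors::metadata(sce3)$variable_genes)
})

test_that("clustering recovers well-separated blobs and ignores cell order", {
  set.seed(73)
  n <- 200; g <- 40
  blob <- rep(1:2, each = n / 2)
  mu <- matrix(1, g, n)
  mu[1:10, blob == 1] <- 8
  mu[11:20, blob == 2] <- 8
  counts <- matrix(rnbinom(g * n, mu = mu, size = 5), g, n)
  sce <- make_cell_matrix(counts, data.frame(
    cell_id = sprintf("c%03d", 1:n), sample_id = "s", condition = "x",
    percent_mito = 1, percent_ribo = 1),
    data.frame(gene_id = sprintf("g%02d", 1:g), symbol = sprintf("g%02d", 1:g)))
  sce <- sc_normalize(sce, n_variable = g)
  sce <- cluster_cells(sce, k = 2, n_pcs = 10)
  cl <- SummarizedExperiment::colData(sce)$cluster
  agree <- max(mean((cl == cl[1]) == (blob == 1)),
               mean((cl == cl[1]) == (blob == 2)))
  expect_gte(agree, 0.99)
  # k = 1: a single cluster
  one <- cluster_cells(sce, k = 1, n_pcs = 10)
  expect_equal(nlevels(SummarizedExperiment::colData(one)$cluster), 1)
  expect_error(cluster_cells(sce, k = 500), "exceeds")
  # permuting cells permutes labels identically
  perm <- sample(n)
  sce_p <- cluster_cells(sc_normalize(
    make_cell_matrix(counts[, perm], data.frame(
      cell_id = sprintf("c%03d", 1:n)[perm], sample_id = "s", condition = "x",
      percent_mito = 1, percent_ribo = 1),
      data.frame(gene_id = sprintf("g%02d", 1:g),
                 symbol = sprintf("g%02d", 1:g))), n_variable = g),
    k = 2, n_pcs = 10)
  cl_p <- SummarizedExperiment::colData(sce_p)$cluster
  # same partition up to label permutation: one nonzero cell per row
  cross <- table(cl[perm], cl_p)
  expect_true(all(rowSums(cross > 0) == 1))
})

test_that("downsampling matches control totals under the min rule, reproducibly", {
  set.seed(79)
  n_t <- 120; n_c <- 80
  counts <- matrix(rpois(20 * (n_t + n_c), 3), 20)
  cond <- rep(c("t", "c"), c(n_t, n_c))
  sce <- make_cell_matrix(counts, data.frame(
    cell_id = sprintf("c%03d", seq_len(n_t + n_c)), sample_id = "s",
    condition = cond, percent_mito = 1, percent_ribo = 1),
    data.frame(gene_id = sprintf("g%02d", 1:20), symbol = sprintf("g%02d", 1:20)))
  SummarizedExperiment::colData(sce)$cluster <-
    factor(rep_len(1:3, n_t + n_c))
  ds <- downsample_to_match(sce, "t", "c", seed = 5)
  cd <- SummarizedExperiment::colData(ds)
  expect_equal(sum(cd$condition == "t"), n_c)  # matched to control total
  expect_equal(sum(cd$condition == "c"), n_c)  # control untouched
  # proportional allocation preserves the test cluster distribution
  tgt <- S4Vectors::metadata(ds)$downsample_report$target
  expect_equal(sum(tgt), n_c)
  # identical seed, identical selection; different seed differs
  ds2 <- downsample_to_match(sce, "t", "c", seed = 5)
  expect_identical(colnames(ds), colnames(ds2))
  # equal counts already: identity on test cells
  sce_eq <- sce[, c(which(cond == "t")[1:80], which(cond == "c"))]
  ds_eq <- downsample_to_match(sce_eq, "t", "c", seed = 1)
  expect_identical(colnames(ds_eq), colnames(sce_eq))
  # cluster with fewer test cells than target: all retained, shortfall logged
  few <- sce[, c(which(cond == "t")[1:10], which(cond == "c"))]
  SummarizedExperiment::colData(few)$cluster <-
    factor(c(rep(1, 10), rep_len(1:2, n_c)))
  ds_few <- downsample_to_match(few, "t", "c", seed = 2)
  expect_equal(sum(SummarizedExperiment::colData(ds_few)$condition == "t"), 10)
  expect_true(sum(S4Vectors::metadata(ds_few)$downsample_report$shortfall) > 0)
})

test_that("DE testing applies detection and fold-change floors correctly", {
  sce <- sc_normalize(toy_sce(n_genes = 40, n_cells = 600, planted_gene = 3,
                              effect = 2, seed = 83), n_variable = 40)
  de <- de_wilcoxon(sce, "t", "c")
  expect_true("g003" %in% de$gene)
  row <- de[de$gene == "g003", ]
  expect_identical(row$direction, "up")
  expect_lt(row$p_adj, 0.05)
  # fold-change recovery near log2(2) = 1 across replicates
  set.seed(89)
  lfc <- replicate(10, {
    s <- sc_normalize(toy_sce(n_genes = 30, n_cells = 600, planted_gene = 1,
                              effect = 2, seed = sample.int(1e6, 1)),
                      n_variable = 30)
    d <- de_wilcoxon(s, "t", "c")
    d$log2fc[d$gene == "g001"]
  })
  expect_lt(abs(mean(lfc) - 1), 0.15)
  # a gene detected below min_pct in both groups is not tested
  sce2 <- toy_sce(n_genes = 20, n_cells = 400, seed = 97, mu = 1)
  counts <- SummarizedExperiment::assay(sce2, "counts")
  counts[5, ] <- 0
  counts[5, c(1, 201)] <- 5  # 0.5% detection in each group
  sce2 <- make_cell_matrix(counts, as.data.frame(
    SummarizedExperiment::colData(sce2))[
      setdiff(colnames(SummarizedExperiment::colData(sce2)), "n_features")],
    as.data.frame(SummarizedExperiment::rowData(sce2)))
  de2 <- de_wilcoxon(sc_normalize(sce2, n_variable = 20), "t", "c",
                     min_pct = 0.01)
  expect_false("g005" %in% de2$gene)
  expect_error(de_wilcoxon(sce, "t", "missing"), "zero cells")
})

test_that("target-set enrichment agrees with enumeration and guards edge cases", {
  de <- data.frame(gene = sprintf("g%03d", 1:10), log2fc = 1,
                   p = 1e-6, p_adj = 1e-5, stringsAsFactors = FALSE)
  bg <- sprintf("g%03d", 1:200)
  targets <- sprintf("g%03d", 1:12)  # all DEGs are targets, targets rare
  res <- target_set_enrichment(de, targets, bg)
  expect_equal(res$observed_frac, 1)
  expect_equal(res$expected_frac, 12 / 200)
  expect_equal(res$p, oracle_fisher_p(10, 0, 2, 188), tolerance = 1e-10)
  expect_error(target_set_enrichment(de, character(0), bg), "empty")
  de_ns <- de; de_ns$p_adj <- 0.5
  expect_warning(r0 <- target_set_enrichment(de_ns, targets, bg), "empty DEG")
  expect_equal(r0$p, 1)
  # family BH adjustment includes sibling tests
  res_fam <- target_set_enrichment(de, targets, bg, family_p = c(0.5, 0.9))
  expect_gte(res_fam$p_bh, res$p)
})

test_that("ortholog mapping keeps paralog expansions and reports unmapped", {
  map <- data.frame(human_symbol = c("YTHDF2", "GMEB1", "GMEB1"),
                    zebrafish_symbol = c("ythdf2", "gmeb1a", "gmeb1b"),
                    stringsAsFactors = FALSE)
  res <- ortholog_map(c("YTHDF2", "GMEB1", "NOPE"), map)
  expect_setequal(res$mapped, c("ythdf2", "gmeb1a", "gmeb1b"))
  expect_identical(res$unmapped, "NOPE")
  expect_gte(length(res$mapped) + length(res$unmapped), 3)
})

test_that("shift tests behave at degeneracy, power and a hand-computed toy", {
  # identical fold-change vectors: paired statistic 0, p 1
  st0 <- data.frame(gene = sprintf("g%d", 1:10),
                    avg_log2fc_kd = seq(0.1, 1, 0.1),
                    avg_log2fc_oe = seq(0.1, 1, 0.1), scope = "all_cells",
                    in_target_set = TRUE, stringsAsFactors = FALSE)
  r0 <- geneset_shift_test(st0)
  expect_equal(r0$statistic[1], 0)
  expect_equal(r0$p[1], 1)
  # planted -0.2 shift, sd 0.1, 100 target genes: p < 1e-6 throughout
  set.seed(101)
  hits <- replicate(10, {
    kd <- rnorm(100, 0, 0.1)
    st <- data.frame(gene = sprintf("g%d", 1:100), avg_log2fc_kd = kd,
                     avg_log2fc_oe = kd - 0.2 + rnorm(100, 0, 0.1),
                     scope = "all_cells", in_target_set = TRUE,
                     stringsAsFactors = FALSE)
    geneset_shift_test(st)$p[1] < 1e-6
  })
  expect_true(all(hits))
  # hand-computed paired t on a 5-gene toy
  kd <- c(0.10, 0.20, 0.05, -0.10, 0.00)
  oe <- c(-0.10, 0.05, -0.20, -0.30, -0.15)
  d <- oe - kd
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  st5 <- data.frame(gene = sprintf("g%d", 1:5), avg_log2fc_kd = kd,
                    avg_log2fc_oe = oe, scope = "all_cells",
                    in_target_set = TRUE, stringsAsFactors = FALSE)
  r5 <- geneset_shift_test(st5)
  expect_equal(r5$statistic[1], t_hand, tolerance = 1e-12)
  expect_equal(r5$p[1], p_hand, tolerance = 1e-12)
  expect_error(geneset_shift_test(st5[1:2, ]), ">= 3")
})
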