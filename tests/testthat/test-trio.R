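test_that("variant normalization reaches the minimal leftmost representation", {
  # already-minimal SNV is unchanged
  expect_identical(normalize_variant(100, "A", "G"),
                   list(pos = 100, ref = "A", alt = "G"))
  # insertion with shared prefix/suffix trims to an anchored form
  expect_identical(normalize_variant(100, "AT", "AATT"),
                   list(pos = 100, ref = "A", alt = "AAT"))
  # deletion inside a repeat left-aligns to the repeat start
  ctx <- "GCATTTTG"
  expect_equal(normalize_variant(5, "TT", "T", context = ctx),
               list(pos = 3, ref = "AT", alt = "A"))
  # random indels in repeat-rich contexts agree with the whole-sequence oracle
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    ctx <- paste(sample(c(bases, "A", "T"), 60, TRUE), collapse = "")
    pos <- sample(10:40, 1)
    len_r <- sample(1:4, 1)
    ref <- substr(ctx, pos, pos + len_r - 1)
    alt <- if (runif(1) < 0.5) {
      paste0(ref, paste(sample(bases, sample(1:3, 1), TRUE), collapse = ""))
    } else {
      paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
    }
    if (alt == ref) next
    got <- normalize_variant(pos, ref, alt, context = ctx)
    exp <- oracle_normalize(pos, ref, alt, context = ctx)
    expect_identical(got, exp,
                     label = sprintf("pos %d %s>%s in %s", pos, ref, alt, ctx))
  }
})

test_that("multiallelic records split into per-allele rows with recoded GTs", {
  v <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G,T",
                  stringsAsFactors = FALSE)
  gt <- matrix(c("0/1", "0/2", "1/2"), 1, 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  sp <- split_multiallelic(v, gt)
  expect_equal(nrow(sp$variants), 2)
  expect_identical(sp$variants$alt, c("G", "T"))
  expect_identical(unname(sp$gt[1, ]), c("0/1", "0/0", "1/0"))
  expect_identical(unname(sp$gt[2, ]), c("0/0", "0/1", "0/1"))
})

test_that("de novo detection requires proband alt absent from both parents", {
  v <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L, 4L), ref = "A",
                  alt = "G", stringsAsFactors = FALSE)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  gt <- rbind(c("0/0", "0/0", "0/1"),   # de novo
              c("0/1", "0/0", "0/1"),   # inherited from father
              c("0/0", NA,    "0/1"),   # parent missing: excluded + logged
              c("0/0", "0/0", "0/0"))   # proband homozygous reference
  colnames(gt) <- c("dad", "mum", "kid")
  fam <- list(proband_id = "kid", father_id = "dad", mother_id = "mum")
  dn <- find_denovo(v, gt, fam)
  expect_identical(dn$key, "chr1:1:A:G")
  expect_identical(attr(dn, "excluded_missing"), "chr1:3:A:G")
})

test_that("generated trios round-trip through VCF with perfect recovery", {
  cfg <- sim_config(seed = 31, trios = list(n_families = 1,
                                            n_inherited = 800, n_denovo = 15))
  tr <- gen_trio_cohort(cfg)
  fam <- tr$families[1, ]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_trio_vcf(tr$variants[[fam$family_id]], tr$gt[[fam$family_id]], path)
  vv <- read_trio_vcf(path)
  expect_setequal(vv$variants$key, tr$variants[[fam$family_id]]$key)
  dn <- find_denovo(vv$variants, vv$gt, fam)
  truth_dn <- tr$truth$key[tr$truth$is_denovo]
  expect_setequal(dn$key, truth_dn)  # precision = recall = 1
})

test_that("LGD, rarity and CNV predicates follow the printed rules", {
  expect_identical(is_lgd(c("frameshift", "stop_gained", "splice_site",
                            "missense", "synonymous", "other")),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  af <- data.frame(af_afr = c(0, 0.003, 0, 0.002),
                   af_amr = 0, af_eas = 0, af_eur = c(0, 0, 0.0019, 0),
                   af_sas = 0)
  expect_identical(is_rare(af), c(TRUE, FALSE, TRUE, FALSE))  # 0.002 strict
  # a missing population counts as zero
  af_na <- data.frame(af_afr = NA_real_, af_amr = 0, af_eas = 0, af_eur = 0,
                      af_sas = 0)
  expect_true(is_rare(af_na))
  expect_identical(is_rare(data.frame(in_dbsnp = c(TRUE, FALSE)),
                           mode = "non_trio"), c(FALSE, TRUE))
  cnvs <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(5, 15, 25),
                     copy_number = 3, precise = c(TRUE, TRUE, FALSE),
                     exonic = TRUE,
                     genes_impacted = c("A,B", "A,B,C", "A"),
                     stringsAsFactors = FALSE)
  kept <- filter_cnvs(cnvs)
  expect_equal(kept$start, 0)  # two genes kept; three genes or imprecise drop
})

test_that("qualifying filters compose in any order and outputs satisfy all", {
  cfg <- sim_config(seed = 55, trios = list(n_families = 1,
                                            n_inherited = 400, n_denovo = 30,
                                            denovo_nonrare_fraction = 0.3))
  tr <- gen_trio_cohort(cfg)
  fam <- tr$families[1, ]
  fid <- fam$family_id
  v <- tr$variants[[fid]]; gt <- tr$gt[[fid]]; ann <- tr$annotation
  a <- ann[match(v$key, ann$key), ]
  # order 1: denovo then lgd then rare
  dn <- find_denovo(v, gt, fam)
  a_dn <- ann[match(dn$key, ann$key), ]
  keys1 <- dn$key[is_lgd(a_dn$consequence) & is_rare(a_dn)]
  # order 2: rare then lgd then denovo (genotypes subset in step)
  mask <- is_rare(a) & is_lgd(a$consequence)
  keys2 <- find_denovo(v[mask, ], gt[mask, , drop = FALSE], fam)$key
  expect_setequal(keys1, keys2)
  # every retained variant satisfies all three predicates
  truth <- tr$truth
  t_keep <- truth[match(keys1, truth$key), ]
  expect_true(all(t_keep$is_denovo))
  expect_true(all(t_keep$consequence %in%
                    c("frameshift", "stop_gained", "splice_site")))
  expect_true(all(t_keep$max_af < 0.002))
  expect_setequal(keys1, truth$key[truth$qualifying])
})

test_that("candidate aggregation counts distinct probands and credits CNV genes", {
  v <- data.frame(key = c("k1", "k2", "k3", "k4"),
                  proband_id = c("p1", "p2", "p3", "p3"),
                  genes = c("CHD8", "CHD8", "CHD8", ""),
                  stringsAsFactors = FALSE)
  cnvs <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                     proband_id = "p4", genes_impacted = "YTHDF2,GMEB1",
                     stringsAsFactors = FALSE)
  pli <- c(CHD8 = 1, YTHDF2 = 0.99, GMEB1 = 0.1)
  out <- aggregate_candidates(v, cnvs, pli)
  expect_identical(attr(out, "skipped"), "k4")
  chd8 <- out[out$gene == "CHD8", ]
  expect_equal(chd8$n_probands, 3)
  expect_true(chd8$pli_flag)
  # duplication spanning two genes credits both
  expect_setequal(c("YTHDF2", "GMEB1"), setdiff(out$gene, "CHD8"))
  expect_false(out$pli_flag[out$gene == "GMEB1"])
  # two variants in one proband count once
  v2 <- data.frame(key = c("a", "b"), proband_id = "p1", genes = "GENE",
                   stringsAsFactors = FALSE)
  expect_equal(aggregate_candidates(v2)$n_probands, 1)
  empty <- aggregate_candidates(v[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("burden statistics match enumeration and textbook behavior", {
  # identical proportions: chi-squared statistic 0, p 1
  eq <- carrier_rate_test(10, 100, 20, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # Fisher on [[2,8],[1,99]] equals the hypergeometric enumeration oracle
  ft <- geneset_fisher_test(matrix(c(2, 8, 1, 99), 2, byrow = TRUE))
  expect_equal(ft$p, oracle_fisher_p(2, 8, 1, 99), tolerance = 1e-10)
  # doubling all counts leaves the odds ratio estimate direction unchanged
  ft2 <- geneset_fisher_test(matrix(c(4, 16, 2, 198), 2, byrow = TRUE))
  expect_equal((2 * 99) / (8 * 1), (4 * 198) / (16 * 2))
  expect_gt(ft2$estimate, 1)
  # zero-margin table: p = 1 with a warning
  expect_warning(zm <- geneset_fisher_test(matrix(c(0, 0, 5, 5), 2,
                                                  byrow = TRUE)), "zero")
  expect_equal(zm$p, 1)
  expect_warning(zc <- carrier_rate_test(0, 10, 0, 10), "zero")
  expect_equal(zc$p, 1)
  # report combines both families of tests
  rep <- burden_tests(
    carrier_tables = list(probands_vs_sibs = list(carriers_a = 19, n_a = 98,
                                                  carriers_b = 33, n_b = 200)),
    fisher_tables = list(missense = matrix(c(2, 8, 1, 99), 2, byrow = TRUE)))
  expect_equal(nrow(rep), 2)
  expect_identical(rep$test, c("chi_squared", "fisher_exact"))
})
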