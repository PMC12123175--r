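#' Synthetic-data generators with known ground truth
#'
#' Every pipeline input can be generated offline with planted, recorded
#' truth: growth references and anthropometric cohorts with a planted
#' macrocephalic fraction; Mendelian trio genotypes with planted de novo
#' SNVs/indels and CNVs of known consequence class and population frequency;
#' scored interaction edge tables with a planted enriched ontology term;
#' group-shifted larval morphometric features and delta-Ct qPCR tables; and
#' clustered negative-binomial single-cell counts with a planted
#' multiplicative downshift on a designated target gene set. All generators
#' are deterministic under their seed and return machine-readable truth
#' tables.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: a cohort with a
#' large planted macrocephalic fraction, trios with 5,000 inherited and 50
#' de novo variants per family, a medium-confidence-scored random
#' interaction network, a ~0.96x morphometric body-length effect at 35
#' larvae per group, and 500 cells per condition over 2,000 genes with
#' negative-binomial dispersion 0.5 and a 0.8x downshift on a 50-gene
#' target set in the overexpression analog.
#'
#' @param seed Integer seed.
#' @param cohort,trios,edges,morpho,sc Named lists overriding defaults.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, cohort = list(), trios = list(),
                       edges = list(), morpho = list(), sc = list()) {
  merge <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop2("unknown config field(s): ",
                           paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = seed,
    cohort = merge(list(n_probands = 2000, macro_fraction = 0.4,
                        hc_height_correlation = 0.5,
                        age_range = c(48, 204)), cohort),
    trios = merge(list(n_families = 3, n_inherited = 5000, n_denovo = 50,
                       lgd_fraction = 0.3, af_shape1 = 0.2, af_shape2 = 50,
                       af_zero_mass = 0.3, denovo_nonrare_fraction = 0.1,
                       n_cnv = 20, n_genes = 400), trios),
    edges = merge(list(n_genes = 300, mean_degree = 8, score_range = c(150, 999),
                       n_seeds = 20, n_terms = 15, term_size = 25), edges),
    morpho = merge(list(n_per_group = 35,
                        effects = c(total_area = 0.95, body_length = 0.96,
                                    eye_distance = 0.97,
                                    telencephalon_width = 0.95,
                                    head_trunk_angle = 1.0),
                        noise_cv = 0.05, ddct = 1.43, ct_sd = 0.1), morpho),
    sc = merge(list(n_cells_per_condition = 500, n_genes = 2000,
                    n_clusters = 5, nb_dispersion = 0.5,
                    target_set_size = 50, target_effect = 0.8,
                    n_samples_per_condition = 3, depth_sdlog = 0.2,
                    n_qc_violators = 5,
                    conditions = c("knockdown", "kd_control",
                                   "overexpression", "oe_control")), sc))
  stopifnot(cfg$cohort$macro_fraction >= 0, cfg$cohort$macro_fraction <= 1,
            cfg$trios$lgd_fraction >= 0, cfg$trios$lgd_fraction <= 1,
            cfg$sc$target_effect > 0, cfg$sc$nb_dispersion > 0)
  structure(cfg, class = "sim_config")
}

#' Built-in synthetic growth reference standards
#'
#' Smooth sex-specific mean/SD curves for head circumference (cm) and height
#' (cm) over 48-204 months and for the cerebral-volume/height ratio
#' (cm^3/cm) over 24-54 months. These are synthetic stand-ins shaped like
#' published growth standards, not published values.
#'
#' @return data.frame with columns `measure`, `sex`, `age_months`, `mean`,
#'   `sd`.
#' @export
gen_growth_reference <- function() {
  rows <- list()
  add <- function(measure, sex, age, mean, sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, sex = sex, age_months = age, mean = mean, sd = sd,
      stringsAsFactors = FALSE)
  ages <- seq(48, 204, by = 12)
  for (sex in c("M", "F")) {
    off <- if (sex == "M") 0 else -1.2
    add("head_circumference_cm", sex, ages,
        round(50.2 + off + 5.4 * (1 - exp(-(ages - 48) / 70)), 2),
        round(1.45 + 0.1 * (ages - 48) / 156, 3))
    h0 <- if (sex == "M") 101 else 100
    hg <- if (sex == "M") 74 else 62
    add("height_cm", sex, ages,
        round(h0 + hg * (ages - 48) / 156, 1),
        round(4.3 + 3.2 * (ages - 48) / 156, 2))
  }
  ages2 <- seq(24, 54, by = 6)
  for (sex in c("M", "F")) {
    v0 <- if (sex == "M") 11.8 else 11.0
    add("cv_height_ratio", sex, ages2,
        round(v0 + 0.012 * (ages2 - 24), 3), 0.8)
  }
  do.call(rbind, rows)
}

#' Generate a growth cohort with a planted macrocephalic fraction
#'
#' Probands draw (head-circumference z, height z) from a bivariate normal
#' with the configured correlation; a `macro_fraction` share instead draws
#' its head-circumference z from the truncated tail above 1.5 SD. Cerebral
#' volume is synthesized from a standard-normal ratio z-score. The truth
#' table records each proband's planted class.
#'
#' @param cfg A [sim_config()].
#' @return List of `reference`, `cohort`, `truth` data.frames.
#' @export
gen_growth_cohort <- function(cfg) {
  set.seed(cfg$seed)
  cc <- cfg$cohort
  n <- cc$n_probands
  rho <- cc$hc_height_correlation
  reference <- gen_growth_reference()
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- round(runif(n, cc$age_range[1], cc$age_range[2]))
  planted <- runif(n) < cc$macro_fraction
  hc_z <- rnorm(n)
  hc_z[planted] <- qnorm(runif(sum(planted), pnorm(1.5), 1))
  ht_z <- rho * hc_z + sqrt(1 - rho^2) * rnorm(n)
  hc_tab <- growth_reference("head_circumference_cm",
                             reference[reference$measure ==
                                         "head_circumference_cm", ])
  ht_tab <- growth_reference("height_cm",
                             reference[reference$measure == "height_cm", ])
  hc_ms <- ref_interp(hc_tab, sex, age)
  ht_ms <- ref_interp(ht_tab, sex, age)
  cohort <- data.frame(
    proband_id = sprintf("P%04d", seq_len(n)), sex = sex, age_months = age,
    head_circumference_cm = round(hc_ms[, "mean"] + hc_z * hc_ms[, "sd"], 2),
    height_cm = round(ht_ms[, "mean"] + ht_z * ht_ms[, "sd"], 1),
    cerebral_volume_cm3 = NA_real_, stringsAsFactors = FALSE)
  truth <- data.frame(proband_id = cohort$proband_id,
                      planted_macro = planted, hc_z = hc_z, ht_z = ht_z,
                      stringsAsFactors = FALSE)
  list(reference = reference, cohort = cohort, truth = truth)
}

.bases <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(.bases, n, replace = TRUE),
                              collapse = "")

#' Generate Mendelian trio genotypes with planted de novo variants
#'
#' Per family: inherited variants are carried by one or both parents and
#' transmitted Bernoulli(0.5); de novo variants are heterozygous in the
#' proband and absent (0/0) in both genotyped parents. Consequence classes
#' are assigned with the configured likely-gene-disruptive fraction;
#' population allele frequencies draw from a Beta with a point mass at zero,
#' and a configurable share of de novos is made common to exercise the
#' rarity filter. CNV calls with known precision/exonic/gene-count flags and
#' a per-gene pLI map are included. The truth table records every planted
#' attribute so the qualifying subset is recomputable by rule.
#'
#' @param cfg A [sim_config()].
#' @return List: `families` (data.frame), per-family `variants`/`gt`
#'   (named lists), `annotation`, `cnvs`, `pli` (named vector), `truth`.
#' @export
gen_trio_cohort <- function(cfg) {
  set.seed(cfg$seed + 1L)
  tc <- cfg$trios
  genes <- sprintf("GENE%03d", seq_len(tc$n_genes))
  pli <- setNames(round(rbeta(tc$n_genes, 0.3, 0.3), 4), genes)
  families <- data.frame(
    family_id = sprintf("FAM%02d", seq_len(tc$n_families)),
    proband_id = sprintf("FAM%02d-P", seq_len(tc$n_families)),
    father_id = sprintf("FAM%02d-F", seq_len(tc$n_families)),
    mother_id = sprintf("FAM%02d-M", seq_len(tc$n_families)),
    stringsAsFactors = FALSE)
  lgd_classes <- c("frameshift", "stop_gained", "splice_site")
  other_classes <- c("missense", "synonymous", "other")
  variants <- list(); gts <- list(); truth_rows <- list(); ann_rows <- list()
  for (f in seq_len(tc$n_families)) {
    n_v <- tc$n_inherited + tc$n_denovo
    pos <- sort(sample(seq_len(5e7), n_v))
    is_indel <- runif(n_v) < 0.2
    ref <- ifelse(is_indel, vapply(sample(2:4, n_v, TRUE), rand_seq, ""),
                  sample(.bases, n_v, TRUE))
    alt <- vapply(seq_len(n_v), function(i) {
      if (is_indel[i]) {
        repeat {
          a <- rand_seq(sample(c(1, 2, 5), 1))
          if (a != ref[i]) return(a)
        }
      }
      sample(setdiff(.bases, ref[i]), 1)
    }, "")
    # store minimal representations so keys are stable through the reader
    for (i in which(is_indel)) {
      nv <- normalize_variant(pos[i], ref[i], alt[i])
      pos[i] <- nv$pos; ref[i] <- nv$ref; alt[i] <- nv$alt
    }
    de_novo <- c(rep(FALSE, tc$n_inherited), rep(TRUE, tc$n_denovo))
    de_novo <- de_novo[sample.int(n_v)]
    fa <- mo <- pro <- character(n_v)
    for (i in seq_len(n_v)) {
      if (de_novo[i]) {
        fa[i] <- "0/0"; mo[i] <- "0/0"; pro[i] <- "0/1"
      } else {
        carrier <- sample(c("fa", "mo", "both"), 1, prob = c(.45, .45, .1))
        fa[i] <- if (carrier %in% c("fa", "both")) "0/1" else "0/0"
        mo[i] <- if (carrier %in% c("mo", "both")) "0/1" else "0/0"
        from_fa <- fa[i] == "0/1" && runif(1) < 0.5
        from_mo <- mo[i] == "0/1" && runif(1) < 0.5
        pro[i] <- if (from_fa && from_mo) "1/1" else
          if (from_fa || from_mo) "0/1" else "0/0"
      }
    }
    keep <- de_novo | pro != "0/0" | fa != "0/0" | mo != "0/0"
    v <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)[keep, ]
    gt <- cbind(fa, mo, pro)[keep, , drop = FALSE]
    colnames(gt) <- c(families$father_id[f], families$mother_id[f],
                      families$proband_id[f])
    v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    de_novo <- de_novo[keep]
    nk <- nrow(v)
    lgd <- runif(nk) < tc$lgd_fraction
    consequence <- ifelse(lgd, sample(lgd_classes, nk, TRUE),
                          sample(other_classes, nk, TRUE))
    zero_af <- runif(nk) < tc$af_zero_mass
    af <- matrix(rbeta(nk * 5, tc$af_shape1, tc$af_shape2), nk, 5)
    af[zero_af, ] <- 0
    common <- de_novo & runif(nk) < tc$denovo_nonrare_fraction
    af[common, ] <- pmax(af[common, , drop = FALSE], 0.01)
    colnames(af) <- c("af_afr", "af_amr", "af_eas", "af_eur", "af_sas")
    gene <- sample(genes, nk, TRUE)
    variants[[families$family_id[f]]] <- v
    gts[[families$family_id[f]]] <- gt
    ann_rows[[f]] <- data.frame(
      key = v$key, consequence = consequence, round(af, 6),
      in_dbsnp = apply(af, 1, max) > 0, genes = gene,
      pli = unname(pli[gene]), stringsAsFactors = FALSE)
    truth_rows[[f]] <- data.frame(
      family_id = families$family_id[f], proband_id = families$proband_id[f],
      key = v$key, is_denovo = de_novo, consequence = consequence,
      max_af = apply(af, 1, max), in_dbsnp = apply(af, 1, max) > 0,
      gene = gene, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  truth$qualifying <- truth$is_denovo &
    truth$consequence %in% lgd_classes & truth$max_af < 0.002
  annotation <- do.call(rbind, ann_rows)
  n_cnv <- cfg$trios$n_cnv
  cnv_start <- sort(sample(seq_len(5e7), n_cnv)) + 6e7
  n_genes_hit <- sample(1:3, n_cnv, TRUE)
  cnvs <- data.frame(
    chrom = "chr1", start = cnv_start, end = cnv_start + sample(1e4:2e5, n_cnv),
    copy_number = sample(c(0, 1, 3, 4), n_cnv, TRUE),
    precise = runif(n_cnv) < 0.7, exonic = runif(n_cnv) < 0.7,
    genes_impacted = vapply(n_genes_hit, function(k)
      paste(sample(genes, k), collapse = ","), ""),
    proband_id = sample(families$proband_id, n_cnv, TRUE),
    stringsAsFactors = FALSE)
  cnvs$truth_pass <- cnvs$precise & cnvs$exonic & n_genes_hit <= 2
  list(families = families, variants = variants, gt = gts,
       annotation = annotation, cnvs = cnvs, pli = pli, truth = truth)
}

#' Write a trio family to a minimal VCF 4.2 file
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gt Genotype matrix, columns named by sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=120000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")), con)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Generate a scored interaction network with a planted enriched term
#'
#' Erdos-Renyi graph at the configured mean degree with integer combined
#' scores uniform on the configured range; a seed gene set is sampled and
#' one annotation term is planted to contain most of it, alongside random
#' background terms.
#'
#' @param cfg A [sim_config()].
#' @return List: `edges`, `seeds`, `annotation` (data.frame),
#'   `background`, `truth` (planted term id and its seed coverage).
#' @export
gen_interaction_network <- function(cfg) {
  set.seed(cfg$seed + 2L)
  ec <- cfg$edges
  genes <- sprintf("NG%03d", seq_len(ec$n_genes))
  p_edge <- min(1, ec$mean_degree / (ec$n_genes - 1))
  pairs <- combn(genes, 2)
  keep <- runif(ncol(pairs)) < p_edge
  edges <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                      combined_score = sample(
                        seq(ec$score_range[1], ec$score_range[2]),
                        sum(keep), TRUE),
                      stringsAsFactors = FALSE)
  seeds <- sort(sample(genes, ec$n_seeds))
  planted_genes <- unique(c(sample(seeds, ceiling(0.8 * length(seeds))),
                            sample(genes, 5)))
  terms <- list(data.frame(term_id = "T000", term_name = "planted_term",
                           gene = planted_genes, stringsAsFactors = FALSE))
  for (t in seq_len(ec$n_terms - 1)) {
    terms[[t + 1L]] <- data.frame(
      term_id = sprintf("T%03d", t), term_name = sprintf("term_%03d", t),
      gene = sample(genes, ec$term_size), stringsAsFactors = FALSE)
  }
  list(edges = edges, seeds = seeds, annotation = do.call(rbind, terms),
       background = genes,
       truth = list(planted_term = "T000",
                    planted_overlap = sum(seeds %in% planted_genes)))
}

#' Generate group-shifted morphometric features and a qPCR table
#'
#' Features are log-normal around typical 3-dpf magnitudes with coefficient
#' of variation `noise_cv`; the test group is scaled by the per-feature
#' multiplicative effects. The qPCR table plants the configured delta-delta-Ct
#' on the target gene with replicate noise `ct_sd`.
#'
#' @param cfg A [sim_config()].
#' @return List: `features` (data.frame), `qpcr` (data.frame), `truth`.
#' @export
gen_morpho_features <- function(cfg) {
  set.seed(cfg$seed + 3L)
  mc <- cfg$morpho
  base <- c(total_area = 1.6e6, body_length = 3500, eye_distance = 350,
            telencephalon_width = 250, head_trunk_angle = 25)
  feats <- names(mc$effects)
  n <- mc$n_per_group
  sdlog <- sqrt(log(1 + mc$noise_cv^2))
  rows <- list()
  for (grp in c("control", "test")) {
    vals <- vapply(feats, function(f) {
      eff <- if (grp == "test") mc$effects[[f]] else 1
      rlnorm(n, log(base[[f]] * eff) - sdlog^2 / 2, sdlog)
    }, numeric(n))
    rows[[grp]] <- data.frame(
      larva_id = sprintf("%s_%02d", grp, seq_len(n)), group = grp,
      as.data.frame(vals), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  qpcr <- do.call(rbind, lapply(c("control", "test"), function(grp) {
    dct <- if (grp == "test") mc$ddct else 0
    do.call(rbind, lapply(1:3, function(r) data.frame(
      sample = sprintf("%s_r%d", grp, r), group = grp,
      gene = c("target", "reference"),
      ct_value = c(24 + dct + rnorm(1, 0, mc$ct_sd),
                   20 + rnorm(1, 0, mc$ct_sd)),
      stringsAsFactors = FALSE)))
  }))
  list(features = features, qpcr = qpcr,
       truth = list(effects = mc$effects, ddct = mc$ddct,
                    expected_fc = 2^(-mc$ddct)))
}

#' Generate clustered negative-binomial single-cell counts
#'
#' Gene means are log-normal; clusters receive boosted marker blocks; counts
#' are negative binomial with the configured dispersion and log-normal
#' per-cell depth factors. In the overexpression condition the target gene
#' set is scaled by `target_effect`. Mito/ribo percentages and low-depth
#' cells are synthesized with planted QC violators of the three absolute
#' rules. Truth records target genes, violator ids and cluster identities.
#'
#' @param cfg A [sim_config()].
#' @return List: `sce` (a `SingleCellExperiment`), `target_genes`, `truth`.
#' @export
gen_sc_counts <- function(cfg) {
  set.seed(cfg$seed + 4L)
  sc <- cfg$sc
  g <- sc$n_genes
  gene_ids <- sprintf("zg%04d", seq_len(g))
  base_mu <- rlnorm(g, log(0.3), 1.2)
  # targets drawn from reliably detected genes so the planted shift is
  # observable at the configured cell counts
  eligible <- which(base_mu > stats::quantile(base_mu, 0.5))
  target_idx <- sort(sample(eligible, sc$target_set_size))
  marker_blocks <- split(sample(setdiff(seq_len(g), target_idx),
                                20 * sc$n_clusters),
                         rep(seq_len(sc$n_clusters), each = 20))
  cells <- list(); counts_cols <- list()
  size <- 1 / sc$nb_dispersion
  cell_n <- 0L
  truth_viol <- list(percent_mito = character(0),
                     percent_ribo = character(0),
                     low_features = character(0))
  cluster_truth <- character(0)
  for (cond in sc$conditions) {
    n_c <- sc$n_cells_per_condition
    clust <- sample(seq_len(sc$n_clusters), n_c, replace = TRUE)
    depth <- rlnorm(n_c, 0, sc$depth_sdlog)
    viol_lo <- sample(n_c, sc$n_qc_violators)
    depth[viol_lo] <- 0.03
    mito <- runif(n_c, 0.3, 4.5)
    ribo <- runif(n_c, 0.3, 4.5)
    viol_m <- sample(setdiff(seq_len(n_c), viol_lo), sc$n_qc_violators)
    mito[viol_m] <- runif(sc$n_qc_violators, 5.5, 12)
    viol_r <- sample(setdiff(seq_len(n_c), c(viol_lo, viol_m)),
                     sc$n_qc_violators)
    ribo[viol_r] <- runif(sc$n_qc_violators, 5.5, 12)
    ids <- sprintf("%s_c%04d", cond, seq_len(n_c))
    mu_cond <- base_mu
    if (cond == "overexpression")
      mu_cond[target_idx] <- mu_cond[target_idx] * sc$target_effect
    mu_mat <- outer(mu_cond, depth)
    for (cl in seq_len(sc$n_clusters)) {
      cols <- clust == cl
      mu_mat[marker_blocks[[cl]], cols] <- mu_mat[marker_blocks[[cl]], cols] * 5
    }
    mat <- matrix(rnbinom(g * n_c, mu = mu_mat, size = size), g, n_c)
    counts_cols[[cond]] <- mat
    cells[[cond]] <- data.frame(
      cell_id = ids, sample_id = paste0(cond, "_s",
        rep(seq_len(sc$n_samples_per_condition),
            length.out = n_c)),
      condition = cond, percent_mito = round(mito, 3),
      percent_ribo = round(ribo, 3), stringsAsFactors = FALSE)
    truth_viol$percent_mito <- c(truth_viol$percent_mito, ids[viol_m])
    truth_viol$percent_ribo <- c(truth_viol$percent_ribo, ids[viol_r])
    truth_viol$low_features <- c(truth_viol$low_features, ids[viol_lo])
    cluster_truth <- c(cluster_truth, paste0(cond, ":", clust))
    cell_n <- cell_n + n_c
  }
  counts <- do.call(cbind, counts_cols)
  cell_meta <- do.call(rbind, cells)
  rownames(cell_meta) <- NULL
  gene_meta <- data.frame(gene_id = gene_ids, symbol = gene_ids,
                          stringsAsFactors = FALSE)
  sce <- make_cell_matrix(counts, cell_meta, gene_meta)
  list(sce = sce, target_genes = gene_ids[target_idx],
       truth = list(qc_violators = truth_viol,
                    target_genes = gene_ids[target_idx],
                    target_effect = sc$target_effect,
                    cluster = cluster_truth))
}

#' Generate a human-to-zebrafish ortholog map
#'
#' Uppercase human symbols map to lowercase zebrafish symbols; a share of
#' genes receives two paralogs (`a`/`b` suffix) and a share is left
#' unmapped.
#'
#' @param human_genes Character vector.
#' @param seed Integer seed.
#' @return data.frame `human_symbol`, `zebrafish_symbol`.
#' @export
gen_ortholog_map <- function(human_genes, seed = 1) {
  set.seed(seed)
  rows <- lapply(human_genes, function(hg) {
    u <- runif(1)
    if (u < 0.1) return(NULL)  # unmapped
    zs <- tolower(hg)
    if (u < 0.3) zs <- paste0(zs, c("a", "b"))  # duplicated paralogs
    data.frame(human_symbol = hg, zebrafish_symbol = zs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write a complete simulated workspace
#'
#' Generates every module's inputs under one seed and writes them in the
#' dialects the pipeline reads (TSV, VCF 4.2, Matrix Market), plus truth
#' tables under `truth/`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created).
#' @return `outdir`, invisibly.
#' @export
simulate_workspace <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  gw <- gen_growth_cohort(cfg)
  write_tsv_file(gw$reference, file.path(outdir, "growth_reference.tsv"))
  write_tsv_file(gw$cohort, file.path(outdir, "cohort_anthro.tsv"))
  write_tsv_file(gw$truth, file.path(outdir, "truth", "growth_truth.tsv"))
  tr <- gen_trio_cohort(cfg)
  write_tsv_file(tr$families, file.path(outdir, "families.tsv"))
  for (fam in tr$families$family_id)
    write_trio_vcf(tr$variants[[fam]], tr$gt[[fam]],
                   file.path(outdir, paste0(fam, ".vcf")))
  write_tsv_file(tr$annotation, file.path(outdir, "variant_annotation.tsv"))
  write_tsv_file(tr$cnvs[setdiff(names(tr$cnvs), "truth_pass")],
                 file.path(outdir, "cnv_calls.tsv"))
  write_tsv_file(tr$cnvs[c("chrom", "start", "end", "truth_pass")],
                 file.path(outdir, "truth", "cnv_truth.tsv"))
  write_tsv_file(data.frame(gene = names(tr$pli), pli = unname(tr$pli)),
                 file.path(outdir, "pli.tsv"))
  write_tsv_file(tr$truth, file.path(outdir, "truth", "trio_truth.tsv"))
  nw <- gen_interaction_network(cfg)
  write_tsv_file(nw$edges, file.path(outdir, "interaction_edges.tsv"))
  write_tsv_file(nw$annotation, file.path(outdir, "term_annotation.tsv"))
  writeLines(nw$seeds, file.path(outdir, "seed_genes.txt"))
  writeLines(nw$background, file.path(outdir, "background_genes.txt"))
  mo <- gen_morpho_features(cfg)
  write_tsv_file(mo$features, file.path(outdir, "larva_features.tsv"))
  write_tsv_file(mo$qpcr, file.path(outdir, "qpcr_ct.tsv"))
  scx <- gen_sc_counts(cfg)
  write_cell_matrix(scx$sce, file.path(outdir, "sc"))
  writeLines(scx$target_genes, file.path(outdir, "fmrp_targets.txt"))
  write_tsv_file(
    data.frame(rule = rep(names(scx$truth$qc_violators),
                          lengths(scx$truth$qc_violators)),
               cell_id = unlist(scx$truth$qc_violators, use.names = FALSE)),
    file.path(outdir, "truth", "sc_qc_truth.tsv"))
  invisible(outdir)
}
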