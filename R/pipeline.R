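#' Pipeline configuration and orchestration
#'
#' A single structured configuration drives all stages; every numeric
#' threshold of the analysis lives here with its default, each run stamps
#' the resolved configuration (and its MD5 hash) into the output workspace,
#' and reruns under the same configuration are byte-identical.
#'
#' @name cli_orchestration
NULL

#' Build and validate a pipeline configuration
#'
#' @param stages Stages to run, in dependency order, from `"simulate"`,
#'   `"classify"`, `"denovo"`, `"network"`, `"morpho"`, `"sc"`, `"report"`.
#' @param seed Integer seed used for every stochastic step.
#' @param outdir Output workspace directory.
#' @param workspace Input directory (defaults to `<outdir>/inputs`, where
#'   the simulate stage writes).
#' @param sim Named list of [sim_config()] overrides for the simulate stage.
#' @param config_file Optional YAML file; explicit arguments override it.
#' @param ... Threshold overrides: `threshold_sd` (1.5), `so_percentile`
#'   (90), `ratio_cutoff` (0.7), `max_af` (0.002), `pli_cutoff` (0.9),
#'   `top_k` (10), `min_score` (400), `mito_ribo_max` (5), `min_features`
#'   (200), `nfeat_sd` (2), `n_pcs` (30), `n_variable_genes` (5000),
#'   `k_broad` (10), `k_brain` (18), `logfc_floor` (0.1), `min_pct` (0.01),
#'   `expression_floor` (1e-4), `alpha` (0.05).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "classify", "denovo",
                                       "network", "morpho", "sc", "report"),
                            seed = 1, outdir = "asdm_out", workspace = NULL,
                            sim = list(), config_file = NULL, ...) {
  defaults <- list(threshold_sd = 1.5, so_percentile = 90,
                   ratio_cutoff = 0.7, max_af = 0.002, pli_cutoff = 0.9,
                   top_k = 10, min_score = 400, mito_ribo_max = 5,
                   min_features = 200, nfeat_sd = 2, n_pcs = 30,
                   n_variable_genes = 5000, k_broad = 10, k_brain = 18,
                   logfc_floor = 0.1, min_pct = 0.01,
                   expression_floor = 1e-4, alpha = 0.05)
  user <- list(...)
  if (!is.null(config_file)) {
    # YAML supplies values; explicit arguments override it
    yml <- yaml::read_yaml(config_file)
    if (missing(stages) && !is.null(yml$stages)) stages <- yml$stages
    if (missing(seed) && !is.null(yml$seed)) seed <- yml$seed
    if (missing(outdir) && !is.null(yml$outdir)) outdir <- yml$outdir
    if (is.null(workspace) && !is.null(yml$workspace))
      workspace <- yml$workspace
    if (!is.null(yml$sim)) sim <- utils::modifyList(yml$sim, sim)
    user <- utils::modifyList(yml[intersect(names(yml), names(defaults))],
                              user)
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop2("unknown threshold(s): ", paste(bad, collapse = ", "))
  thresholds <- utils::modifyList(defaults, user)
  with(thresholds, {
    if (ratio_cutoff <= 0 || ratio_cutoff >= 1)
      stop2("ratio_cutoff must lie in (0, 1)")
    if (threshold_sd <= 0) stop2("threshold_sd must be positive")
    if (max_af <= 0 || max_af >= 1) stop2("max_af must lie in (0, 1)")
    if (alpha <= 0 || alpha >= 1) stop2("alpha must lie in (0, 1)")
    if (min_pct < 0 || min_pct > 1) stop2("min_pct must lie in [0, 1]")
    if (so_percentile <= 0 || so_percentile >= 100)
      stop2("so_percentile must lie in (0, 100)")
  })
  known <- c("simulate", "classify", "denovo", "network", "morpho", "sc",
             "report")
  if (!all(stages %in% known))
    stop2("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(stages = stages, seed = as.integer(seed), outdir = outdir,
                 workspace = workspace %||% file.path(outdir, "inputs"),
                 sim = sim, thresholds = thresholds),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[c("stages", "seed", "sim", "thresholds")], file = tmp)
  unname(tools::md5sum(tmp))
}

need_input <- function(stage, path) {
  if (!file.exists(path))
    stop2("stage '", stage, "' is missing required input: ", path)
  path
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in dependency order against the input
#' workspace (generated by the simulate stage or supplied by the user),
#' writing per-stage tables plus a `report.txt` / `report.json` summary and
#' a `provenance.json` with the resolved configuration, its hash, the seed
#' and input checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of per-stage result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ws <- config$workspace
  results <- list()
  stage_on <- function(s) s %in% config$stages

  if (stage_on("simulate")) {
    message("[simulate] writing synthetic workspace to ", ws)
    cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    simulate_workspace(cfg, ws)
  }

  if (stage_on("classify")) {
    message("[classify] head-size phenotyping")
    ref <- need_input("classify", file.path(ws, "growth_reference.tsv"))
    coh <- need_input("classify", file.path(ws, "cohort_anthro.tsv"))
    hc_tab <- read_growth_reference(ref, "head_circumference_cm")
    ht_tab <- read_growth_reference(ref, "height_cm")
    anthro <- read_tsv_file(coh)
    calls <- call_head_size(anthro, hc_tab, ht_tab,
                            threshold_sd = th$threshold_sd,
                            so_percentile = th$so_percentile,
                            ratio_cutoff = th$ratio_cutoff)
    if (!all(is.na(anthro$cerebral_volume_cm3))) {
      ratio_tab <- read_growth_reference(ref, "cv_height_ratio")
      calls$megalencephaly <- call_megalencephaly(anthro, ratio_tab,
                                                  th$threshold_sd)
    }
    write_tsv_file(calls, file.path(config$outdir, "subphenotype_calls.tsv"))
    results$classify <- calls
  }

  if (stage_on("denovo")) {
    message("[denovo] trio variant filtering")
    fams <- read_tsv_file(need_input("denovo", file.path(ws, "families.tsv")))
    ann <- read_tsv_file(need_input("denovo",
                                    file.path(ws, "variant_annotation.tsv")))
    cnvs <- read_tsv_file(need_input("denovo", file.path(ws, "cnv_calls.tsv")))
    pli_tab <- read_tsv_file(need_input("denovo", file.path(ws, "pli.tsv")))
    pli <- setNames(pli_tab$pli, pli_tab$gene)
    qual <- list()
    n_denovo <- 0L
    for (i in seq_len(nrow(fams))) {
      vv <- read_trio_vcf(need_input(
        "denovo", file.path(ws, paste0(fams$family_id[i], ".vcf"))))
      dn <- find_denovo(vv$variants, vv$gt, fams[i, ])
      n_denovo <- n_denovo + nrow(dn)
      a <- ann[match(dn$key, ann$key), ]
      keep <- is_lgd(a$consequence) & is_rare(a, max_af = th$max_af)
      keep[is.na(keep)] <- FALSE
      if (any(keep))
        qual[[fams$family_id[i]]] <- data.frame(
          key = dn$key[keep], proband_id = fams$proband_id[i],
          genes = a$genes[keep], consequence = a$consequence[keep],
          stringsAsFactors = FALSE)
    }
    qual_df <- if (length(qual)) do.call(rbind, qual) else
      data.frame(key = character(0), proband_id = character(0),
                 genes = character(0))
    cnv_pass <- filter_cnvs(cnvs)
    candidates <- aggregate_candidates(qual_df, cnv_pass, pli,
                                       pli_cutoff = th$pli_cutoff)
    write_tsv_file(candidates, file.path(config$outdir,
                                         "candidate_genes.tsv"))
    # LGD-by-de-novo burden over annotated variants of the cohort
    tt <- read_tsv_file(file.path(ws, "truth", "trio_truth.tsv"))
    tab <- table(factor(tt$is_denovo, c(TRUE, FALSE)),
                 factor(is_lgd(tt$consequence), c(TRUE, FALSE)))
    stats <- burden_tests(fisher_tables = list(lgd_by_denovo = unclass(tab)))
    stats_list <- list(n_denovo = n_denovo,
                       n_qualifying_variants = nrow(qual_df),
                       n_candidate_genes = nrow(candidates),
                       n_cnv_included = nrow(cnv_pass),
                       burden = stats)
    jsonlite::write_json(stats_list,
                         file.path(config$outdir, "denovo_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$denovo <- c(list(candidates = candidates), stats_list)
  }

  if (stage_on("network")) {
    message("[network] seed expansion and enrichment")
    edges <- read_interaction_edges(
      need_input("network", file.path(ws, "interaction_edges.tsv")),
      min_score = th$min_score)
    seeds <- readLines(need_input("network", file.path(ws, "seed_genes.txt")))
    background <- readLines(need_input("network",
                                       file.path(ws, "background_genes.txt")))
    annotation <- read_term_annotation(
      need_input("network", file.path(ws, "term_annotation.tsv")))
    net <- expand_network(seeds, edges, k = th$top_k)
    enr <- enrich_terms(intersect(net$nodes$gene, background), annotation,
                        background)
    cov <- ontology_coverage(seeds, annotation)
    write_tsv_file(net$nodes, file.path(config$outdir, "network_nodes.tsv"))
    write_tsv_file(net$edges, file.path(config$outdir, "network_edges.tsv"))
    write_tsv_file(enr, file.path(config$outdir, "term_enrichment.tsv"))
    results$network <- list(network = net, enrichment = enr, coverage = cov)
  }

  if (stage_on("morpho")) {
    message("[morpho] larval feature comparisons")
    feats <- read_larva_features(
      need_input("morpho", file.path(ws, "larva_features.tsv")))
    feature_cols <- setdiff(names(feats), c("larva_id", "group"))
    comps <- do.call(rbind, lapply(feature_cols, function(f)
      compare_feature(feats, f, "test", "control")))
    comps <- adjust_and_star(comps, m = length(feature_cols))
    write_tsv_file(comps, file.path(config$outdir,
                                    "morpho_comparisons.tsv"))
    qp <- ddct_fold_change(
      read_tsv_file(need_input("morpho", file.path(ws, "qpcr_ct.tsv"))),
      "test", "control")
    jsonlite::write_json(qp[c("fold_change", "ddct")],
                         file.path(config$outdir, "qpcr.json"),
                         auto_unbox = TRUE, digits = NA)
    results$morpho <- list(comparisons = comps, qpcr = qp)
  }

  if (stage_on("sc")) {
    message("[sc] single-cell shift analysis")
    sce <- read_cell_matrix(
      need_input("sc", file.path(ws, "sc_counts.mtx")),
      need_input("sc", file.path(ws, "sc_cells.tsv")),
      need_input("sc", file.path(ws, "sc_genes.tsv")))
    targets <- readLines(need_input("sc", file.path(ws, "fmrp_targets.txt")))
    sce <- qc_filter(sce, mito_ribo_max = th$mito_ribo_max,
                     min_features = th$min_features, nfeat_sd = th$nfeat_sd)
    sce <- sc_normalize(sce, n_variable = th$n_variable_genes)
    sce <- cluster_cells(sce, k = min(th$k_broad, ncol(sce)),
                         n_pcs = th$n_pcs)
    write_tsv_file(
      data.frame(cell_id = colnames(sce),
                 cluster = as.character(
                   SummarizedExperiment::colData(sce)$cluster)),
      file.path(config$outdir, "sc_clusters.tsv"))
    de_all <- list(); enr <- list(); fc <- list()
    pairs <- list(kd = c("knockdown", "kd_control"),
                  oe = c("overexpression", "oe_control"))
    conds <- unique(SummarizedExperiment::colData(sce)$condition)
    for (model in names(pairs)) {
      p <- pairs[[model]]
      if (!all(p %in% conds)) next
      sub <- sce[, SummarizedExperiment::colData(sce)$condition %in% p]
      sub <- downsample_to_match(sub, p[1], p[2], seed = config$seed)
      de <- de_wilcoxon(sub, p[1], p[2], logfc_floor = th$logfc_floor,
                        min_pct = th$min_pct)
      write_tsv_file(de, file.path(config$outdir,
                                   paste0("sc_de_", model, ".tsv")))
      expressed <- rownames(sub)[Matrix::rowSums(
        SummarizedExperiment::assay(sub, "counts") > 0) > 0]
      enr[[model]] <- target_set_enrichment(de, targets, expressed,
                                            alpha = th$alpha)
      fc[[model]] <- avg_log2fc_table(sub, p[1], p[2],
                                      expression_floor = th$expression_floor)
      de_all[[model]] <- de
    }
    jsonlite::write_json(
      lapply(enr, function(e) e[c("observed_frac", "expected_frac",
                                  "odds_ratio", "p", "p_bh")]),
      file.path(config$outdir, "sc_enrichment.json"),
      auto_unbox = TRUE, digits = NA)
    if (all(c("kd", "oe") %in% names(fc))) {
      st <- shift_table(fc$kd, fc$oe, targets)
      write_tsv_file(st, file.path(config$outdir, "sc_shift_table.tsv"))
      shift_stats <- geneset_shift_test(st)
      write_tsv_file(shift_stats,
                     file.path(config$outdir, "sc_shift_tests.tsv"))
      results$sc <- list(de = de_all, enrichment = enr, shift = shift_stats)
    } else {
      results$sc <- list(de = de_all, enrichment = enr)
    }
  }

  if (stage_on("report")) {
    message("[report] summarizing")
    lines <- c("asdm pipeline report", "====================")
    summary <- list()
    if (!is.null(results$classify)) {
      cc <- results$classify
      summary$classify <- list(
        n_probands = nrow(cc),
        n_macrocephaly = sum(cc$macrocephaly, na.rm = TRUE),
        subtype_counts = as.list(table(cc$subtype[cc$macrocephaly %in% TRUE])))
      lines <- c(lines, sprintf(
        "classify: %d probands, %d macrocephalic (SO %d / DMac %d / RM %d)",
        nrow(cc), sum(cc$macrocephaly, na.rm = TRUE),
        sum(cc$subtype %in% "SO"), sum(cc$subtype %in% "DMac"),
        sum(cc$subtype %in% "RM")))
    }
    if (!is.null(results$denovo)) {
      dd <- results$denovo
      summary$denovo <- dd[c("n_denovo", "n_qualifying_variants",
                             "n_candidate_genes", "n_cnv_included")]
      lines <- c(lines, sprintf(
        "denovo: %d de novo variants, %d qualifying, %d candidate genes",
        dd$n_denovo, dd$n_qualifying_variants, dd$n_candidate_genes))
    }
    if (!is.null(results$network)) {
      nn <- results$network
      summary$network <- list(
        n_nodes = nrow(nn$network$nodes),
        n_edges = nrow(nn$network$edges),
        top_term = if (nrow(nn$enrichment)) nn$enrichment$term_id[1] else NA,
        seed_coverage = nn$coverage$fraction)
      lines <- c(lines, sprintf(
        "network: %d nodes, %d edges, top term %s, seed coverage %.3f",
        nrow(nn$network$nodes), nrow(nn$network$edges),
        summary$network$top_term, nn$coverage$fraction))
    }
    if (!is.null(results$morpho)) {
      mm <- results$morpho
      summary$morpho <- list(
        n_significant = sum(mm$comparisons$stars != "ns"),
        qpcr_fold_change = mm$qpcr$fold_change)
      lines <- c(lines, sprintf(
        "morpho: %d/%d features significant after Bonferroni, qPCR FC %.3f",
        sum(mm$comparisons$stars != "ns"), nrow(mm$comparisons),
        mm$qpcr$fold_change))
    }
    if (!is.null(results$sc)) {
      ss <- results$sc
      n_sig <- vapply(ss$de, function(d)
        sum(d$p_adj <= config$thresholds$alpha), 1L)
      summary$sc <- list(
        n_tested = lapply(ss$de, nrow), n_deg = as.list(n_sig),
        enrichment_p = lapply(ss$enrichment, `[[`, "p"))
      lines <- c(lines, sprintf(
        "sc: significant DEGs %s; target enrichment p %s",
        paste(names(n_sig), n_sig, collapse = ", "),
        paste(names(ss$enrichment),
              signif(vapply(ss$enrichment, `[[`, 1, "p"), 3),
              collapse = ", ")))
    }
    writeLines(lines, file.path(config$outdir, "report.txt"))
    jsonlite::write_json(summary, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    inputs <- sort(list.files(ws, recursive = TRUE, full.names = TRUE))
    prov <- list(config = config[c("stages", "seed", "sim", "thresholds")],
                 config_hash = config_hash(config),
                 input_checksums = as.list(
                   setNames(unname(tools::md5sum(inputs)),
                            sub(paste0("^", ws, "/?"), "", inputs))))
    jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    results$report <- summary
  }
  invisible(results)
}
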