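#' Single-cell expression shift analysis
#'
#' Cell-by-gene count matrices (stored genes-by-cells in a
#' \linkS4class{SingleCellExperiment}) move through QC filtering,
#' depth-scaling log normalization with variable-gene selection, PCA-based
#' hierarchical clustering with a tree cut, cluster-proportional downsampling
#' of the perturbed condition to match its control, rank-sum differential
#' expression with fold-change and detection floors, target-gene-set Fisher
#' enrichment, and paired/unpaired gene-set fold-change shift tests between
#' a knockdown model and an overexpression model.
#'
#' @name sc_shift
NULL

#' Assemble a cell matrix
#'
#' @param counts Non-negative integer matrix or sparse Matrix, genes in rows,
#'   cells in columns.
#' @param cell_meta data.frame with one row per cell: `cell_id`, `sample_id`,
#'   `condition`, `percent_mito`, `percent_ribo` (0-100), optionally
#'   `doublet` and `cluster`. `n_features` is (re)computed from the counts.
#' @param gene_meta data.frame with `gene_id`, `symbol` per row of `counts`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
make_cell_matrix <- function(counts, cell_meta, gene_meta) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  if (nrow(cell_meta) != ncol(counts))
    stop2("cell_meta rows must match count-matrix columns")
  if (nrow(gene_meta) != nrow(counts))
    stop2("gene_meta rows must match count-matrix rows")
  cell_meta$n_features <- Matrix::colSums(counts > 0)
  rownames(counts) <- gene_meta$gene_id
  colnames(counts) <- cell_meta$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta, row.names = cell_meta$cell_id),
    rowData = S4Vectors::DataFrame(gene_meta, row.names = gene_meta$gene_id))
}

#' Read a cell matrix from Matrix Market + TSV sidecars
#'
#' @param mtx_path Matrix Market file (genes x cells).
#' @param cells_path TSV of cell metadata (see [make_cell_matrix()]).
#' @param genes_path TSV of gene metadata.
#' @return A `SingleCellExperiment`.
#' @export
read_cell_matrix <- function(mtx_path, cells_path, genes_path) {
  counts <- Matrix::readMM(mtx_path)
  make_cell_matrix(counts, read_tsv_file(cells_path),
                   read_tsv_file(genes_path))
}

#' Write a cell matrix to Matrix Market + TSV sidecars
#'
#' @param sce A `SingleCellExperiment`.
#' @param prefix Output path prefix; writes `<prefix>_counts.mtx`,
#'   `<prefix>_cells.tsv`, `<prefix>_genes.tsv`.
#' @return The three paths, invisibly.
#' @export
write_cell_matrix <- function(sce, prefix) {
  paths <- paste0(prefix, c("_counts.mtx", "_cells.tsv", "_genes.tsv"))
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"), paths[1])
  write_tsv_file(as.data.frame(SummarizedExperiment::colData(sce)), paths[2])
  write_tsv_file(as.data.frame(SummarizedExperiment::rowData(sce)), paths[3])
  invisible(paths)
}

#' Quality-control cell filtering
#'
#' Removes cells with mitochondrial or ribosomal percentage above
#' `mito_ribo_max`, feature counts strictly below `min_features`, feature
#' counts above the sample mean plus `nfeat_sd` standard deviations (mean and
#' SD computed over the pre-filter cells of the same sample), and flagged
#' doublets when a `doublet` column is present. Set `nfeat_sd = Inf` to
#' disable the sample-relative upper rule.
#'
#' @param sce A `SingleCellExperiment` from [make_cell_matrix()].
#' @param mito_ribo_max Percentage cutoff (default 5).
#' @param min_features Minimum feature count (default 200; "below" is
#'   strict, so exactly 200 is retained).
#' @param nfeat_sd SD multiple for the upper feature-count rule (default 2).
#' @return Filtered `SingleCellExperiment`; per-rule removal counts and cell
#'   ids in `S4Vectors::metadata(sce)$qc_report`.
#' @export
qc_filter <- function(sce, mito_ribo_max = 5, min_features = 200,
                      nfeat_sd = 2) {
  cd <- SummarizedExperiment::colData(sce)
  mito <- cd$percent_mito > mito_ribo_max
  ribo <- cd$percent_ribo > mito_ribo_max
  low <- cd$n_features < min_features
  high <- rep(FALSE, ncol(sce))
  if (is.finite(nfeat_sd)) {
    for (s in unique(cd$sample_id)) {
      i <- cd$sample_id == s
      if (sum(i) < 2) next
      cut <- mean(cd$n_features[i]) + nfeat_sd * sd(cd$n_features[i])
      high[i] <- cd$n_features[i] > cut
    }
  }
  doub <- if ("doublet" %in% names(cd)) cd$doublet else rep(FALSE, ncol(sce))
  drop <- mito | ribo | low | high | doub
  out <- sce[, !drop]
  report <- list(
    removed = colnames(sce)[drop],
    by_rule = list(percent_mito = colnames(sce)[mito],
                   percent_ribo = colnames(sce)[ribo],
                   low_features = colnames(sce)[low],
                   high_features = colnames(sce)[high],
                   doublet = colnames(sce)[doub]),
    n_removed = sum(drop), n_kept = sum(!drop))
  small <- table(SummarizedExperiment::colData(out)$sample_id) < 10
  if (any(small))
    warning("sample(s) with < 10 cells after filtering: ",
            paste(names(small)[small], collapse = ", "))
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Depth-scaling log normalization and variable-gene selection
#'
#' Counts are scaled per cell to the median library size and transformed
#' with `log1p` (natural log), stored as the `lognorm` assay. The
#' `n_variable` most variable genes are selected by the variance of
#' standardized counts (per-gene counts standardized by their expected SD
#' from a loess fit of log variance on log mean, clipped at `sqrt(n)`), and
#' recorded in `metadata(sce)$variable_genes` for clustering. Optionally the
#' log-normalized values are residualized per gene on mitochondrial and
#' ribosomal percentages.
#'
#' @param sce QC-filtered `SingleCellExperiment`.
#' @param n_variable Number of variable genes (default 5000, capped at the
#'   gene count).
#' @param regress Residualize on `percent_mito`/`percent_ribo` (default
#'   `FALSE`).
#' @return `sce` with a `lognorm` assay and `variable_genes` metadata.
#' @export
sc_normalize <- function(sce, n_variable = 5000, regress = FALSE) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) stop2("zero-depth cell encountered after QC")
  target <- median(depth)
  lognorm <- counts %*% Matrix::Diagonal(x = target / depth)
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "lognorm") <- lognorm
  S4Vectors::metadata(sce)$variable_genes <-
    variable_genes(counts, n = n_variable)
  if (regress) {
    cd <- SummarizedExperiment::colData(sce)
    X <- cbind(1, cd$percent_mito, cd$percent_ribo)
    dense <- as.matrix(lognorm)
    beta <- t(solve(crossprod(X), crossprod(X, t(dense))))
    resid <- dense - beta %*% t(X)
    SummarizedExperiment::assay(sce, "lognorm") <-
      methods::as(resid, "CsparseMatrix")
  }
  sce
}

# standardized-variance variable-gene ranking (vst flavor): fit expected
# log10 variance as a loess in log10 mean, clip standardized counts, rank by
# their variance; constant genes are never selected
variable_genes <- function(counts, n) {
  mu <- Matrix::rowMeans(counts)
  m2 <- Matrix::rowMeans(counts^2)
  v <- (m2 - mu^2) * ncol(counts) / max(1, ncol(counts) - 1)
  ok <- !is.na(v) & v > 0 & mu > 0
  if (sum(ok) < 3) return(rownames(counts)[ok])
  esd <- if (sum(ok) >= 50) {
    # loess mean-variance trend needs a reasonable number of genes
    fit <- tryCatch(
      suppressWarnings(loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3,
                             degree = 2)),
      error = function(e) NULL)
    if (is.null(fit)) sqrt(mu[ok]) else sqrt(10^predict(fit))
  } else {
    sqrt(mu[ok])  # Poisson expectation at small gene counts
  }
  clip <- sqrt(ncol(counts))
  dense <- as.matrix(counts[ok, , drop = FALSE])
  z <- pmin((dense - mu[ok]) / esd, clip)
  sv <- apply(z, 1, var)
  names(sv) <- rownames(counts)[ok]
  names(sort(sv, decreasing = TRUE))[seq_len(min(n, length(sv)))]
}

#' PCA-based hierarchical clustering with a tree cut
#'
#' PCA of the log-normalized expression of the variable genes (cells scored
#' on the first `n_pcs` components, component signs fixed by forcing the
#' largest-magnitude gene loading positive), Euclidean distances between
#' cells in that embedding, agglomerative clustering (Ward linkage by
#' default) and a cut of the dendrogram into `k` flat clusters.
#'
#' @param sce Normalized `SingleCellExperiment` (see [sc_normalize()]).
#' @param k Number of clusters.
#' @param n_pcs Principal components to use (default 30, capped by the data).
#' @param linkage `hclust` method (default `"ward.D2"`; `"complete"` and
#'   `"average"` also supported).
#' @return `sce` with a `cluster` column (factor) in `colData` and the cell
#'   embedding in `reducedDim(sce, "PCA")`.
#' @export
cluster_cells <- function(sce, k, n_pcs = 30, linkage = "ward.D2") {
  if (k > ncol(sce)) stop2("k exceeds the number of cells")
  vg <- S4Vectors::metadata(sce)$variable_genes
  if (is.null(vg)) stop2("run sc_normalize() before cluster_cells()")
  expr <- t(as.matrix(SummarizedExperiment::assay(sce, "lognorm")[vg, ,
                                                                  drop = FALSE]))
  keep <- apply(expr, 2, var) > 0
  expr <- expr[, keep, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(expr) - 1L, nrow(expr) - 1L)
  pc <- prcomp(expr, center = TRUE, scale. = TRUE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    w <- pc$rotation[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  emb <- sweep(pc$x, 2, flip, `*`)
  if (k == 1) {
    cl <- rep(1L, ncol(sce))
  } else {
    hc <- hclust(dist(emb), method = linkage)
    cl <- cutree(hc, k = k)
  }
  SummarizedExperiment::colData(sce)$cluster <- factor(unname(cl))
  SingleCellExperiment::reducedDim(sce, "PCA") <- emb
  sce
}

#' Downsample a perturbed condition to match its control
#'
#' Test cells are sampled without replacement so their total matches the
#' control total while preserving the test condition's own cluster
#' proportions (`mode = "proportional"`, the default): the control total is
#' allocated across clusters proportionally to the test cluster distribution
#' (largest-remainder rounding), and each cluster retains
#' `min(available, target)` cells. `mode = "per_cluster"` instead matches the
#' control's per-cluster counts. Control cells are untouched; the draw is
#' deterministic under `seed`.
#'
#' @param sce Clustered `SingleCellExperiment`.
#' @param test_condition,control_condition Values of `colData()$condition`.
#' @param seed Integer seed for the sampling.
#' @param mode Allocation mode (see above).
#' @return `sce` restricted to the sampled test cells plus all other cells;
#'   shortfall per cluster in `metadata(sce)$downsample_report`.
#' @export
downsample_to_match <- function(sce, test_condition, control_condition, seed,
                                mode = c("proportional", "per_cluster")) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$cluster)) stop2("cluster labels required; run cluster_cells()")
  test_i <- which(cd$condition == test_condition)
  ctrl_i <- which(cd$condition == control_condition)
  clusters <- sort(unique(as.character(cd$cluster)))
  avail <- table(factor(as.character(cd$cluster[test_i]), levels = clusters))
  if (mode == "proportional") {
    target_total <- length(ctrl_i)
    raw <- as.numeric(avail) / max(1, sum(avail)) * target_total
    target <- floor(raw)
    rem <- target_total - sum(target)
    if (rem > 0) {
      ord <- order(-(raw - floor(raw)), clusters)
      target[ord[seq_len(rem)]] <- target[ord[seq_len(rem)]] + 1L
    }
  } else {
    target <- as.numeric(table(factor(as.character(cd$cluster[ctrl_i]),
                                      levels = clusters)))
  }
  names(target) <- clusters
  keep_ids <- character(0)
  shortfall <- integer(0)
  set.seed(seed)
  for (cl in clusters) {
    ids <- colnames(sce)[test_i][as.character(cd$cluster[test_i]) == cl]
    n_take <- min(length(ids), target[[cl]])
    shortfall[[cl]] <- target[[cl]] - n_take
    keep_ids <- c(keep_ids, sort(sample(ids, n_take)))
  }
  drop <- setdiff(colnames(sce)[test_i], keep_ids)
  out <- sce[, !(colnames(sce) %in% drop)]
  S4Vectors::metadata(out)$downsample_report <-
    list(mode = mode, target = target, shortfall = shortfall,
         kept_test_cells = length(keep_ids))
  out
}

# rank-sum p for each row of a dense matrix, columns split into two groups;
# normal approximation with tie correction + continuity correction (group
# sizes here are far beyond the exact regime)
ranksum_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  apply(mat[, c(idx1, idx2), drop = FALSE], 1, function(x) {
    r <- rank(x)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- u - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Rank-sum differential expression
#'
#' Genes detected in at least `min_pct` of cells in either group are tested.
#' The log2 fold change is `log2((mean(expm1(test)) + eps) /
#' (mean(expm1(control)) + eps))` over the log-normalized layer with
#' `eps = 1e-9`; genes below `logfc_floor` in absolute value are skipped.
#' Two-sided rank-sum p-values (midranks) are Benjamini-Hochberg adjusted
#' over the tested genes. In `one_vs_rest` mode (`group_test` a cluster
#' label, `group_control = NULL`) only positive-fold-change genes are kept
#' and a raw-p `return_thresh` applies, as in marker detection.
#'
#' @param sce Normalized `SingleCellExperiment`.
#' @param group_test,group_control Condition labels (two-group mode) or a
#'   cluster label and `NULL` (one-vs-rest mode).
#' @param logfc_floor Minimum |log2FC| to test (default 0.1).
#' @param min_pct Minimum detection fraction in either group (default 0.01).
#' @param mode `"two_group"` or `"one_vs_rest"`.
#' @param return_thresh Raw-p cutoff in one-vs-rest mode (default 0.01).
#' @param eps Pseudocount on de-logged means (default 1e-9).
#' @return data.frame `gene`, `log2fc`, `pct_test`, `pct_control`, `p`,
#'   `p_adj`, `direction`, ordered by `p`; the number of genes passing
#'   `min_pct` in `attr(, "n_detected")`.
#' @export
de_wilcoxon <- function(sce, group_test, group_control = NULL,
                        logfc_floor = 0.1, min_pct = 0.01,
                        mode = c("two_group", "one_vs_rest"),
                        return_thresh = 0.01, eps = 1e-9) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(sce)
  if (mode == "two_group") {
    idx1 <- which(cd$condition == group_test)
    idx2 <- which(cd$condition == group_control)
  } else {
    idx1 <- which(as.character(cd$cluster) == as.character(group_test))
    idx2 <- setdiff(seq_len(ncol(sce)), idx1)
  }
  if (length(idx1) == 0 || length(idx2) == 0)
    stop2("a comparison group has zero cells")
  expr <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  pct1 <- rowMeans(expr[, idx1, drop = FALSE] > 0)
  pct2 <- rowMeans(expr[, idx2, drop = FALSE] > 0)
  detected <- pct1 >= min_pct | pct2 >= min_pct
  mu1 <- rowMeans(expm1(expr[, idx1, drop = FALSE]))
  mu2 <- rowMeans(expm1(expr[, idx2, drop = FALSE]))
  log2fc <- log2((mu1 + eps) / (mu2 + eps))
  test_me <- detected & abs(log2fc) >= logfc_floor
  if (mode == "one_vs_rest") test_me <- test_me & log2fc > 0
  out <- data.frame(gene = rownames(expr)[test_me],
                    log2fc = log2fc[test_me],
                    pct_test = pct1[test_me], pct_control = pct2[test_me],
                    stringsAsFactors = FALSE)
  out$p <- if (nrow(out)) ranksum_rows(expr[test_me, , drop = FALSE],
                                       idx1, idx2) else numeric(0)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  if (mode == "one_vs_rest") out <- out[out$p <= return_thresh, , drop = FALSE]
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_detected") <- sum(detected)
  out
}

#' Target-gene-set enrichment among differentially expressed genes
#'
#' Two-sided Fisher's exact test on the 2x2 classification of the expressed
#' background into DEG / non-DEG by target / non-target, where DEGs are the
#' rows of `de_results` with adjusted p at or below `alpha`. The expected
#' fraction is the target share of the background; the observed fraction is
#' the target share of the DEGs. When `family_p` supplies the raw p-values
#' of sibling enrichment tests, the returned `p_bh` is adjusted across the
#' family (this test last).
#'
#' @param de_results data.frame from [de_wilcoxon()].
#' @param target_genes Non-empty character vector.
#' @param expressed_background Character vector, the expressed gene universe.
#' @param alpha Adjusted-p DEG cutoff (default 0.05).
#' @param family_p Numeric vector of sibling raw p-values (optional).
#' @return List: `observed_frac`, `expected_frac`, `odds_ratio`, `p`,
#'   `p_bh`, `table`.
#' @export
target_set_enrichment <- function(de_results, target_genes,
                                  expressed_background, alpha = 0.05,
                                  family_p = NULL) {
  if (length(target_genes) == 0) stop2("target gene set is empty")
  bg <- unique(expressed_background)
  targets <- intersect(unique(target_genes), bg)
  degs <- intersect(de_results$gene[de_results$p_adj <= alpha], bg)
  if (length(degs) == 0) {
    warning("empty DEG set; p set to 1")
    return(list(observed_frac = NA_real_,
                expected_frac = length(targets) / length(bg),
                odds_ratio = NA_real_, p = 1, p_bh = 1, table = NULL))
  }
  in_deg <- bg %in% degs
  in_tgt <- bg %in% targets
  tab <- matrix(c(sum(in_deg & in_tgt), sum(in_deg & !in_tgt),
                  sum(!in_deg & in_tgt), sum(!in_deg & !in_tgt)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("deg", "non_deg"),
                                c("target", "non_target")))
  ft <- fisher.test(tab, alternative = "two.sided")
  p_bh <- if (is.null(family_p)) p.adjust(ft$p.value, method = "BH") else
    p.adjust(c(family_p, ft$p.value), method = "BH")[length(family_p) + 1L]
  list(observed_frac = sum(in_deg & in_tgt) / sum(in_deg),
       expected_frac = sum(in_tgt) / length(bg),
       odds_ratio = unname(ft$estimate), p = ft$p.value, p_bh = p_bh,
       table = tab)
}

#' Map gene symbols through an ortholog table
#'
#' All mapped symbols are returned deduplicated; one-to-many expansions are
#' kept and unmapped inputs are reported.
#'
#' @param genes Character vector of source symbols.
#' @param map_table data.frame with columns `human_symbol`,
#'   `zebrafish_symbol` (or a TSV path).
#' @return List with `mapped` (character) and `unmapped` (character).
#' @export
ortholog_map <- function(genes, map_table) {
  if (!is.data.frame(map_table)) map_table <- read_tsv_file(map_table)
  req <- c("human_symbol", "zebrafish_symbol")
  if (!all(req %in% names(map_table)))
    stop2("ortholog map needs columns: ", paste(req, collapse = ", "))
  hit <- map_table[map_table$human_symbol %in% genes, ]
  list(mapped = unique(hit$zebrafish_symbol),
       unmapped = sort(setdiff(genes, map_table$human_symbol)))
}

#' Per-gene average log2 fold change for the shift analysis
#'
#' Computes, for genes expressed (detected) in at least `expression_floor`
#' fraction of cells in both conditions, the DE-style group-mean log2 ratio
#' of de-logged normalized expression.
#'
#' @param sce Normalized `SingleCellExperiment`.
#' @param test_condition,control_condition Condition labels.
#' @param expression_floor Detection-fraction floor applied in both
#'   conditions (default 1e-4, i.e. 0.01% of cells).
#' @param eps Pseudocount (default 1e-9).
#' @return data.frame `gene`, `avg_log2fc`.
#' @export
avg_log2fc_table <- function(sce, test_condition, control_condition,
                             expression_floor = 1e-4, eps = 1e-9) {
  cd <- SummarizedExperiment::colData(sce)
  idx1 <- which(cd$condition == test_condition)
  idx2 <- which(cd$condition == control_condition)
  if (length(idx1) == 0 || length(idx2) == 0)
    stop2("a condition has zero cells")
  expr <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  keep <- rowMeans(expr[, idx1, drop = FALSE] > 0) >= expression_floor &
    rowMeans(expr[, idx2, drop = FALSE] > 0) >= expression_floor
  mu1 <- rowMeans(expm1(expr[keep, idx1, drop = FALSE]))
  mu2 <- rowMeans(expm1(expr[keep, idx2, drop = FALSE]))
  data.frame(gene = rownames(expr)[keep],
             avg_log2fc = log2((mu1 + eps) / (mu2 + eps)),
             stringsAsFactors = FALSE)
}

#' Build a gene-set shift table from two models
#'
#' Joins the per-gene average log2 fold changes of the knockdown and
#' overexpression models over their shared genes and flags membership in the
#' target set.
#'
#' @param fc_kd,fc_oe data.frames from [avg_log2fc_table()].
#' @param target_genes Character vector.
#' @param scope Label recorded in the table (e.g. `"all_cells"`,
#'   `"brain_cells"`).
#' @return data.frame `gene`, `avg_log2fc_kd`, `avg_log2fc_oe`, `scope`,
#'   `in_target_set`.
#' @export
shift_table <- function(fc_kd, fc_oe, target_genes, scope = "all_cells") {
  shared <- intersect(fc_kd$gene, fc_oe$gene)
  data.frame(gene = shared,
             avg_log2fc_kd = fc_kd$avg_log2fc[match(shared, fc_kd$gene)],
             avg_log2fc_oe = fc_oe$avg_log2fc[match(shared, fc_oe$gene)],
             scope = scope,
             in_target_set = shared %in% target_genes,
             stringsAsFactors = FALSE)
}

#' Gene-set fold-change shift tests
#'
#' Between models: paired two-sided t-test of the overexpression versus
#' knockdown average log2 fold changes over the shared target genes. Within
#' each model: unpaired two-sided t-test of target versus non-target genes.
#' Group medians are reported alongside.
#'
#' @param shift_tab data.frame from [shift_table()].
#' @return data.frame with one row per test: `test`, `scope`, `n_target`,
#'   `n_other`, `statistic`, `p`, `median_target`, `median_other`.
#' @export
geneset_shift_test <- function(shift_tab) {
  tg <- shift_tab[shift_tab$in_target_set, ]
  ot <- shift_tab[!shift_tab$in_target_set, ]
  if (nrow(tg) < 3) stop2("need >= 3 target genes in the shift table")
  scope <- shift_tab$scope[1]
  safe_t <- function(...) {
    degenerate <- list(statistic = c(t = 0), p.value = 1)  # zero variance
    out <- tryCatch(t.test(...), error = function(e) degenerate)
    if (!is.finite(unname(out$statistic))) degenerate else out
  }
  paired <- safe_t(tg$avg_log2fc_oe, tg$avg_log2fc_kd, paired = TRUE)
  rows <- list(data.frame(
    test = "paired_oe_vs_kd_targets", scope = scope,
    n_target = nrow(tg), n_other = NA_integer_,
    statistic = unname(paired$statistic), p = paired$p.value,
    median_target = median(tg$avg_log2fc_oe - tg$avg_log2fc_kd),
    median_other = NA_real_, stringsAsFactors = FALSE))
  for (model in c("kd", "oe")) {
    col <- paste0("avg_log2fc_", model)
    if (nrow(ot) >= 3) {
      tt <- safe_t(tg[[col]], ot[[col]])
      rows[[length(rows) + 1L]] <- data.frame(
        test = paste0("unpaired_target_vs_other_", model), scope = scope,
        n_target = nrow(tg), n_other = nrow(ot),
        statistic = unname(tt$statistic), p = tt$p.value,
        median_target = median(tg[[col]]), median_other = median(ot[[col]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
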