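#' Larval morphometric group comparisons
#'
#' Features extracted from standardized larval images (total area, body
#' length, eye distance, telencephalon width, head-trunk angle, midbrain and
#' forebrain area) are compared between an injected group and its control
#' with a two-sided rank-sum test, a median-ratio fold change, Bonferroni
#' adjustment over the experiment's feature family and significance stars.
#'
#' @name morphometrics
NULL

# FishInspector export column names accepted as aliases
.fishinspector_aliases <- c(
  contourDV_regionpropsArea = "total_area",
  contourDV_regionpropsLengthOfCentralLine = "body_length",
  YdistanceCenter_eye1DV_eye2DV = "eye_distance",
  YdistanceEdge_eye1DV_eye2DV = "telencephalon_width"
)

#' Read a larval feature table
#'
#' TSV with columns `larva_id`, `group` and one column per feature;
#' FishInspector export names are renamed to their canonical aliases.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_larva_features <- function(path) {
  tab <- read_tsv_file(path)
  hits <- names(tab) %in% names(.fishinspector_aliases)
  names(tab)[hits] <- .fishinspector_aliases[names(tab)[hits]]
  if (!all(c("larva_id", "group") %in% names(tab)))
    stop2("feature table needs larva_id and group columns")
  tab
}

#' Compare one morphometric feature between two groups
#'
#' Two-sided Wilcoxon rank-sum test (see [rank_sum_test()]) with fold change
#' defined as median(test) / median(control) (mean ratio by `fold = "mean"`).
#'
#' @param table Feature data.frame (see [read_larva_features()]).
#' @param feature Feature column name.
#' @param test_group,control_group Values of `group` to compare.
#' @param fold `"median"` (default) or `"mean"` ratio fold change.
#' @return A one-row data.frame: `feature`, `group_test`, `group_control`,
#'   `n_test`, `n_control`, `fold_change`, `statistic`, `p`.
#' @export
compare_feature <- function(table, feature, test_group, control_group,
                            fold = c("median", "mean")) {
  fold <- match.arg(fold)
  if (!feature %in% names(table)) stop2("unknown feature: ", feature)
  x <- table[[feature]][table$group == test_group]
  y <- table[[feature]][table$group == control_group]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop2("need >= 3 non-missing larvae per group for ", feature)
  agg <- if (fold == "median") median else mean
  ts <- rank_sum_test(x, y)
  data.frame(feature = feature, group_test = test_group,
             group_control = control_group,
             n_test = length(x), n_control = length(y),
             fold_change = agg(x) / agg(y),
             statistic = ts$statistic, p = ts$p.value,
             stringsAsFactors = FALSE)
}

#' Bonferroni-adjust comparisons and assign stars
#'
#' `p_adjusted = min(1, m * p)` with `m` the family size (by convention the
#' number of features tested in the experiment, e.g. 4 gross morphometric
#' features or 2 brain areas). Stars follow inclusive thresholds on the
#' adjusted p: `<= 0.05` \*, `<= 0.01` \*\*, `<= 0.001` \*\*\*.
#'
#' @param comparisons data.frame of [compare_feature()] rows.
#' @param m Family size; defaults to `nrow(comparisons)` and must be at least
#'   that.
#' @return `comparisons` with `p_adjusted` and `stars` columns.
#' @export
adjust_and_star <- function(comparisons, m = nrow(comparisons)) {
  if (m < nrow(comparisons))
    stop2("family size m must be >= number of comparisons")
  comparisons$p_adjusted <- pmin(1, m * comparisons$p)
  comparisons$stars <- star_code(comparisons$p_adjusted)
  comparisons
}

star_code <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Per group, the mean Ct of the target gene minus the mean Ct of the
#' reference gene gives delta-Ct; the test-minus-control difference of those
#' is delta-delta-Ct and fold change is `2^(-ddCt)`. Replicate-level fold
#' changes (each test replicate's delta-Ct against the control-group mean
#' delta-Ct) are returned for dispersion checks.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene` (values
#'   `"target"`/`"reference"`), `ct_value`.
#' @param test_group,control_group Group labels.
#' @return List with `fold_change`, `ddct`, per-group `dct`, and
#'   `replicate_fc`.
#' @export
ddct_fold_change <- function(ct, test_group, control_group) {
  need <- c("sample", "group", "gene", "ct_value")
  if (!all(need %in% names(ct))) stop2("ct table needs: ",
                                       paste(need, collapse = ", "))
  for (g in c(test_group, control_group)) {
    sub <- ct[ct$group == g, ]
    if (!all(c("target", "reference") %in% sub$gene))
      stop2("group '", g, "' missing target or reference gene measurements")
    if (min(table(sub$gene)[c("target", "reference")]) < 3)
      stop2("need >= 3 replicates per gene in group '", g, "'")
  }
  dct_group <- function(g) {
    sub <- ct[ct$group == g, ]
    mean(sub$ct_value[sub$gene == "target"]) -
      mean(sub$ct_value[sub$gene == "reference"])
  }
  dct_t <- dct_group(test_group); dct_c <- dct_group(control_group)
  ddct <- dct_t - dct_c
  # per-replicate: pair target and reference Ct within each test sample
  sub <- ct[ct$group == test_group, ]
  reps <- vapply(unique(sub$sample), function(s) {
    tt <- sub$ct_value[sub$sample == s & sub$gene == "target"]
    rr <- sub$ct_value[sub$sample == s & sub$gene == "reference"]
    2^(-(mean(tt) - mean(rr) - dct_c))
  }, numeric(1))
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct = c(test = dct_t, control = dct_c), replicate_fc = reps)
}
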