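#' De novo likely gene-disruptive variant discovery in trios
#'
#' Variants are normalized to a minimal left-aligned representation and keyed
#' `chrom:pos:ref:alt` so proband-versus-parent comparison is robust to
#' representation differences. A de novo call requires at least one alternate
#' allele in the proband and the allele's absence from both parents at the
#' same normalized key. Candidate variants are likely gene-disruptive
#' (frameshift, stop-gain or splice-site), rare (allele frequency below 0.2%
#' in all five continental reference populations, or absent from dbSNP for
#' probands without parental data), and copy-number calls are included when
#' precise, exonic and impacting at most two genes. Candidates aggregate to
#' genes with distinct-proband recurrence and a constraint flag (pLI > 0.9).
#'
#' @name trio_variants
NULL

#' Normalize a variant to its minimal left-aligned representation
#'
#' Right-trims shared suffix bases, left-trims shared prefix bases (advancing
#' `pos`), and, when reference context is supplied, left-aligns indels by
#' shifting through repeats until no further move is possible. Multiallelic
#' records should be split before calling (see [split_multiallelic()]).
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings (`ref != alt`).
#' @param context Optional reference sequence string covering the variant
#'   locus, used for left-alignment and `ref` validation.
#' @param context_start 1-based genomic position of `substr(context, 1, 1)`.
#' @return List with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, context = NULL,
                              context_start = 1L) {
  if (ref == alt) stop2("ref and alt must differ")
  if (!is.null(context)) {
    off <- pos - context_start + 1L
    if (off < 1L || substr(context, off, off + nchar(ref) - 1L) != ref)
      stop2("ref allele inconsistent with supplied reference context at pos ",
            pos)
  }
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    changed <- FALSE
    # right-trim a shared suffix base; if an allele would empty, extend both
    # alleles left from the reference context (classic left-alignment step)
    if (nchar(ref) > 0 && nchar(alt) > 0 && last(ref) == last(alt)) {
      can_extend <- !is.null(context) && (pos - context_start) >= 1L
      if (min(nchar(ref), nchar(alt)) > 1L || can_extend) {
        ref <- substr(ref, 1, nchar(ref) - 1L)
        alt <- substr(alt, 1, nchar(alt) - 1L)
        if (nchar(ref) == 0L || nchar(alt) == 0L) {
          off <- pos - context_start  # context index of the base at pos - 1
          b <- substr(context, off, off)
          ref <- paste0(b, ref); alt <- paste0(b, alt)
          pos <- pos - 1L
        }
        changed <- TRUE
      }
    }
    # left-trim a shared prefix base while both alleles keep >= 1 base
    if (!changed && nchar(ref) >= 2 && nchar(alt) >= 2 &&
        substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Split multiallelic variant rows
#'
#' One output row per ALT allele; genotype strings are recoded per allele
#' (the split allele becomes `1`, any other alternate allele `0`).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated alternates allowed).
#' @param gt Character genotype matrix, rows aligned to `variants`, entries
#'   like `"0/1"` with allele indices into `c(ref, alts)`.
#' @return List of expanded `variants` and `gt`.
#' @export
split_multiallelic <- function(variants, gt) {
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  n_out <- lengths(alts)
  idx <- rep(seq_len(nrow(variants)), n_out)
  a_i <- unlist(lapply(n_out, seq_len))
  out <- variants[idx, , drop = FALSE]
  out$alt <- unlist(alts)
  rownames(out) <- NULL
  if (!is.null(gt)) {
    gt_out <- gt[idx, , drop = FALSE]
    recode <- function(g, allele) {
      if (is.na(g)) return(NA_character_)
      toks <- strsplit(g, "[/|]")[[1]]
      toks <- ifelse(toks == ".", NA, ifelse(toks == allele, "1", "0"))
      if (anyNA(toks)) return(NA_character_)
      paste(toks, collapse = "/")
    }
    for (i in seq_len(nrow(gt_out)))
      gt_out[i, ] <- vapply(gt_out[i, ], recode, "", allele = as.character(a_i[i]))
    gt <- gt_out
  }
  list(variants = out, gt = gt)
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors describing normalized variants.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Normalize a variant table and attach keys
#'
#' Splits multiallelic records, minimally represents each allele pair
#' (left-aligning against `contexts` when given) and adds a `key` column.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gt Optional genotype matrix aligned to rows.
#' @param contexts Optional named list of reference context strings per
#'   chromosome (each assumed to start at position 1).
#' @return List of `variants` (with `key`) and `gt`.
#' @export
normalize_variant_table <- function(variants, gt = NULL, contexts = NULL) {
  sp <- split_multiallelic(variants, gt)
  v <- sp$variants
  for (i in seq_len(nrow(v))) {
    ctx <- if (!is.null(contexts)) contexts[[v$chrom[i]]] else NULL
    nv <- normalize_variant(v$pos[i], v$ref[i], v$alt[i], context = ctx)
    v$pos[i] <- nv$pos; v$ref[i] <- nv$ref; v$alt[i] <- nv$alt
  }
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  list(variants = v, gt = sp$gt)
}

#' Read a trio VCF
#'
#' Reads a VCF (one family or joint) via \pkg{vcfR} and returns the variant
#' table plus a genotype matrix; set `normalize = TRUE` (default) to split
#' multiallelics and key variants by their minimal representation.
#'
#' @param path VCF path.
#' @param normalize Normalize and key variants.
#' @return List of `variants` data.frame and `gt` matrix (samples in
#'   columns).
#' @export
read_trio_vcf <- function(path, normalize = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  variants <- data.frame(chrom = fx[, "CHROM"],
                         pos = as.integer(fx[, "POS"]),
                         ref = fx[, "REF"], alt = fx[, "ALT"],
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- NULL
  if (normalize) normalize_variant_table(variants, gt)
  else {
    variants$key <- variant_key(variants$chrom, variants$pos, variants$ref,
                                variants$alt)
    list(variants = variants, gt = gt)
  }
}

carries_alt <- function(g) !is.na(g) & grepl("1", g, fixed = TRUE)

#' Find de novo variants in a trio
#'
#' Keeps variants where the proband carries at least one alternate allele and
#' both parents were genotyped without that allele at the same normalized
#' key. Sites where a parent genotype is missing are excluded (conservative)
#' and listed in the `excluded_missing` attribute.
#'
#' @param variants Normalized variant data.frame with `key`.
#' @param gt Genotype matrix with columns named by sample id.
#' @param family List/row with `proband_id`, `father_id`, `mother_id`.
#' @return Subset of `variants`; excluded-for-missing keys in
#'   `attr(, "excluded_missing")`.
#' @export
find_denovo <- function(variants, gt, family) {
  if (nrow(variants) != nrow(gt))
    stop2("variants and genotype matrix must have aligned rows")
  ids <- c(family$proband_id, family$father_id, family$mother_id)
  if (!all(ids %in% colnames(gt)))
    stop2("trio samples absent from genotype matrix: ",
          paste(setdiff(ids, colnames(gt)), collapse = ", "))
  pro <- gt[, family$proband_id]
  fa <- gt[, family$father_id]
  mo <- gt[, family$mother_id]
  has_alt <- carries_alt(pro)
  parent_missing <- has_alt & (is.na(fa) | is.na(mo))
  keep <- has_alt & !parent_missing & !carries_alt(fa) & !carries_alt(mo)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_missing") <- variants$key[parent_missing]
  out
}

#' Likely gene-disruptive consequence?
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical: `TRUE` for frameshift, stop-gain or splice-site.
#' @export
is_lgd <- function(consequence) {
  consequence %in% c("frameshift", "stop_gained", "splice_site")
}

#' Rare-variant predicate
#'
#' Trio mode: allele frequency strictly below `max_af` in all five
#' continental reference populations (AFR, AMR, EAS, EUR, SAS); a missing
#' population frequency counts as 0. Non-trio mode (no parental genotypes):
#' rare means absent from dbSNP.
#'
#' @param af data.frame/matrix with columns `af_afr`, `af_amr`, `af_eas`,
#'   `af_eur`, `af_sas` (trio mode) and/or logical `in_dbsnp` (non-trio
#'   mode).
#' @param max_af Frequency cutoff, default 0.002 (0.2%).
#' @param mode `"trio"` or `"non_trio"`.
#' @return Logical vector.
#' @export
is_rare <- function(af, max_af = 0.002, mode = c("trio", "non_trio")) {
  mode <- match.arg(mode)
  if (mode == "non_trio") {
    if (!"in_dbsnp" %in% names(af)) stop2("non-trio mode needs in_dbsnp")
    return(!af$in_dbsnp)
  }
  cols <- c("af_afr", "af_amr", "af_eas", "af_eur", "af_sas")
  if (!all(cols %in% names(af))) stop2("trio mode needs columns: ",
                                       paste(cols, collapse = ", "))
  m <- as.matrix(as.data.frame(af)[cols])
  m[is.na(m)] <- 0
  apply(m < max_af, 1, all)
}

#' Copy-number variant inclusion rule
#'
#' Keeps calls that are precise, exonic and impact no more than two genes.
#'
#' @param cnvs data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `copy_number`, `precise`, `exonic`, `genes_impacted` (comma-separated).
#' @return Filtered data.frame.
#' @export
filter_cnvs <- function(cnvs) {
  n_genes <- vapply(strsplit(cnvs$genes_impacted, ",", fixed = TRUE),
                    function(g) length(g[nzchar(g)]), integer(1))
  out <- cnvs[cnvs$precise & cnvs$exonic & n_genes <= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate qualifying variants to candidate genes
#'
#' One record per gene hit by a qualifying de novo LGD variant or included
#' CNV; recurrence counts distinct probands (two variants in one proband
#' count once), CNVs credit every impacted gene, and `pli_flag` marks
#' constraint (pLI > 0.9). Variants without a gene annotation are skipped and
#' reported.
#'
#' @param variants data.frame with `key`, `proband_id` and `genes`
#'   (comma-separated symbols); may be empty.
#' @param cnvs Filtered CNV data.frame with `proband_id` and
#'   `genes_impacted`; may be `NULL`.
#' @param pli Named numeric vector of pLI scores per gene (optional).
#' @param pli_cutoff Constraint cutoff, default 0.9.
#' @return data.frame `gene`, `n_probands`, `variant_ids`
#'   (comma-separated), `pli`, `pli_flag`, ordered by decreasing recurrence
#'   then gene; skipped variant keys in `attr(, "skipped")`.
#' @export
aggregate_candidates <- function(variants, cnvs = NULL, pli = NULL,
                                 pli_cutoff = 0.9) {
  rows <- list()
  skipped <- character(0)
  add <- function(genes_str, proband, id) {
    genes <- strsplit(genes_str %||% "", ",", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      skipped <<- c(skipped, id)
      return()
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = genes, proband_id = proband, variant_id = id,
      stringsAsFactors = FALSE)
  }
  if (!is.null(variants) && nrow(variants) > 0)
    for (i in seq_len(nrow(variants)))
      add(variants$genes[i], variants$proband_id[i], variants$key[i])
  if (!is.null(cnvs) && nrow(cnvs) > 0)
    for (i in seq_len(nrow(cnvs)))
      add(cnvs$genes_impacted[i], cnvs$proband_id[i],
          paste0("cnv:", cnvs$chrom[i], ":", cnvs$start[i], "-", cnvs$end[i]))
  if (length(rows) == 0) {
    out <- data.frame(gene = character(0), n_probands = integer(0),
                      variant_ids = character(0), pli = numeric(0),
                      pli_flag = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  long <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(long, long$gene), function(d) {
    data.frame(gene = d$gene[1],
               n_probands = length(unique(d$proband_id)),
               variant_ids = paste(sort(unique(d$variant_id)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$pli <- if (is.null(pli)) NA_real_ else unname(pli[out$gene])
  out$pli_flag <- !is.na(out$pli) & out$pli > pli_cutoff
  out <- out[order(-out$n_probands, out$gene), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Burden comparisons between groups
#'
#' `carrier_rate_test()` compares carrier proportions between two groups with
#' a 1-df chi-squared test on the 2x2 table (no continuity correction by
#' default); `geneset_fisher_test()` runs a two-sided Fisher's exact test on
#' a 2x2 gene-set-by-group count table. Both return the contingency table
#' used; degenerate tables with a zero margin return p = 1 with a warning.
#'
#' @param carriers_a,n_a Carriers and total in group A.
#' @param carriers_b,n_b Carriers and total in group B.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `table`, `statistic` (chi-squared only), `estimate`
#'   (odds ratio, Fisher only), and `p`.
#' @export
carrier_rate_test <- function(carriers_a, n_a, carriers_b, n_b,
                              correct = FALSE) {
  tab <- matrix(c(carriers_a, n_a - carriers_a,
                  carriers_b, n_b - carriers_b), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("carrier", "non_carrier")))
  if (any(tab < 0)) stop2("carriers cannot exceed group size")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero-margin table; p set to 1")
    return(list(table = tab, statistic = 0, p = 1))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value)
}

#' @rdname carrier_rate_test
#' @param tab A 2x2 integer matrix.
#' @export
geneset_fisher_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero-margin table; p set to 1")
    return(list(table = tab, estimate = NA_real_, p = 1))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, estimate = unname(ft$estimate), p = ft$p.value)
}

#' Burden statistics report
#'
#' Runs [carrier_rate_test()] on each element of `carrier_tables` (lists with
#' `carriers_a`, `n_a`, `carriers_b`, `n_b`) and [geneset_fisher_test()] on
#' each 2x2 matrix in `fisher_tables`, returning one tidy data.frame with the
#' tables serialized alongside.
#'
#' @param carrier_tables,fisher_tables Named lists (either may be empty).
#' @param correct Continuity correction for the chi-squared tests.
#' @return data.frame with `comparison`, `test`, `statistic`, `estimate`,
#'   `p`, `table` (flattened counts `a;b;c;d`).
#' @export
burden_tests <- function(carrier_tables = list(), fisher_tables = list(),
                         correct = FALSE) {
  rows <- list()
  for (nm in names(carrier_tables)) {
    ct <- carrier_tables[[nm]]
    r <- carrier_rate_test(ct$carriers_a, ct$n_a, ct$carriers_b, ct$n_b,
                           correct = correct)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = nm, test = "chi_squared", statistic = r$statistic,
      estimate = NA_real_, p = r$p,
      table = paste(as.vector(t(r$table)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (nm in names(fisher_tables)) {
    r <- geneset_fisher_test(fisher_tables[[nm]])
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = nm, test = "fisher_exact", statistic = NA_real_,
      estimate = r$estimate, p = r$p,
      table = paste(as.vector(t(r$table)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop2("no tables supplied")
  do.call(rbind, rows)
}
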