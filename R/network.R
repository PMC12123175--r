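#' Scored-network seed expansion and ontology enrichment
#'
#' Candidate gene sets are expanded over a user-supplied scored interaction
#' edge table (STRING `protein.links` dialect: two gene symbols plus a
#' combined score on 0-1000): each seed contributes its top `k` interactors
#' by descending score, and term enrichment of any gene set against a
#' background universe is computed with the hypergeometric upper tail and
#' Benjamini-Hochberg adjustment. All computation is file-driven; no web
#' service is consulted.
#'
#' @name network_enrichment
NULL

#' Read a scored interaction edge table
#'
#' TSV with columns `gene_a`, `gene_b`, `combined_score` (the STRING
#' `protein1 protein2 combined_score` header is accepted). Edges are stored
#' undirected with `gene_a < gene_b`, deduplicated (max score wins),
#' self-loops dropped, and optionally thresholded on score.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @param min_score Minimum combined score to retain (default 400, the
#'   conventional medium-confidence cutoff; set 0 to keep all).
#' @return data.frame `gene_a`, `gene_b`, `combined_score`.
#' @export
read_interaction_edges <- function(path, min_score = 400) {
  edges <- if (is.data.frame(path)) path else read_tsv_file(path)
  nm <- names(edges)
  nm[nm == "protein1"] <- "gene_a"
  nm[nm == "protein2"] <- "gene_b"
  names(edges) <- nm
  req <- c("gene_a", "gene_b", "combined_score")
  if (!all(req %in% names(edges)))
    stop2("edge table needs columns: ", paste(req, collapse = ", "))
  edges <- edges[edges$gene_a != edges$gene_b, req, drop = FALSE]
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b, -edges$combined_score), ]
  edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), ]
  edges <- edges[edges$combined_score >= min_score, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Top-k interactors of a seed gene
#'
#' Neighbors of `seed` ranked by combined score descending, ties broken
#' lexicographically by gene symbol; at most `k` returned. Genes listed in
#' `exclude` (typically the seed set itself) are not counted among the
#' interactors. A seed absent from the edge table yields an empty vector.
#'
#' @param seed Gene symbol.
#' @param edges Edge table from [read_interaction_edges()].
#' @param k Maximum interactors (default 10).
#' @param exclude Genes to exclude from the ranking.
#' @return Character vector of at most `k` gene symbols, best first.
#' @export
top_k_interactors <- function(seed, edges, k = 10, exclude = seed) {
  stopifnot(k >= 1)
  a <- edges$gene_b[edges$gene_a == seed]
  sa <- edges$combined_score[edges$gene_a == seed]
  b <- edges$gene_a[edges$gene_b == seed]
  sb <- edges$combined_score[edges$gene_b == seed]
  nb <- c(a, b); sc <- c(sa, sb)
  keep <- !(nb %in% exclude)
  nb <- nb[keep]; sc <- sc[keep]
  if (length(nb) == 0) return(character(0))
  ord <- order(-sc, nb)
  utils::head(nb[ord], k)
}

#' Expand a seed set over the interaction network
#'
#' Node set is the seeds plus the union of each seed's top-k interactors;
#' edges induced among the node set are retained and each node records its
#' origin (`seed` or `interactor`). Output is independent of seed order.
#'
#' @param seeds Character vector of seed genes.
#' @param edges Edge table from [read_interaction_edges()].
#' @param k Interactors per seed (default 10).
#' @return List with `nodes` (data.frame `gene`, `origin`) and `edges`
#'   (induced subgraph edge table).
#' @export
expand_network <- function(seeds, edges, k = 10) {
  seeds <- sort(unique(seeds))
  if (length(seeds) == 0) stop2("seed set is empty")
  inter <- unique(unlist(lapply(seeds, top_k_interactors, edges = edges,
                                k = k, exclude = seeds)))
  inter <- sort(setdiff(inter, seeds))
  nodes <- data.frame(
    gene = c(seeds, inter),
    origin = rep(c("seed", "interactor"), c(length(seeds), length(inter))),
    stringsAsFactors = FALSE)
  keep <- edges$gene_a %in% nodes$gene & edges$gene_b %in% nodes$gene
  sub <- edges[keep, , drop = FALSE]
  rownames(sub) <- NULL
  list(nodes = nodes, edges = sub)
}

#' Read a term annotation table
#'
#' TSV with columns `term_id`, `term_name`, `gene` (one gene per row);
#' returns a list of term records, optionally pooled by a grouping table
#' (`term_id`, `pooled_label`) that merges similar terms into one gene set.
#'
#' @param path TSV path or data.frame.
#' @param pooling Optional pooling TSV path or data.frame.
#' @return Named list of lists with `term_id`, `term_name`, `genes`.
#' @export
read_term_annotation <- function(path, pooling = NULL) {
  tab <- if (is.data.frame(path)) path else read_tsv_file(path)
  req <- c("term_id", "term_name", "gene")
  if (!all(req %in% names(tab)))
    stop2("annotation table needs columns: ", paste(req, collapse = ", "))
  if (!is.null(pooling)) {
    pool <- if (is.data.frame(pooling)) pooling else read_tsv_file(pooling)
    idx <- match(tab$term_id, pool$term_id)
    hit <- !is.na(idx)
    tab$term_id[hit] <- pool$pooled_label[idx[hit]]
    tab$term_name[hit] <- pool$pooled_label[idx[hit]]
  }
  lapply(split(tab, tab$term_id), function(d) {
    list(term_id = d$term_id[1], term_name = d$term_name[1],
         genes = unique(d$gene))
  })
}

#' Hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability (including the
#' observed count) of the overlap between the query set and the term's genes
#' within the background universe, Benjamini-Hochberg adjusted across terms.
#' `ease = TRUE` substitutes the EASE variant (overlap reduced by one, as in
#' DAVID). Terms with no background genes are skipped.
#'
#' @param query Character vector, a subset of `background`.
#' @param annotation List of term records ([read_term_annotation()]).
#' @param background Character vector, the gene universe.
#' @param ease Use the EASE score variant (default `FALSE`).
#' @return data.frame `term_id`, `term_name`, `overlap`, `term_size`,
#'   `query_size`, `expected`, `p`, `p_bh`, ordered by `p`.
#' @export
enrich_terms <- function(query, annotation, background, ease = FALSE) {
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop2("query genes must be contained in the background universe")
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(annotation, function(term) {
    tg <- intersect(term$genes, background)
    if (length(tg) == 0) return(NULL)
    ov <- length(intersect(tg, query))
    ov_used <- if (ease) max(0L, ov - 1L) else ov
    # P(X >= ov_used), X ~ Hypergeometric(term in bg, bg - term, drawn n_q)
    p <- phyper(ov_used - 1L, length(tg), n_bg - length(tg), n_q,
                lower.tail = FALSE)
    data.frame(term_id = term$term_id, term_name = term$term_name,
               overlap = ov, term_size = length(tg), query_size = n_q,
               expected = n_q * length(tg) / n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term_id = character(0), term_name = character(0),
                      overlap = integer(0), term_size = integer(0),
                      query_size = integer(0), expected = numeric(0),
                      p = numeric(0), p_bh = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Fraction of genes annotated to at least one pooled term
#'
#' @param genes Character vector of genes to assess.
#' @param annotation List of term records whose gene sets are pooled.
#' @return List with `fraction`, `annotated`, `total`.
#' @export
ontology_coverage <- function(genes, annotation) {
  genes <- unique(genes)
  pooled <- unique(unlist(lapply(annotation, `[[`, "genes")))
  annotated <- sum(genes %in% pooled)
  list(fraction = if (length(genes)) annotated / length(genes) else 0,
       annotated = annotated, total = length(genes))
}
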