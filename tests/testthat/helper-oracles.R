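# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: enumeration, closed forms and literal rule
# re-application only.

# two-sided Fisher p for a 2x2 table by enumerating the hypergeometric
# support and summing probabilities no larger than the observed one
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# upper-tail hypergeometric probability P(X >= ov) by direct summation
oracle_hyper_upper <- function(ov, term_size, bg_size, query_size) {
  hi <- min(term_size, query_size)
  if (ov > hi) return(0)
  sum(stats::dhyper(ov:hi, term_size, bg_size - term_size, query_size))
}

# Benjamini-Hochberg step-up closed form
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# two-sided rank-sum p by full enumeration of n1-subsets of the midranks
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  sums <- utils::combn(r, n1, sum)
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

# literal re-application of the three printed subtype rules
oracle_subtype <- function(hc_z, hc_pct, ht_pct, threshold_sd = 1.5) {
  if (!(hc_z > threshold_sd)) return("none")
  if (hc_pct > 90 && ht_pct > 90) return("SO")
  if (ht_pct / hc_pct < 0.7) return("DMac")
  "RM"
}

# minimal leftmost variant representation via whole-sequence comparison:
# apply the edit to the context, then take longest common suffix first and
# prefix second (suffix-first gives the leftmost alignment in repeats)
oracle_normalize <- function(pos, ref, alt, context) {
  S <- context
  T_ <- paste0(substr(S, 1, pos - 1), alt,
               substr(S, pos + nchar(ref), nchar(S)))
  sv <- strsplit(S, "")[[1]]; tv <- strsplit(T_, "")[[1]]
  ls <- length(sv); lt <- length(tv)
  s <- 0L
  while (s < min(ls, lt) && sv[ls - s] == tv[lt - s]) s <- s + 1L
  p <- 0L
  while (p < min(ls, lt) - s && sv[p + 1L] == tv[p + 1L]) p <- p + 1L
  ref_seg <- if (p + 1L <= ls - s) paste(sv[(p + 1L):(ls - s)], collapse = "") else ""
  alt_seg <- if (p + 1L <= lt - s) paste(tv[(p + 1L):(lt - s)], collapse = "") else ""
  if (nchar(ref_seg) == 0L || nchar(alt_seg) == 0L) {
    anchor <- sv[p]
    list(pos = p, ref = paste0(anchor, ref_seg),
         alt = paste0(anchor, alt_seg))
  } else {
    list(pos = p + 1L, ref = ref_seg, alt = alt_seg)
  }
}

# brute-force sort-and-slice neighbor ranking
oracle_topk <- function(seed, edges, k, exclude = seed) {
  nb <- character(0); sc <- integer(0)
  for (i in seq_len(nrow(edges))) {
    if (edges$gene_a[i] == seed) {
      nb <- c(nb, edges$gene_b[i]); sc <- c(sc, edges$combined_score[i])
    } else if (edges$gene_b[i] == seed) {
      nb <- c(nb, edges$gene_a[i]); sc <- c(sc, edges$combined_score[i])
    }
  }
  keep <- !(nb %in% exclude)
  nb <- nb[keep]; sc <- sc[keep]
  nb[order(-sc, nb)][seq_len(min(k, length(nb)))]
}

# small random edge table with score ties
random_edge_table <- function(n_genes, n_edges, tie_scores = FALSE) {
  genes <- sprintf("R%03d", seq_len(n_genes))
  pairs <- t(utils::combn(genes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  scores <- if (tie_scores) sample(c(400, 500, 600, 700), length(pick), TRUE)
  else sample(150:999, length(pick), TRUE)
  data.frame(gene_a = pairs[pick, 1], gene_b = pairs[pick, 2],
             combined_score = scores, stringsAsFactors = FALSE)
}

# flat two-age reference table: z-scores equal (value - mean) / sd exactly
flat_reference <- function(measure, mean, sd) {
  growth_reference(measure, data.frame(
    sex = rep(c("M", "F"), each = 2), age_months = rep(c(48, 204), 2),
    mean = mean, sd = sd))
}
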