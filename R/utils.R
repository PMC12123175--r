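#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm sd var median rnorm runif rbinom rnbinom
#'   rlnorm rbeta p.adjust fisher.test chisq.test t.test phyper dhyper
#'   setNames prcomp dist hclust cutree aggregate approx loess predict
#'   complete.cases quantile
#' @importFrom utils read.delim write.table head combn
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' pipeline inputs: tab separator, header, no factor coercion, `NA` for empty
#' fields.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a tab-separated table deterministically
#'
#' Fixed formatting (tab separator, no quotes, no row names) so reruns under
#' the same seed produce byte-identical files.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

# stop() with a consistent prefix so pipeline errors name their stage
stop2 <- function(...) stop(..., call. = FALSE)
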