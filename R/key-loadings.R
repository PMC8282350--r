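#' Published key-gene component loadings for engineered chick muscle
#'
#' The published PCA of bulk transcriptomes from engineered chick muscle
#' tissues (week 1 vs week 3 of differentiation) reported, for each of the
#' first three principal components, the explained variance percentage and
#' the genes in the highest 2% of component-loading magnitudes — sarcomere,
#' calcium-handling, mitochondrial and NMJ genes such as *MYH1G*, *TNNI1*,
#' *ACTN1*, *MB*, *AGRN* and *CHRNA1*. This function returns that table as
#' shipped with the package.
#'
#' @return data frame with columns `component`, `variance_pct`, `gene`,
#'   `loading`, `expression_change`.
#' @export
key_gene_loadings <- function() {
  path <- system.file("extdata", "pc_key_gene_loadings.tsv",
                      package = "ntmetrics", mustWork = TRUE)
  read.delim(path, check.names = FALSE,
             colClasses = c("integer", "numeric", "character", "numeric",
                            "character"))
}

#' Cumulative variance explained by the first principal components
#'
#' Sums the per-component variance percentages of a loading table (one
#' value per component; duplicated rows per gene are collapsed first).
#'
#' @param tbl a table with `component` and `variance_pct` columns, as from
#'   [key_gene_loadings()] or assembled from a [pca_with_loadings()] result.
#' @param n_components number of leading components to sum.
#' @return cumulative variance percentage.
#' @examples
#' cumulative_pc_variance(key_gene_loadings(), 3)  # ~69%
#' @export
cumulative_pc_variance <- function(tbl, n_components = 3) {
  stopifnot(all(c("component", "variance_pct") %in% names(tbl)))
  per_comp <- tapply(tbl$variance_pct, tbl$component, unique)
  if (any(lengths(per_comp) != 1))
    stop("inconsistent variance_pct within a component")
  comps <- as.integer(names(per_comp))
  sum(unlist(per_comp)[comps <= n_components])
}
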