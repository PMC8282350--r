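#' FPKM-UQ normalization
#'
#' Fragments per kilobase of transcript per million mapped reads, upper
#' quartile variant:
#' `fpkm_uq[g, s] = counts[g, s] * 1e9 / (gene_length_bp[g] * UQ_s)`,
#' where `UQ_s` is the 75th percentile (linear-interpolation quantile) of
#' sample `s`'s *nonzero* gene counts. Genes with zero counts in every
#' sample are filtered out first. Because `UQ_s` scales linearly with the
#' sample's counts, each sample's normalized column is invariant under
#' uniform scaling of that sample's counts.
#'
#' @param cm a `count_matrix` (see [make_count_matrix()] /
#'   [read_count_matrix()]).
#' @return object of class `normalized_matrix`: `fpkm_uq` (genes x samples),
#'   `uq_per_sample`, `groups`, `gene_length_bp`.
#' @export
fpkm_uq <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  keep <- rowSums(counts) > 0
  if (!all(keep)) counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("invalid input: no expressed genes")
  lengths <- cm$gene_length_bp[rownames(counts)]
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) stop("invalid input: sample with all-zero counts")
    as.numeric(quantile(nz, 0.75))
  })
  fpkm <- sweep(counts * 1e9 / lengths, 2, uq, "/")
  structure(list(fpkm_uq = fpkm, uq_per_sample = uq,
                 groups = cm$groups, gene_length_bp = lengths),
            class = "normalized_matrix")
}

#' Gene-specific differential expression at p < 0.05 and |FC| > 1.5
#'
#' Per gene, a two-sample t test (Welch by default) on `log2(fpkm_uq + 1)`
#' between the two groups, and a linear fold change
#' `(mean2 + eps) / (mean1 + eps)` computed on the linear FPKM-UQ scale
#' with a small pseudo-mean `eps` for stability at low expression. A gene is
#' flagged differentially expressed when `p < p_cutoff` and the linear fold
#' change exceeds `fc_cutoff` in either direction. No multiple-testing
#' correction is applied by default, matching the plain p = 0.05 cut-off
#' convention of the assay; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param nm a [fpkm_uq()] result.
#' @param groups factor of two levels (defaults to `nm$groups`).
#' @param p_cutoff p-value cut-off.
#' @param fc_cutoff linear fold-change cut-off (> 1).
#' @param eps pseudo-mean added to both group means for the fold change.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method); the DEG flag uses the adjusted values.
#' @return data frame of class `deg_table`: `gene`, `mean1`, `mean2`,
#'   `fold_change` (linear, group2/group1), `log2_fc`, `p_value`,
#'   `neg_log10_p`, `is_deg`.
#' @export
differential_expression <- function(nm, groups = NULL, p_cutoff = 0.05,
                                    fc_cutoff = 1.5, eps = 1e-3,
                                    var_equal = FALSE, adjust = "none") {
  stopifnot(inherits(nm, "normalized_matrix"))
  groups <- groups %||% nm$groups
  groups <- droplevels(factor(groups))
  stopifnot(nlevels(groups) == 2)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("at least two samples per group are required")

  x <- log2(nm$fpkm_uq + 1)
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, g2, drop = FALSE], 1, var)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    dfree <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    dfree <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * pt(-abs(tstat), dfree)
  ## degenerate genes: zero variance in both groups
  degen <- se == 0 | !is.finite(p)
  p[degen] <- ifelse(abs(m2 - m1)[degen] < .Machine$double.eps, 1, 0)
  p_adj <- stats::p.adjust(p, method = adjust)

  lin1 <- rowMeans(nm$fpkm_uq[, g1, drop = FALSE])
  lin2 <- rowMeans(nm$fpkm_uq[, g2, drop = FALSE])
  fc <- (lin2 + eps) / (lin1 + eps)

  out <- data.frame(gene = rownames(nm$fpkm_uq),
                    mean1 = lin1, mean2 = lin2,
                    fold_change = fc, log2_fc = log2(fc),
                    p_value = p_adj,
                    neg_log10_p = -log10(pmax(p_adj, 1e-300)),
                    is_deg = p_adj < p_cutoff &
                      (fc > fc_cutoff | fc < 1 / fc_cutoff),
                    row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' PCA of samples over genes, with per-gene component loadings
#'
#' PCA of the samples on gene-centered `log2(fpkm_uq + 1)` values. Variance
#' percentages cover all components (they sum to 100); per-gene loadings
#' are the Pearson correlations between each gene's expression vector and
#' each component's sample scores, so they are bounded by 1 in magnitude.
#' Genes with constant expression get `NA` loadings.
#'
#' @param nm a [fpkm_uq()] result.
#' @param n_components number of components to report (truncated with a
#'   warning when exceeding `n_samples - 1`).
#' @return object of class `pca_result`: `variance_pct` (all components,
#'   non-increasing), `scores` (samples x k), `loadings` (genes x k).
#' @export
pca_with_loadings <- function(nm, n_components = 3) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- log2(nm$fpkm_uq + 1)
  n_samp <- ncol(x)
  if (n_samp < 2) stop("at least two samples are required")
  k_max <- n_samp - 1
  if (n_components > k_max) {
    warning(sprintf("n_components truncated to %d (samples - 1)", k_max))
    n_components <- k_max
  }
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  sds <- apply(x, 1, sd)
  loadings <- suppressWarnings(cor(t(x), scores))
  loadings[sds == 0, ] <- NA_real_
  colnames(loadings) <- colnames(scores)
  structure(list(variance_pct = var_pct, scores = scores,
                 loadings = loadings),
            class = "pca_result")
}

#' Top genes by component-loading magnitude
#'
#' Report filter mirroring a "highest 2% of component loading magnitudes"
#' selection for a given principal component.
#'
#' @param pca a [pca_with_loadings()] result.
#' @param component component index.
#' @param top_frac fraction of genes to keep.
#' @return data frame `gene`, `loading`, sorted by |loading| descending.
#' @export
top_loading_genes <- function(pca, component = 1, top_frac = 0.02) {
  stopifnot(inherits(pca, "pca_result"),
            component >= 1, component <= ncol(pca$loadings))
  l <- pca$loadings[, component]
  l <- l[!is.na(l)]
  n_keep <- max(1L, ceiling(top_frac * length(l)))
  ord <- order(abs(l), decreasing = TRUE)[seq_len(n_keep)]
  data.frame(gene = names(l)[ord], loading = unname(l[ord]))
}

#' Hierarchical heatmap ordering of genes and samples
#'
#' Agglomerative clustering with average linkage on a correlation distance
#' (`1 - Pearson r`) over gene-standardized `log2(fpkm_uq + 1)` values.
#' Constant genes are dropped with a warning. The returned leaf orders are
#' deterministic for a fixed input.
#'
#' @param nm a [fpkm_uq()] result.
#' @return list with `gene_order`, `sample_order` (integer leaf orders into
#'   the retained genes / samples), `genes` (retained gene names),
#'   `gene_hclust`, `sample_hclust`.
#' @export
cluster_heatmap_order <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- log2(nm$fpkm_uq + 1)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("at least two genes and two samples are required")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s)", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (x - rowMeans(x)) / sds
  gene_d <- as.dist(1 - cor(t(z)))
  samp_d <- as.dist(1 - cor(z))
  gh <- hclust(gene_d, method = "average")
  sh <- hclust(samp_d, method = "average")
  list(gene_order = gh$order, sample_order = sh$order,
       genes = rownames(z), gene_hclust = gh, sample_hclust = sh)
}
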