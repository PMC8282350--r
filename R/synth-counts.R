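#' Specification for a synthetic two-group RNA-seq count matrix
#'
#' Negative-binomial counts for two groups (e.g. week-1 vs week-3 tissues)
#' with a stated fraction of differentially expressed genes. True log2 fold
#' changes of DE genes are drawn from `N(0, lfc_sd)` excluding the window
#' `|LFC| < log2(1.5)`, so every programmed DE gene exceeds the pipeline's
#' fold-change cut-off in truth.
#'
#' @param n_genes number of genes.
#' @param n_per_group integer pair: samples per group.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param base_mean_log_range pair: log2 range of baseline mean counts.
#' @param frac_de fraction of DE genes in `[0, 1]`.
#' @param lfc_sd SD of true log2 fold changes.
#' @param gene_length_bp_range integer pair: gene length range in bp.
#' @return object of class `count_matrix_spec`.
#' @export
count_matrix_spec <- function(n_genes = 2000, n_per_group = c(4, 4),
                              dispersion = 0.1,
                              base_mean_log_range = c(1, 10),
                              frac_de = 0.1, lfc_sd = 1.5,
                              gene_length_bp_range = c(500L, 5000L)) {
  stopifnot(n_genes >= 1, length(n_per_group) == 2, all(n_per_group >= 1),
            dispersion > 0, frac_de >= 0, frac_de <= 1, lfc_sd > 0,
            length(base_mean_log_range) == 2, length(gene_length_bp_range) == 2)
  structure(as.list(environment()), class = "count_matrix_spec")
}

#' Generate a synthetic count matrix with DE ground truth
#'
#' Baseline means are log2-uniform over `base_mean_log_range`; group 2 means
#' of DE genes are scaled by `2^LFC`. Counts are negative binomial with the
#' stated dispersion. The truth sidecar records per-gene DE labels and true
#' LFCs.
#'
#' @param spec a [count_matrix_spec()].
#' @param seed integer RNG seed.
#' @return list with `cm` (class `count_matrix`: `counts` genes x samples,
#'   `gene_length_bp`, `groups` factor) and `truth`.
#' @export
make_count_matrix <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "count_matrix_spec"))
  with_rng_seed(seed, {
    n <- spec$n_genes
    mu <- 2^runif(n, spec$base_mean_log_range[1], spec$base_mean_log_range[2])
    n_de <- round(spec$frac_de * n)
    de_idx <- sort(sample.int(n, n_de))
    lfc <- numeric(n)
    if (n_de > 0) {
      draw <- rnorm(n_de, 0, spec$lfc_sd)
      while (any(bad <- abs(draw) < log2(1.5)))
        draw[bad] <- rnorm(sum(bad), 0, spec$lfc_sd)
      lfc[de_idx] <- draw
    }
    n1 <- spec$n_per_group[1]; n2 <- spec$n_per_group[2]
    size <- 1 / spec$dispersion
    counts <- matrix(0L, n, n1 + n2)
    for (j in seq_len(n1))
      counts[, j] <- rnbinom(n, mu = mu, size = size)
    for (j in seq_len(n2))
      counts[, n1 + j] <- rnbinom(n, mu = mu * 2^lfc, size = size)
    rownames(counts) <- sprintf("gene_%05d", seq_len(n))
    colnames(counts) <- c(sprintf("week1_%d", seq_len(n1)),
                          sprintf("week3_%d", seq_len(n2)))
    groups <- factor(rep(c("week1", "week3"), c(n1, n2)),
                     levels = c("week1", "week3"))
    lengths <- sample(seq(spec$gene_length_bp_range[1],
                          spec$gene_length_bp_range[2]), n, replace = TRUE)
    names(lengths) <- rownames(counts)
    cm <- structure(list(counts = counts, gene_length_bp = lengths,
                         groups = groups),
                    class = "count_matrix")
    truth <- synthetic_truth(
      "count_matrix",
      params = list(n_genes = n, n_per_group = spec$n_per_group,
                    dispersion = spec$dispersion, frac_de = spec$frac_de,
                    lfc_sd = spec$lfc_sd,
                    is_de = seq_len(n) %in% de_idx,
                    true_lfc = lfc,
                    base_mean = mu),
      seed = seed)
    list(cm = cm, truth = truth)
  })
}

#' Write / read a count matrix as TSV
#'
#' Genes in rows; a header row of sample IDs plus a `gene_length_bp` column.
#' Group labels are inferred from the sample-ID prefix before the last
#' underscore when reading.
#'
#' @param cm a `count_matrix`.
#' @param path path of the `.tsv` file.
#' @return `write_count_matrix` returns `path` invisibly; `read_count_matrix`
#'   a `count_matrix`.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(gene = rownames(cm$counts),
                   gene_length_bp = cm$gene_length_bp,
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot(all(c("gene", "gene_length_bp") %in% names(df)))
  samples <- setdiff(names(df), c("gene", "gene_length_bp"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$gene
  lengths <- setNames(df$gene_length_bp, df$gene)
  groups <- factor(sub("_[^_]*$", "", samples))
  structure(list(counts = counts, gene_length_bp = lengths, groups = groups),
            class = "count_matrix")
}
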