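test_that("fpkm_uq matches the hand-computed toy example exactly", {
  ## one sample, counts (10, 100, 0), lengths (1000, 2000, 500) bp:
  ## nonzero UQ = 10 + 0.75 * (100 - 10) = 77.5
  ## gene1 = 10 * 1e9 / (1000 * 77.5)  = 129032.2581
  ## gene2 = 100 * 1e9 / (2000 * 77.5) = 645161.2903
  cm <- structure(list(
    counts = matrix(c(10, 100, 0), ncol = 1,
                    dimnames = list(c("g1", "g2", "g3"), "s1")),
    gene_length_bp = c(g1 = 1000, g2 = 2000, g3 = 500),
    groups = factor("a")), class = "count_matrix")
  nm <- fpkm_uq(cm)
  expect_equal(nm$uq_per_sample[["s1"]], 77.5)
  expect_equal(nm$fpkm_uq["g1", 1], 10 * 1e9 / (1000 * 77.5))
  expect_equal(nm$fpkm_uq["g2", 1], 100 * 1e9 / (2000 * 77.5))
  ## the gene expressed nowhere is filtered out
  expect_false("g3" %in% rownames(nm$fpkm_uq))

  ## a zero count in one sample (but not all) normalizes to 0
  cm2 <- structure(list(
    counts = matrix(c(10, 0, 100, 5), 2,
                    dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    gene_length_bp = c(g1 = 1000, g2 = 500),
    groups = factor(c("a", "b"))), class = "count_matrix")
  nm2 <- fpkm_uq(cm2)
  expect_equal(nm2$fpkm_uq["g2", "s1"], 0)

  ## all-zero sample is refused
  cm3 <- cm2
  cm3$counts[, 1] <- 0
  expect_error(fpkm_uq(cm3), "all-zero")
})

test_that("fpkm_uq columns are exactly invariant to per-sample count scaling", {
  g <- make_count_matrix(count_matrix_spec(n_genes = 300), seed = 5)
  nm <- fpkm_uq(g$cm)
  cm10 <- g$cm
  cm10$counts[, 3] <- cm10$counts[, 3] * 10L
  nm10 <- fpkm_uq(cm10)
  ## exact up to floating-point rounding of the rescaled upper quartile
  expect_equal(nm10$fpkm_uq[, 3], nm$fpkm_uq[, 3], tolerance = 1e-12)
  expect_identical(nm10$fpkm_uq[, -3], nm$fpkm_uq[, -3])
})

test_that("differential expression: identical groups, type I error, power", {
  ## identical groups: FC = 1, nothing flagged
  g <- make_count_matrix(count_matrix_spec(n_genes = 100, frac_de = 0),
                         seed = 6)
  cm <- g$cm
  cm$counts <- cbind(cm$counts[, 1:4], cm$counts[, 1:4])
  colnames(cm$counts) <- c(paste0("week1_", 1:4), paste0("week3_", 1:4))
  nm <- fpkm_uq(cm)
  deg <- differential_expression(nm)
  expect_true(all(abs(deg$fold_change - 1) < 1e-12))
  expect_false(any(deg$is_deg))

  ## null simulation: type-I error within [0.03, 0.08] over replicates
  t1 <- mean(vapply(7:11, function(sd) {
    gn <- make_count_matrix(count_matrix_spec(n_genes = 2000,
                                              n_per_group = c(3, 3),
                                              frac_de = 0), seed = sd)
    mean(differential_expression(fpkm_uq(gn$cm))$p_value < 0.05)
  }, numeric(1)))
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.08)

  ## spiked genes with |LFC| >= 2 at high mean: >= 80% flagged
  gs <- make_count_matrix(count_matrix_spec(
    n_genes = 1000, n_per_group = c(4, 4), frac_de = 0.2, lfc_sd = 2,
    base_mean_log_range = c(5, 10)), seed = 8)
  ds <- differential_expression(fpkm_uq(gs$cm))
  big <- gs$truth$params$is_de & abs(gs$truth$params$true_lfc) >= 2
  expect_gte(mean(ds$is_deg[big]), 0.8)

  ## DEG recall increases with true effect size
  de <- gs$truth$params$is_de
  alfc <- abs(gs$truth$params$true_lfc)
  rec_small <- mean(ds$is_deg[de & alfc < 1.5])
  rec_large <- mean(ds$is_deg[de & alfc >= 2.5])
  expect_gte(rec_large, rec_small)
})

test_that("PCA: bounded loadings, complete variance, group separation", {
  g <- make_count_matrix(count_matrix_spec(
    n_genes = 500, n_per_group = c(4, 4), frac_de = 0.4, lfc_sd = 2),
    seed = 9)
  nm <- fpkm_uq(g$cm)
  pca <- pca_with_loadings(nm, n_components = 3)
  expect_true(all(abs(pca$loadings) <= 1 + 1e-9, na.rm = TRUE))
  expect_true(all(diff(pca$variance_pct) <= 1e-9))
  expect_lt(abs(sum(pca$variance_pct) - 100), 0.1)

  ## strong group effect: PC1 separates groups
  sc1 <- pca$scores[, 1]
  grp <- nm$groups
  expect_true(max(sc1[grp == "week1"]) < min(sc1[grp == "week3"]) ||
                min(sc1[grp == "week1"]) > max(sc1[grp == "week3"]))

  ## duplicated samples, two groups, strong effect: PC1 variance > 90%
  cm2 <- g$cm
  cm2$counts <- cm2$counts[, c(1, 1, 5, 5)]
  colnames(cm2$counts) <- c("week1_1", "week1_2", "week3_1", "week3_2")
  cm2$groups <- factor(rep(c("week1", "week3"), each = 2))
  pca2 <- suppressWarnings(pca_with_loadings(fpkm_uq(cm2), n_components = 2))
  expect_gt(pca2$variance_pct[1], 90)

  expect_warning(pca_with_loadings(nm, n_components = 10), "truncated")

  tl <- top_loading_genes(pca, 1, top_frac = 0.02)
  expect_equal(nrow(tl), ceiling(0.02 * sum(!is.na(pca$loadings[, 1]))))
  expect_true(all(diff(abs(tl$loading)) <= 1e-12))
})

test_that("heatmap ordering is deterministic and group-structured", {
  g <- make_count_matrix(count_matrix_spec(
    n_genes = 200, n_per_group = c(4, 4), frac_de = 0.5, lfc_sd = 2.5),
    seed = 10)
  nm <- fpkm_uq(g$cm)
  o1 <- cluster_heatmap_order(nm)
  o2 <- cluster_heatmap_order(nm)
  expect_identical(o1$gene_order, o2$gene_order)
  expect_identical(o1$sample_order, o2$sample_order)

  ## the top split of the sample dendrogram separates the groups
  top2 <- stats::cutree(o1$sample_hclust, k = 2)
  expect_equal(length(unique(top2[1:4])), 1)
  expect_equal(length(unique(top2[5:8])), 1)
  expect_false(top2[1] == top2[5])

  ## identical samples end up adjacent
  cm <- g$cm
  cm$counts <- cbind(cm$counts, dup = cm$counts[, 1])
  cm$groups <- factor(c(as.character(cm$groups), "week1"))
  od <- cluster_heatmap_order(fpkm_uq(cm))
  pos <- match(c(1, 9), od$sample_order)
  expect_equal(abs(diff(pos)), 1)

  ## constant genes dropped with a warning
  nmc <- fpkm_uq(g$cm)
  nmc$fpkm_uq[1, ] <- 7
  expect_warning(cluster_heatmap_order(nmc), "constant gene")
})

test_that("published key-gene table reproduces the ~69% top-3 variance", {
  tbl <- key_gene_loadings()
  expect_equal(nrow(tbl), 15)
  expect_true(all(abs(tbl$loading) <= 1))
  cum3 <- cumulative_pc_variance(tbl, 3)
  expect_equal(cum3, 35.55 + 24.51 + 9.04)
  expect_equal(round(cum3), 69)
})
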