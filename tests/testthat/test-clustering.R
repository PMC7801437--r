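# PCA on the mtDNA subspace, SNN/Louvain clustering, HE/LE labelling,
# retention and marker detection.

blob_embedding <- function(n = 100, sep = 10, seed = 1) {
  set.seed(seed)
  emb <- rbind(cbind(rnorm(n), rnorm(n)),
               cbind(rnorm(n) + sep, rnorm(n)))
  rownames(emb) <- sprintf("c%03d", seq_len(2 * n))
  list(embedding = emb, truth = rep(c("A", "B"), each = n))
}

test_that("PCA matches a brute-force eigendecomposition on a toy", {
  set.seed(4)
  x <- matrix(rnorm(25), 5, 5)          # 5 genes x 5 cells
  m <- toy_count_matrix(matrix(rpois(25, 10), 5))
  e <- normalize_and_scale(m)
  e$scaled <- x
  rownames(e$scaled) <- rownames(m$counts)
  colnames(e$scaled) <- colnames(m$counts)
  emb <- pca_mtdna(e, rownames(m$counts))
  # oracle: eigendecomposition of the cell covariance
  xc <- scale(t(x), center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc))
  scores <- xc %*% ev$vectors[, 1:2]
  for (j in 1:2)
    expect_lt(min(max(abs(emb[, j] - scores[, j])),
                  max(abs(emb[, j] + scores[, j]))), 1e-8)
  expect_true(all(diff(attr(emb, "sdev")) <= 1e-12))
})

test_that("perfectly correlated genes put all variance on PC1", {
  set.seed(2)
  base <- rpois(30, 20) + 1L
  bg <- rpois(30, 50)                  # varies the cell totals
  cnt <- rbind(g1 = base, g2 = base, bg = bg)
  storage.mode(cnt) <- "integer"
  m <- toy_count_matrix(cnt, genes = rownames(cnt))
  e <- normalize_and_scale(m)
  emb <- pca_mtdna(e, c("g1", "g2"))
  expect_gt(attr(emb, "var_explained")[1], 1 - 1e-10)
})

test_that("well-separated blobs are recovered exactly (ARI = 1)", {
  b <- blob_embedding(n = 100, sep = 10)
  sc <- scan_resolutions(b$embedding, seq(0.1, 1, 0.1), seed = 3)
  expect_true(sc$two_cluster_found)
  a <- sc$selected
  expect_equal(mclust::adjustedRandIndex(a$cluster, b$truth), 1.0)
  # determinism at a fixed resolution
  a1 <- density_cluster(b$embedding, resolution = 0.4, seed = 3)
  a2 <- density_cluster(b$embedding, resolution = 0.4, seed = 3)
  expect_identical(a1$cluster, a2$cluster)
})

test_that("a single blob stays one cluster at low resolution", {
  set.seed(8)
  emb <- cbind(rnorm(120), rnorm(120))
  rownames(emb) <- sprintf("c%03d", 1:120)
  a <- density_cluster(emb, resolution = 0.1, seed = 2)
  expect_equal(length(unique(a$cluster)), 1)
  sc <- scan_resolutions(emb, c(0.1, 0.2), seed = 2)
  expect_equal(sc$table$n_clusters[1], 1)
})

test_that("resolution scan finds the two-cluster solution on planted data", {
  b <- blob_embedding(n = 80, sep = 8, seed = 5)
  sc <- scan_resolutions(b$embedding, seq(0.1, 1, 0.1), seed = 4)
  expect_true(sc$two_cluster_found)
  expect_equal(length(unique(sc$selected$cluster)), 2)
  sc1 <- scan_resolutions(b$embedding, 0.5, seed = 4)
  expect_equal(nrow(sc1$table), 1)
})

test_that("HE/LE labels follow mean mtDNA expression, not cluster ids", {
  sim <- simulate_counts(sim_expression_config(
    n_cells_he = 150, n_cells_le = 150, mt_logfc = 2, dropout_rate = 0.05,
    seed = 19))
  e <- normalize_and_scale(sim$matrix)
  mt <- mtdna_gene_set("FluidigmC1")
  emb <- pca_mtdna(e, mt)
  sc <- scan_resolutions(emb, seq(0.1, 1, 0.1), seed = 6)
  expect_true(sc$two_cluster_found)
  a <- label_he_le(sc$selected, e, mt)
  truth <- sim$truth$cell_labels[names(a$he_le)]
  expect_gte(mean(a$he_le == truth), 0.95)
  # swapping cluster ids leaves the HE/LE labels unchanged
  b <- sc$selected
  b$cluster <- setNames(3L - b$cluster, names(b$cluster))
  b <- label_he_le(b, e, mt)
  expect_identical(b$he_le, a$he_le)
})

test_that("planted subgroups are recovered with high ARI", {
  sim <- simulate_counts(sim_expression_config(
    n_cells_he = 200, n_cells_le = 200, mt_logfc = 2,
    nb_dispersion = 0.3, dropout_rate = 0.05, seed = 29))
  e <- normalize_and_scale(sim$matrix)
  mt <- mtdna_gene_set("FluidigmC1")
  emb <- pca_mtdna(e, mt)
  sc <- scan_resolutions(emb, seq(0.1, 1, 0.1), seed = 7)
  expect_true(sc$two_cluster_found)
  a <- label_he_le(sc$selected, e, mt)
  truth <- sim$truth$cell_labels[names(a$he_le)]
  expect_gte(mclust::adjustedRandIndex(a$he_le, truth), 0.9)
})

test_that("retention arithmetic and permutation behaviour are correct", {
  cells <- sprintf("c%03d", 1:100)
  mk <- function(lab) {
    a <- structure(list(cluster = setNames(as.integer(factor(lab)), cells),
                        he_le = setNames(lab, cells),
                        scope = "x"), class = "cluster_assignment")
    a
  }
  lab <- rep(c("HE", "LE"), each = 50)
  expect_equal(cluster_retention(list(mk(lab)), mk(lab))$fraction_retained,
               1.0)
  flipped <- lab
  flipped[1:10] <- "LE"
  expect_equal(cluster_retention(list(mk(lab)),
                                 mk(flipped))$fraction_retained, 0.90)
  # independent random labelings agree about half the time
  set.seed(12)
  fr <- replicate(200, {
    cluster_retention(list(mk(sample(lab))),
                      mk(sample(lab)))$fraction_retained
  })
  expect_lt(abs(mean(fr) - 0.5), 0.02)
  # symmetric in its two labelings
  a <- mk(lab); b <- mk(flipped)
  expect_equal(cluster_retention(list(a), b)$fraction_retained,
               cluster_retention(list(b), a)$fraction_retained)
})

test_that("marker detection honors the expressed-fraction filter", {
  set.seed(33)
  n <- 40                                # per group
  # gene expressed in 22.5% of cells of each group -> excluded at 0.25
  g_low <- integer(80)
  g_low[c(1:9, 41:49)] <- 5L
  g_hi <- as.integer(rpois(80, 10) + rep(c(20, 0), each = n))
  cnt <- rbind(low = g_low, hi = g_hi, base = as.integer(rpois(80, 8)))
  m <- toy_count_matrix(cnt, genes = c("low", "hi", "base"),
                        cells = sprintf("c%02d", 1:80))
  labels <- setNames(rep(c("HE", "LE"), each = n), colnames(m$counts))
  e <- normalize_and_scale(m)
  tab <- find_markers(e, labels, min_expressed_fraction = 0.25,
                      test = "bimod")
  expect_false("low" %in% tab$gene)
  expect_true("hi" %in% tab$gene)
  expect_lt(tab$p_adjusted[tab$gene == "hi"], 0.05)
})

test_that("planted markers are found and null groups yield none", {
  sim <- simulate_counts(sim_expression_config(
    n_cells_he = 100, n_cells_le = 100, mt_logfc = 2, oxphos_logfc = 2,
    dropout_rate = 0.1, seed = 43))
  lab <- sim$truth$cell_labels[colnames(sim$matrix$counts)]
  e <- normalize_and_scale(sim$matrix)
  tab <- find_markers(e, lab, test = "bimod")
  mt <- names(sim$truth$gene_class)[sim$truth$gene_class == "mt"]
  expect_gte(mean(tab$p_adjusted[tab$gene %in% mt] < 0.05), 0.95)
  # random labels: no marker should survive FDR
  set.seed(3)
  tab0 <- find_markers(e, setNames(sample(lab), names(lab)),
                       test = "bimod")
  expect_lte(sum(tab0$p_adjusted < 0.05), 2)
})

test_that("random-gene control is seeded and calibrated near alpha", {
  sim <- simulate_counts(sim_expression_config(
    n_cells_he = 60, n_cells_le = 60, mt_logfc = 0, oxphos_logfc = 0,
    marker_logfc = 0, dropout_rate = 0.1, seed = 51))
  lab <- setNames(sample(rep(c("HE", "LE"), 60)),
                  colnames(sim$matrix$counts))
  e <- normalize_and_scale(sim$matrix)
  rg <- random_gene_control(e, lab, n_genes = 50, n_resamples = 40,
                            seed = 5, test = "bimod")
  rg2 <- random_gene_control(e, lab, n_genes = 50, n_resamples = 40,
                             seed = 5, test = "bimod")
  expect_identical(rg$significant_counts, rg2$significant_counts)
  expect_equal(length(rg$significant_counts), 40)
  frac <- mean(rg$significant_counts) / rg$n_genes
  expect_gt(frac, 0.005); expect_lt(frac, 0.12)
  rg1 <- random_gene_control(e, lab, n_genes = 50, n_resamples = 1,
                             seed = 5)
  expect_equal(length(rg1$significant_counts), 1)
})
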