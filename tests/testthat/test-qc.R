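# Cell-level QC rules, the dataset-level mtDNA rules, and the
# normalize/scale transform.

toy_qc_matrix <- function() {
  # genes: 2 mt, 2 ribosomal, INS, GCG, 4 background
  genes <- c("MT-ND1", "MT-CO1", "RPS1", "RPL2", "INS", "GCG",
             sprintf("B%d", 1:4))
  cnt <- matrix(5L, nrow = length(genes), ncol = 4,
                dimnames = list(genes, sprintf("c%d", 1:4)))
  count_matrix(cnt, data.frame(cell = colnames(cnt), individual = "D1",
                               cell_type = "beta", platform = "FluidigmC1"))
}

test_that("per-cell rules flag exactly the offending metric", {
  m <- toy_qc_matrix()
  cfg <- qc_config(min_genes_per_cell = 5, doublet_min_count = 100,
                   mtdna_fraction_rule = "none")
  r <- compute_cell_qc(m, cfg)
  expect_true(all(r$pass))

  # 2999 detected genes under a 3000 cutoff fails min_genes
  sim <- simulate_counts(sim_expression_config(n_cells_he = 3,
                                               n_cells_le = 3, seed = 1))
  big <- sim$matrix
  r2 <- compute_cell_qc(big, qc_config(min_genes_per_cell = 3000))
  expect_true(all(r2$fail_min_genes))   # toy matrices have < 3000 genes
  expect_true(all(!r2$pass))
  expect_true(all(grepl("min_genes", r2$failed_rules)))
})

test_that("ribosomal fraction above 20% fails and at 20% passes", {
  m <- toy_qc_matrix()
  cnt <- m$counts
  # cell c1: ribosomal 21% of total
  tot <- sum(cnt[, "c1"])
  cnt["RPS1", "c1"] <- cnt["RPS1", "c1"] + 6L   # 16/56 = 28.6%
  m2 <- count_matrix(cnt, m$cell_meta)
  r <- compute_cell_qc(m2, qc_config(min_genes_per_cell = 1,
                                     doublet_min_count = 100))
  expect_true(r$fail_ribosomal[r$cell == "c1"])
  expect_false(any(r$fail_ribosomal[r$cell != "c1"]))
  expect_false(r$pass[r$cell == "c1"])
})

test_that("zero-mtDNA cells fail and the doublet rule needs both markers", {
  m <- toy_qc_matrix()
  cnt <- m$counts
  cnt[c("MT-ND1", "MT-CO1"), "c2"] <- 0L
  cnt["INS", "c3"] <- 50L; cnt["GCG", "c3"] <- 50L
  cnt["INS", "c4"] <- 50L; cnt["GCG", "c4"] <- 0L
  m2 <- count_matrix(cnt, m$cell_meta)
  r <- compute_cell_qc(m2, qc_config(min_genes_per_cell = 1,
                                     doublet_min_count = 5))
  expect_true(r$fail_zero_mtdna[r$cell == "c2"])
  expect_true(r$fail_doublet[r$cell == "c3"])
  expect_false(r$fail_doublet[r$cell == "c4"])
})

test_that("dataset-level mtDNA rules use the documented arithmetic", {
  # fixed_10pct: fractions {0.05, 0.08, 0.12} -> only the third fails
  genes <- c("MT-ND1", "B1")
  cnt <- rbind(c(5L, 8L, 12L), c(95L, 92L, 88L))
  dimnames(cnt) <- list(genes, c("c1", "c2", "c3"))
  m <- count_matrix(cnt, data.frame(cell = colnames(cnt),
                                    individual = "D1", cell_type = "beta",
                                    platform = "FluidigmC1"))
  r <- compute_cell_qc(m, qc_config(min_genes_per_cell = 1,
                                    mtdna_fraction_rule = "fixed_10pct"))
  r <- apply_mtdna_fraction_rule(r, "fixed_10pct")
  expect_identical(r$cell[r$fail_mtdna_fraction], "c3")

  # twofold_median: counts {100,100,100,250}, median 100 -> 250 fails
  genes4 <- c("MT-ND1", sprintf("B%d", 1:3))
  cnt2 <- rbind(c(100L, 100L, 100L, 250L),
                matrix(900L, nrow = 3, ncol = 4))
  dimnames(cnt2) <- list(genes4, sprintf("c%d", 1:4))
  m2 <- count_matrix(cnt2, data.frame(cell = colnames(cnt2),
                                      individual = "D1",
                                      cell_type = "beta", platform = "p"))
  r2 <- compute_cell_qc(m2, qc_config(min_genes_per_cell = 1))
  r2 <- apply_mtdna_fraction_rule(r2, "twofold_median")
  expect_identical(r2$cell[r2$fail_mtdna_fraction], "c4")

  # median_plus_2sd with all equal counts: SD 0, strict > -> none fail
  cnt3 <- rbind(rep(100L, 4), matrix(900L, nrow = 3, ncol = 4))
  dimnames(cnt3) <- list(genes4, sprintf("c%d", 1:4))
  m3 <- count_matrix(cnt3, data.frame(cell = colnames(cnt3),
                                      individual = "D1",
                                      cell_type = "beta", platform = "p"))
  r3 <- compute_cell_qc(m3, qc_config(min_genes_per_cell = 1))
  r3 <- apply_mtdna_fraction_rule(r3, "median_plus_2sd")
  expect_false(any(r3$fail_mtdna_fraction))
})

test_that("filter_cells removes exactly the failing cells, order kept", {
  fx <- qc_truth_table_fixture()
  r <- compute_cell_qc(fx$matrix, qc_config(min_genes_per_cell = 50,
                                            doublet_min_count = 5))
  r <- apply_mtdna_fraction_rule(r, "fixed_10pct")
  kept <- filter_cells(fx$matrix, r)
  expect_setequal(setdiff(colnames(fx$matrix$counts),
                          colnames(kept$counts)),
                  unname(fx$planted))
  expect_identical(colnames(kept$counts),
                   setdiff(colnames(fx$matrix$counts), fx$planted))
})

test_that("raising min_genes_per_cell never enlarges the passing set", {
  sim <- simulate_counts(sim_expression_config(n_cells_he = 40,
                                               n_cells_le = 40,
                                               seed = 3))
  pass_at <- function(k) {
    r <- compute_cell_qc(sim$matrix, qc_config(min_genes_per_cell = k,
                                               mtdna_fraction_rule = "none"))
    r$cell[r$pass]
  }
  cuts <- c(10, 50, 100, 150, 200)
  sets <- lapply(cuts, pass_at)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("normalization is depth-invariant and scaling centres genes", {
  cnt <- matrix(c(2L, 4L, 6L, 1L, 2L, 3L, 5L, 1L, 7L), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  m <- toy_count_matrix(cnt, genes = rownames(cnt), cells = colnames(cnt))
  e <- normalize_and_scale(m)
  # cells x and y are proportional -> identical normalized profiles
  expect_equal(e$normalized[, "x"], e$normalized[, "y"])
  expect_true(all(abs(rowMeans(e$scaled)) < 1e-12))
  # zero count stays zero before scaling
  cnt["a", "x"] <- 0L
  e2 <- normalize_and_scale(toy_count_matrix(cnt, rownames(cnt),
                                             colnames(cnt)))
  expect_equal(e2$normalized["a", "x"], 0)
})

test_that("regressing totals leaves genes uncorrelated with depth", {
  sim <- simulate_counts(sim_expression_config(n_cells_he = 50,
                                               n_cells_le = 50, seed = 9))
  e <- normalize_and_scale(sim$matrix, regress_total = TRUE)
  tot <- e$total_counts
  cors <- apply(e$scaled[1:50, ], 1, function(g)
    if (sd(g) == 0) 0 else cor(g, tot))
  expect_true(all(abs(cors) < 1e-8))
})
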