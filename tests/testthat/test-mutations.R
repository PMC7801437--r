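# Variant filters, cell eligibility, the repertoire permutation and
# the sharing-based classifications.

test_that("base frequencies divide strand-summed counts by depth", {
  p <- data.frame(cell = "c", pos = 1L, ref = "G", depth = 400L,
                  fwd_A = 150L, fwd_C = 0L, fwd_G = 50L, fwd_T = 0L,
                  rev_A = 150L, rev_C = 0L, rev_G = 50L, rev_T = 0L,
                  end_A = 0L, end_C = 0L, end_G = 0L, end_T = 0L,
                  skipped = 0L)
  f <- base_frequencies(p)
  expect_equal(unname(f[c("A", "G")]), c(0.75, 0.25))
  expect_equal(sum(f), 1)
  p$depth <- 0L
  expect_error(base_frequencies(p), "depth")
})

test_that("the boundary fixture yields exactly the hand-enumerated calls", {
  fx <- variant_boundary_fixture()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cellA.pileup")
  writeLines(fx$lines, path)
  p <- read_pileup(path)
  calls <- call_variants(list(cellA = p),
                         variant_qc_config(coding_region = c(101, 1500)))
  got <- calls[order(calls$pos, calls$alt_base), c("pos", "alt_base")]
  rownames(got) <- rownames(fx$expected) <- NULL
  expect_identical(got, fx$expected)
  # per-strand support and strict frequency recorded on a known call
  c101 <- calls[calls$pos == 101, ]
  expect_equal(c101$fwd_support, 3L)
  expect_equal(c101$rev_support, 2L)
  expect_equal(c101$frequency, 5 / 400)
})

test_that("filters are monotone: tightening never adds calls", {
  pv <- data.frame(position = c(200, 400, 600),
                   alt_base = c("A", "C", "T"),
                   frequency = c(0.02, 0.05, 0.10),
                   group = c("HE", "HE", "LE"), strand_balance = 0.5)
  sim <- simulate_pileups(sim_pileup_config(
    mt_length = 800, coding_region = c(1, 800),
    n_cells = c(HE = 3, LE = 3), coverage_mean = 700, coverage_sd = 80,
    planted_variants = pv, seed = 3))
  key <- function(calls) paste(calls$cell, calls$pos, calls$alt_base)
  base <- call_variants(sim$pileups,
                        variant_qc_config(coding_region = c(1, 800)))
  for (cfg in list(variant_qc_config(min_coverage = 650,
                                     coding_region = c(1, 800)),
                   variant_qc_config(min_frequency = 0.03,
                                     coding_region = c(1, 800)),
                   variant_qc_config(min_reads_per_strand = 5,
                                     coding_region = c(1, 800)))) {
    expect_true(all(key(call_variants(sim$pileups, cfg)) %in% key(base)))
  }
})

test_that("planted variants are recovered with no false positives", {
  pv <- data.frame(position = c(150, 350, 550, 750),
                   alt_base = c("A", "C", "G", "T"),
                   frequency = c(0.03, 0.05, 0.08, 0.04),
                   group = rep(c("HE", "LE"), 2), strand_balance = 0.5)
  sim <- simulate_pileups(sim_pileup_config(
    mt_length = 900, coding_region = c(1, 900),
    n_cells = c(HE = 5, LE = 5), coverage_mean = 600, coverage_sd = 0,
    planted_variants = pv, seed = 7))
  calls <- call_variants(sim$pileups,
                         variant_qc_config(coding_region = c(1, 900)))
  groups <- sub("_cell.*", "", calls$cell)
  # no calls anywhere but planted positions
  expect_true(all(calls$pos %in% pv$position))
  # recall over planted (cell, position) pairs
  expected <- merge(data.frame(cell = names(sim$truth$cell_groups),
                               grp = sim$truth$cell_groups), pv,
                    by.x = "grp", by.y = "group")
  hit <- paste(calls$cell, calls$pos) %in%
    paste(expected$cell, expected$position)
  recall <- sum(hit) / nrow(expected)
  expect_gte(recall, 0.95)
  # planted alleles match
  expect_true(all(calls$alt_base ==
                    pv$alt_base[match(calls$pos, pv$position)]))
})

test_that("cell eligibility applies the covered-position threshold", {
  mk <- function(cell, npos, depth = 400L) {
    df <- data.frame(cell = cell, pos = seq_len(npos), ref = "G",
                     depth = depth, fwd_G = depth %/% 2L,
                     rev_G = depth - depth %/% 2L)
    for (cl in setdiff(pileup_count_cols(),
                       c("fwd_G", "rev_G"))) df[[cl]] <- 0L
    df
  }
  ps <- list(ok = mk("ok", 1000), short = mk("short", 999),
             empty = mk("empty", 1)[0, ])
  expect_identical(eligible_cells(ps, variant_qc_config()), "ok")
})

test_that("repertoire equals the closed form when pools are exhausted", {
  hq <- list(c1 = 1:1000, c2 = 1001:2000)
  calls <- data.frame(cell = c("c1", "c1", "c1", "c2"),
                      pos = c(5L, 10L, 15L, 1007L))
  rr <- repertoire_permutation(calls, hq, c(c1 = "HE", c2 = "HE"),
                               n_iter = 25, sample_size = 1000, seed = 2)
  expect_true(all(rr$subgroups$HE$percent == 0.2))
  expect_equal(rr$subgroups$HE$sd, 0)
  # zero variants -> 0% every iteration
  rr0 <- repertoire_permutation(calls[0, ], hq, c(c1 = "HE", c2 = "HE"),
                                n_iter = 10, sample_size = 1000, seed = 2)
  expect_true(all(rr0$subgroups$HE$percent == 0))
  expect_error(repertoire_permutation(calls, list(c1 = 1:50), c(c1 = "HE"),
                                      sample_size = 1000),
               "smaller than sample_size")
})

test_that("subsampled repertoire matches the hypergeometric expectation", {
  hq <- list(c1 = 1:2000)
  vp <- seq(1, 2000, by = 40)        # 50 variants uniform in the pool
  calls <- data.frame(cell = "c1", pos = vp)
  n_iter <- 400
  rr <- repertoire_permutation(calls, hq, c(c1 = "HE"), n_iter = n_iter,
                               sample_size = 1000, seed = 9)
  # E[hits] = 50 * 1000/2000 = 25 -> 2.5%; SE from the hypergeometric
  sd1 <- sqrt(1000 * (50 / 2000) * (1 - 50 / 2000) *
                (2000 - 1000) / (2000 - 1))
  mc_se <- (sd1 / 1000 * 100) / sqrt(n_iter)
  expect_lt(abs(rr$subgroups$HE$mean - 2.5), 3 * mc_se)
})

test_that("inherited classification keys on position and allele sharing", {
  beta <- data.frame(cell = c("b1", "b1", "b2", "b2"),
                     pos = c(5000L, 6000L, 5000L, 7000L),
                     alt_base = c("A", "C", "A", "T"),
                     frequency = 0.05,
                     subgroup = c("HE", "HE", "LE", "LE"))
  alpha <- data.frame(cell = "a1", pos = 5000L, alt_base = "A")
  res <- classify_inherited(beta, alpha)
  expect_identical(res$calls$inherited_flag,
                   c("candidate_inherited", "other",
                     "candidate_inherited", "other"))
  expect_equal(res$percent_table$percent_inherited, c(50, 50))
  # no alpha cells: flags unset with a warning
  expect_warning(res0 <- classify_inherited(beta, alpha[0, ]),
                 "alpha")
  expect_true(all(res0$calls$inherited_flag == "unset"))
})

test_that("unique/overlapping counts partition the mutation union", {
  he <- data.frame(pos = c(1L, 2L, 3L), alt_base = "A")
  le <- data.frame(pos = c(3L, 4L), alt_base = c("A", "C"))
  u <- unique_vs_overlapping(he, le)
  expect_equal(unname(u), c(2, 1, 1))
  u2 <- unique_vs_overlapping(le, he)
  expect_equal(unname(u2[c(2, 1, 3)]), unname(u[c(1, 2, 3)]))
  same <- data.frame(pos = 1:4, alt_base = "G")
  expect_equal(unname(unique_vs_overlapping(same, same)), c(0, 0, 4))
  expect_equal(sum(u), length(union(paste(he$pos, he$alt_base),
                                    paste(le$pos, le$alt_base))))
})

test_that("subgroup summaries recompute like a spreadsheet", {
  calls <- data.frame(cell = c("c1", "c1", "c2", "c3", "c3", "c3",
                               "c4", "c4", "c5", "c6"),
                      pos = 1:10, alt_base = "A",
                      frequency = c(0.02, 0.04, 0.05, 0.01, 0.03, 0.02,
                                    0.06, 0.02, 0.08, 0.011),
                      subgroup = rep(c("HE", "LE"), each = 5))
  s <- summarize_subgroup_mutations(calls)
  he <- calls[calls$subgroup == "HE", ]
  expect_equal(s$mean_frequency[s$subgroup == "HE"], mean(he$frequency))
  expect_equal(s$sd_frequency[s$subgroup == "HE"], sd(he$frequency))
  expect_equal(s$mean_per_cell[s$subgroup == "HE"],
               mean(table(he$cell)))
  one <- data.frame(cell = "c", pos = 1L, alt_base = "A",
                    frequency = 0.05, subgroup = "HE")
  s1 <- summarize_subgroup_mutations(one)
  expect_equal(s1$mean_frequency, 0.05)
  expect_equal(s1$sd_frequency, 0)
})
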