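# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Small count matrix with explicit integer counts.
toy_count_matrix <- function(counts, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  count_matrix(counts, data.frame(cell = cells, individual = "D1",
                                  cell_type = "beta",
                                  platform = "FluidigmC1",
                                  stringsAsFactors = FALSE))
}

# One mpileup text line. `fwd`/`rev` are named counts of explicit base
# chars; ref reads are written as "."/",". `end_str` is appended raw
# (e.g. "A$A$") and its reads must be included in depth.
mpileup_line <- function(pos, ref, n_ref_fwd, n_ref_rev, alt = "",
                         extra = "", chrom = "MT") {
  bases <- paste0(strrep(".", n_ref_fwd), strrep(",", n_ref_rev), alt,
                  extra)
  depth <- n_ref_fwd + n_ref_rev +
    nchar(gsub("[^ACGTNacgtn*<>]", "", gsub("\\^.", "", strip_indels_for_test(alt)))) +
    nchar(gsub("[^ACGTNacgtn*<>]", "", extra))
  sprintf("%s\t%d\t%s\t%d\t%s\t%s", chrom, pos, ref, depth, bases,
          strrep("I", depth))
}

strip_indels_for_test <- function(s) {
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) break
    n <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    s <- paste0(substr(s, 1L, m - 1L),
                substring(s, m + attr(m, "match.length") + n))
  }
  s
}

# The variant-filter boundary fixture: mpileup text spanning every
# filter edge, plus the hand-enumerated expected call set under
# variant_qc_config(coding_region = c(101, 1500)).
variant_boundary_fixture <- function() {
  alt5 <- function(b) paste0(strrep(b, 3), strrep(tolower(b), 2))
  lines <- c(
    # pos 101: depth 400, alt A 3 fwd + 2 rev, 1.25% -> CALLED
    mpileup_line(101, "G", 198, 197, alt5("A")),
    # pos 102: depth 399, same support -> below min coverage
    mpileup_line(102, "G", 197, 197, alt5("A")),
    # pos 103: depth 400, alt A 2+2 = exactly 1.0% -> strict > fails
    mpileup_line(103, "G", 198, 198, "AAaa"),
    # pos 104: alt A 5 fwd + 0 rev (1.25%) -> strand filter fails
    mpileup_line(104, "G", 198, 197, "AAAAA"),
    # pos 105: alt A 1 fwd + 4 rev -> strand filter fails
    mpileup_line(105, "G", 198, 197, "Aaaaa"),
    # pos 106: alt A 3+2 all flagged read-end -> read-end-only fails
    mpileup_line(106, "G", 198, 197, "", "A$A$A$a$a$"),
    # pos 107: alt A 3+2, only 2 of 5 at read end -> CALLED
    mpileup_line(107, "G", 198, 197, "Aaa", "A$A$"),
    # pos 108: depth 500, alt C 3+3 = 1.2% -> CALLED
    mpileup_line(108, "G", 247, 247, "CCCccc"),
    # pos 109: depth 1000, alt T 5+5 = exactly 1.0% -> fails
    mpileup_line(109, "G", 495, 495, "TTTTTttttt"),
    # pos 110: two alts, A 3+2 (1.25%) and C 4+4 (2%) -> BOTH CALLED
    mpileup_line(110, "G", 194, 193, paste0(alt5("A"), "CCCCcccc")),
    # pos 50: outside the coding region -> ignored
    mpileup_line(50, "G", 198, 197, alt5("A")),
    # pos 111: pure reference -> no call
    mpileup_line(111, "G", 200, 200),
    # pos 112: depth 2000, alt T 11+10 = 1.05% -> CALLED
    mpileup_line(112, "G", 990, 989,
                 paste0(strrep("T", 11), strrep("t", 10))),
    # pos 113: alt A 2 fwd + 3 rev, 1.25% (per-strand min inclusive) -> CALLED
    mpileup_line(113, "G", 198, 197, "AAaaa"),
    # pos 114: caret/indel noise around alt A 3+2 -> CALLED
    mpileup_line(114, "G", 198, 197, "^IA+2ATAAaa-1c"))
  expected <- data.frame(
    pos = c(101L, 107L, 108L, 110L, 110L, 112L, 113L, 114L),
    alt_base = c("A", "A", "C", "A", "C", "T", "A", "A"),
    stringsAsFactors = FALSE)
  list(lines = lines, expected = expected[order(expected$pos,
                                                expected$alt_base), ])
}

# Synthetic matrix with planted QC violations on named cells; returns
# the matrix and the planted cell ids. Built on a null (mt_logfc = 0)
# simulated matrix so that non-planted cells pass all rules, including
# fixed_10pct.
qc_truth_table_fixture <- function(seed = 7) {
  sim <- simulate_counts(sim_expression_config(
    n_cells_he = 30, n_cells_le = 30, mt_logfc = 0, oxphos_logfc = 0,
    marker_logfc = 0, dropout_rate = 0.1, seed = seed))
  cnt <- sim$matrix$counts
  mt <- grep("^MT-", rownames(cnt), value = TRUE)
  ribo <- grep("^RPS", rownames(cnt), value = TRUE)
  planted <- c(low_genes = "cell0001", high_ribo = "cell0002",
               zero_mt = "cell0003", doublet = "cell0004",
               high_mt = "cell0005")
  # neutralize chance rule hits in the unplanted background
  cnt["GCG", ] <- 0L
  cnt["INS", ] <- pmax(cnt["INS", ], 10L)
  cnt[mt[1], ] <- pmax(cnt[mt[1], ], 1L)
  over <- colSums(cnt[mt, ]) / colSums(cnt) > 0.08
  cnt[mt, over] <- cnt[mt, over] %/% 3L
  cnt[mt[1], ] <- pmax(cnt[mt[1], ], 1L)
  keepers <- c(mt[1], "INS")          # keep mtDNA > 0, avoid doublet rule
  zero <- setdiff(rownames(cnt), keepers)
  cnt[zero, planted["low_genes"]] <- 0L
  cnt[ribo, planted["high_ribo"]] <-
    cnt[ribo, planted["high_ribo"]] + 400L   # ~28% ribosomal
  cnt[mt, planted["zero_mt"]] <- 0L
  cnt["INS", planted["doublet"]] <- 50L
  cnt["GCG", planted["doublet"]] <- 50L
  bump <- as.integer(ceiling(sum(cnt[, planted["high_mt"]]) * 0.13))
  cnt[mt[1], planted["high_mt"]] <- cnt[mt[1], planted["high_mt"]] + bump
  m <- count_matrix(cnt, sim$matrix$cell_meta)
  list(matrix = m, planted = planted)
}
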