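# Cell-level quality control: per-cell rules (detected genes, ribosomal
# fraction, non-zero mtDNA, marker doublets) plus a dataset-level mtDNA
# over-representation rule computed on the cells passing the per-cell
# rules.

#' Quality-control configuration
#'
#' Defaults follow the filters the pipeline applies to full-length
#' platforms: at least 3000 detected genes per cell (Fluidigm C1 /
#' CEL-Seq2; shallower droplet platforms such as inDrops need a lower
#' cutoff, 500 by default), at most 20% ribosomal reads, no cell with
#' zero mtDNA counts, and removal of marker doublets (cells expressing
#' both INS and GCG above a raw-count threshold). mtDNA
#' over-representation is handled by one of three dataset-level rules:
#' `fixed_10pct` (mtDNA fraction > 10% fails), `twofold_median` (mtDNA
#' read count > 2x the dataset median fails) or `median_plus_2sd`
#' (mtDNA read count > median + 2 SD fails).
#'
#' @param min_genes_per_cell minimum detected (count > 0) genes.
#' @param max_ribosomal_fraction maximum ribosomal read fraction.
#' @param require_nonzero_mtdna fail cells with zero mtDNA counts.
#' @param doublet_markers two gene ids whose co-expression marks a
#'   doublet.
#' @param doublet_min_count raw-count threshold each marker must exceed
#'   (inclusive) to flag a doublet.
#' @param mtdna_fraction_rule one of `"fixed_10pct"`,
#'   `"twofold_median"`, `"median_plus_2sd"`, or `"none"`.
#' @param mtdna_gene_set,ribosomal_gene_set gene-id vectors; defaults
#'   resolve `MT-`/`mt-` and `RPS/RPL` prefixes against the matrix.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes_per_cell = 3000,
                      max_ribosomal_fraction = 0.20,
                      require_nonzero_mtdna = TRUE,
                      doublet_markers = c("INS", "GCG"),
                      doublet_min_count = 5,
                      mtdna_fraction_rule = c("median_plus_2sd",
                                              "fixed_10pct",
                                              "twofold_median", "none"),
                      mtdna_gene_set = NULL,
                      ribosomal_gene_set = NULL) {
  mtdna_fraction_rule <- match.arg(mtdna_fraction_rule)
  stopifnot(min_genes_per_cell >= 0, max_ribosomal_fraction >= 0,
            max_ribosomal_fraction <= 1, doublet_min_count >= 0,
            length(doublet_markers) == 2)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_ribosomal_fraction = max_ribosomal_fraction,
                 require_nonzero_mtdna = require_nonzero_mtdna,
                 doublet_markers = doublet_markers,
                 doublet_min_count = doublet_min_count,
                 mtdna_fraction_rule = mtdna_fraction_rule,
                 mtdna_gene_set = mtdna_gene_set,
                 ribosomal_gene_set = ribosomal_gene_set),
            class = "qc_config")
}

resolve_gene_set <- function(set, genes, pattern, what) {
  if (is.null(set)) set <- grep(pattern, genes, value = TRUE)
  else {
    missing <- setdiff(set, genes)
    if (length(missing) == length(set))
      stop_ctx("none of the ", what, " genes are present in the matrix")
    set <- intersect(set, genes)
  }
  set
}

#' Compute per-cell QC metrics and per-cell rule outcomes
#'
#' @param m a [count_matrix()].
#' @param cfg a [qc_config()].
#' @return A `qc_report`: data.frame with one row per cell
#'   (genes_detected, ribosomal_fraction, mtdna_fraction, mtdna_counts,
#'   doublet_flag, per-rule logicals, `pass`, `failed_rules`) plus a
#'   `removed_per_rule` attribute.
#' @export
compute_cell_qc <- function(m, cfg = qc_config()) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) == 0 || nrow(m$counts) == 0)
    stop_ctx("empty count matrix")
  genes <- rownames(m$counts)
  mt <- resolve_gene_set(cfg$mtdna_gene_set, genes, "^(MT-|mt-)", "mtDNA")
  ribo <- resolve_gene_set(cfg$ribosomal_gene_set, genes, "^(RPS|RPL|Rps|Rpl)",
                           "ribosomal")
  totals <- colSums(m$counts)
  genes_detected <- colSums(m$counts > 0)
  mt_counts <- if (length(mt))
    colSums(m$counts[mt, , drop = FALSE]) else rep(0, ncol(m$counts))
  ribo_counts <- if (length(ribo))
    colSums(m$counts[ribo, , drop = FALSE]) else rep(0, ncol(m$counts))
  mtdna_fraction <- ifelse(totals > 0, mt_counts / totals, 0)
  ribosomal_fraction <- ifelse(totals > 0, ribo_counts / totals, 0)
  dm <- intersect(cfg$doublet_markers, genes)
  doublet_flag <- if (length(dm) == 2)
    m$counts[dm[1], ] >= cfg$doublet_min_count &
      m$counts[dm[2], ] >= cfg$doublet_min_count
  else rep(FALSE, ncol(m$counts))

  rep_df <- data.frame(
    cell = colnames(m$counts),
    genes_detected = as.integer(genes_detected),
    total_counts = as.numeric(totals),
    mtdna_counts = as.numeric(mt_counts),
    ribosomal_fraction = ribosomal_fraction,
    mtdna_fraction = mtdna_fraction,
    doublet_flag = doublet_flag,
    fail_min_genes = genes_detected < cfg$min_genes_per_cell,
    fail_ribosomal = ribosomal_fraction > cfg$max_ribosomal_fraction,
    fail_zero_mtdna = cfg$require_nonzero_mtdna & mt_counts == 0,
    fail_doublet = doublet_flag,
    fail_mtdna_fraction = FALSE,
    stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  finalize_qc_report(rep_df)
}

qc_rule_cols <- function() c("fail_min_genes", "fail_ribosomal",
                             "fail_zero_mtdna", "fail_doublet",
                             "fail_mtdna_fraction")

finalize_qc_report <- function(rep_df) {
  rules <- qc_rule_cols()
  fails <- as.matrix(rep_df[, rules])
  rep_df$pass <- rowSums(fails) == 0
  rep_df$failed_rules <- apply(fails, 1, function(r)
    paste(sub("^fail_", "", rules[r]), collapse = ";"))
  attr(rep_df, "removed_per_rule") <- colSums(fails)
  class(rep_df) <- c("qc_report", "data.frame")
  rep_df
}

#' Apply a dataset-level mtDNA over-representation rule
#'
#' The rule is evaluated on the cells that pass all per-cell rules (the
#' population defining the median/SD), and its failures are added to the
#' report. `fixed_10pct`: mtDNA fraction > 0.10 fails. `twofold_median`:
#' mtDNA read count > 2x the median mtDNA count fails.
#' `median_plus_2sd`: mtDNA read count > median + 2 SD fails (strict
#' inequalities throughout).
#'
#' @param report a `qc_report` from [compute_cell_qc()].
#' @param rule the rule name (see [qc_config()]); defaults to the rule
#'   recorded in `cfg`.
#' @param m the [count_matrix()] the report came from (unused by the
#'   current rules; kept for signature stability).
#' @return The updated `qc_report`.
#' @export
apply_mtdna_fraction_rule <- function(report,
                                      rule = c("median_plus_2sd",
                                               "fixed_10pct",
                                               "twofold_median", "none"),
                                      m = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(report, "qc_report"))
  if (rule == "none") return(report)
  base_pass <- rowSums(as.matrix(report[, setdiff(qc_rule_cols(),
                                                  "fail_mtdna_fraction")])) == 0
  if (rule == "fixed_10pct") {
    fail <- report$mtdna_fraction > 0.10
  } else {
    if (sum(base_pass) < 3)
      stop_ctx("fewer than 3 cells pass per-cell QC: dataset-level ",
               "median/SD rule undefined")
    cnt <- report$mtdna_counts
    ref <- cnt[base_pass]
    cut <- if (rule == "twofold_median") 2 * median(ref)
    else median(ref) + 2 * sd(ref)
    fail <- cnt > cut
  }
  report$fail_mtdna_fraction <- fail & base_pass
  finalize_qc_report(as.data.frame(report))
}

#' Keep only cells passing QC
#'
#' @param m a [count_matrix()].
#' @param report its `qc_report`.
#' @return A [count_matrix()] of passing cells, column order preserved.
#' @export
filter_cells <- function(m, report) {
  stopifnot(inherits(m, "count_matrix"), inherits(report, "qc_report"))
  if (!setequal(report$cell, colnames(m$counts)))
    stop_ctx("report does not match the matrix cells")
  keep <- report$cell[report$pass]
  if (!length(keep)) stop_ctx("zero cells pass QC")
  subset_cells(m, keep)
}

#' Depth-normalize, log-transform and per-gene scale a count matrix
#'
#' Counts are divided by the cell total, multiplied by `scale_factor`
#' (10,000) and log1p-transformed; each gene is then centred and scaled
#' to unit variance (constant genes scale to 0). With
#' `regress_total = TRUE` each gene's scaled values are replaced by the
#' residuals of a linear fit on total counts per cell, removing the
#' cell-complexity trend before clustering.
#'
#' @param m a [count_matrix()].
#' @param regress_total regress per-cell total counts out of the scaled
#'   values.
#' @param scale_factor depth-normalization scale factor.
#' @return An `expression_matrix`: list with `normalized` and `scaled`
#'   gene x cell matrices and `total_counts`.
#' @export
normalize_and_scale <- function(m, regress_total = FALSE,
                                scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- colSums(m$counts)
  if (any(totals == 0)) stop_ctx("zero-total cell present; run QC first")
  norm <- log1p(t(t(m$counts) / totals) * scale_factor)
  sc <- t(scale(t(norm)))
  sc[is.na(sc)] <- 0       # constant genes
  if (regress_total) {
    tc <- totals - mean(totals)
    denom <- sum(tc^2)
    if (denom > 0) {
      beta <- (sc %*% tc) / denom
      sc <- sc - beta %*% t(tc)
    }
  }
  structure(list(normalized = norm, scaled = sc, total_counts = totals),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (normalized + scaled)\n",
              nrow(x$normalized), ncol(x$normalized)))
  invisible(x)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d cells, %d pass\n", nrow(x), sum(x$pass)))
  rm <- attr(x, "removed_per_rule")
  for (r in names(rm)) cat(sprintf("  %-22s %d\n", sub("^fail_", "", r),
                                   rm[[r]]))
  invisible(x)
}
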