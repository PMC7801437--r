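# Heterogenic mitochondrial RNA variant calling from per-cell pileups,
# under coverage / strand / read-end / frequency filters, plus the
# permutation mutational-repertoire statistic and sharing-based
# classification of mutations.

#' Variant quality-control configuration
#'
#' A non-reference base is called only when the position lies in the
#' coding region, position depth >= `min_coverage` (400), the base has
#' at least `min_reads_per_strand` (2) supporting reads on each strand,
#' its support is not exclusively from read ends, and its frequency
#' (supporting reads / depth) strictly exceeds `min_frequency` (1%).
#' Cells enter mutation analyses only with at least
#' `min_covered_positions_per_cell` (1000) coding positions at
#' `min_coverage`.
#'
#' @param min_coverage minimum position depth (inclusive).
#' @param min_reads_per_strand minimum supporting reads per strand
#'   (inclusive).
#' @param exclude_read_end drop bases whose supporting reads all
#'   terminate at the position.
#' @param min_frequency frequency threshold (strict >).
#' @param min_covered_positions_per_cell cell-eligibility threshold
#'   (inclusive).
#' @param coding_region `c(start, end)`, 1-based inclusive.
#' @return A `variant_qc_config` list.
#' @export
variant_qc_config <- function(min_coverage = 400,
                              min_reads_per_strand = 2,
                              exclude_read_end = TRUE,
                              min_frequency = 0.01,
                              min_covered_positions_per_cell = 1000,
                              coding_region = c(1L, .Machine$integer.max)) {
  stopifnot(min_coverage > 0, min_reads_per_strand > 0,
            min_frequency > 0, min_covered_positions_per_cell > 0,
            length(coding_region) == 2,
            coding_region[1] <= coding_region[2])
  structure(list(min_coverage = min_coverage,
                 min_reads_per_strand = min_reads_per_strand,
                 exclude_read_end = exclude_read_end,
                 min_frequency = min_frequency,
                 min_covered_positions_per_cell =
                   min_covered_positions_per_cell,
                 coding_region = as.integer(coding_region)),
            class = "variant_qc_config")
}

#' Per-base frequencies at one pileup position
#'
#' `frequency(b) = count(b) / depth` over both strands; frequencies sum
#' to at most 1 (reads skipped as indels/N do not contribute a base).
#'
#' @param p a single pileup row (data.frame of one row).
#' @return Named numeric vector over A, C, G, T.
#' @export
base_frequencies <- function(p) {
  stopifnot(nrow(p) == 1)
  if (p$depth <= 0) stop_ctx("depth is 0: frequencies undefined")
  counts <- vapply(PILEUP_BASES, function(b)
    p[[paste0("fwd_", b)]] + p[[paste0("rev_", b)]], numeric(1))
  counts / p$depth
}

#' Call heterogenic variants from per-cell pileups
#'
#' Applies the filters of [variant_qc_config()] to every non-reference
#' base at every coding-region position of every cell; each qualifying
#' alt base is a separate call. Cells are not eligibility-filtered here
#' (see [eligible_cells()]).
#'
#' @param pileups named list of pileup data.frames (one per cell), or a
#'   single pileup data.frame.
#' @param cfg a [variant_qc_config()].
#' @return A calls data.frame: cell, pos, ref_base, alt_base, frequency,
#'   fwd_support, rev_support, depth.
#' @export
call_variants <- function(pileups, cfg = variant_qc_config()) {
  stopifnot(inherits(cfg, "variant_qc_config"))
  if (is.data.frame(pileups)) pileups <- split(pileups, pileups$cell)
  out <- lapply(pileups, function(p) {
    need <- c("pos", "ref", "depth", pileup_count_cols())
    if (!all(need %in% names(p))) stop_ctx("malformed pileup data.frame")
    p <- p[p$pos >= cfg$coding_region[1] & p$pos <= cfg$coding_region[2] &
             p$depth >= cfg$min_coverage, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    rows <- lapply(PILEUP_BASES, function(b) {
      alt <- p$ref != b
      fwd <- p[[paste0("fwd_", b)]]
      rev <- p[[paste0("rev_", b)]]
      nend <- p[[paste0("end_", b)]]
      tot <- fwd + rev
      ok <- alt & fwd >= cfg$min_reads_per_strand &
        rev >= cfg$min_reads_per_strand &
        tot / p$depth > cfg$min_frequency
      if (cfg$exclude_read_end) ok <- ok & nend < tot
      if (!any(ok)) return(NULL)
      data.frame(cell = p$cell[ok], pos = p$pos[ok], ref_base = p$ref[ok],
                 alt_base = b, frequency = (tot / p$depth)[ok],
                 fwd_support = fwd[ok], rev_support = rev[ok],
                 depth = p$depth[ok], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      frequency = numeric(0), fwd_support = integer(0),
                      rev_support = integer(0), depth = integer(0))
  rownames(out) <- NULL
  out[order(out$cell, out$pos, out$alt_base), , drop = FALSE]
}

#' Positions covered well enough per cell
#' @param pileups named list of pileup data.frames.
#' @param cfg a [variant_qc_config()].
#' @return Named list of integer vectors: coding-region positions with
#'   depth >= `min_coverage`, per cell.
#' @export
high_quality_positions <- function(pileups, cfg = variant_qc_config()) {
  lapply(pileups, function(p) {
    sort(p$pos[p$pos >= cfg$coding_region[1] &
                 p$pos <= cfg$coding_region[2] &
                 p$depth >= cfg$min_coverage])
  })
}

#' Cells eligible for mutation analyses
#'
#' A cell qualifies with at least `min_covered_positions_per_cell`
#' coding-region positions at depth >= `min_coverage`.
#'
#' @param pileups named list of pileup data.frames.
#' @param cfg a [variant_qc_config()].
#' @return Character vector of eligible cell ids.
#' @export
eligible_cells <- function(pileups, cfg = variant_qc_config()) {
  hq <- high_quality_positions(pileups, cfg)
  names(hq)[lengths(hq) >= cfg$min_covered_positions_per_cell]
}

#' Permutation mutational-repertoire statistic per subgroup
#'
#' Per iteration, `sample_size` positions are drawn without replacement
#' from each cell's high-quality position pool; the iteration's
#' subgroup percentage is the number of sampled positions that carry a
#' called variant, summed over the subgroup's cells, divided by
#' `sample_size x n_cells`, times 100. With `sample_size` equal to the
#' pool size the statistic is exact every iteration.
#'
#' @param calls calls data.frame from [call_variants()].
#' @param hq_positions named list from [high_quality_positions()],
#'   restricted to eligible cells.
#' @param subgroups named character vector: cell -> subgroup label.
#' @param n_iter iterations (default 1000).
#' @param sample_size positions sampled per cell per iteration
#'   (default 1000).
#' @param seed integer seed.
#' @return A `repertoire_result`: list per subgroup with `n_cells`,
#'   `percent` (per-iteration vector), `mean`, `sd`.
#' @export
repertoire_permutation <- function(calls, hq_positions, subgroups,
                                   n_iter = 1000, sample_size = 1000,
                                   seed = 1L) {
  cells <- names(hq_positions)
  stopifnot(all(cells %in% names(subgroups)))
  short <- cells[lengths(hq_positions) < sample_size]
  if (length(short))
    stop_ctx("high-quality pool smaller than sample_size (",
             sample_size, ") for cell(s): ",
             paste(head(short, 5), collapse = ", "))
  var_pos <- lapply(cells, function(cl)
    unique(calls$pos[calls$cell == cl]))
  names(var_pos) <- cells
  grp_of <- subgroups[cells]
  res <- with_seed(seed, {
    per_iter <- matrix(0, nrow = n_iter, ncol = length(cells),
                       dimnames = list(NULL, cells))
    for (cl in cells) {
      pool <- hq_positions[[cl]]
      vp <- var_pos[[cl]]
      if (!length(vp)) next
      hit <- pool %in% vp
      for (it in seq_len(n_iter))
        per_iter[it, cl] <- sum(hit[sample.int(length(pool), sample_size)])
    }
    per_iter
  })
  out <- lapply(split(cells, grp_of), function(cl) {
    pct <- rowSums(res[, cl, drop = FALSE]) /
      (sample_size * length(cl)) * 100
    list(n_cells = length(cl), percent = pct, mean = mean(pct),
         sd = sd(pct))
  })
  structure(list(subgroups = out, n_iter = n_iter,
                 sample_size = sample_size, seed = seed),
            class = "repertoire_result")
}

#' @export
print.repertoire_result <- function(x, ...) {
  cat(sprintf("mutational repertoire (%d iterations, %d positions/cell):\n",
              x$n_iter, x$sample_size))
  for (g in names(x$subgroups))
    cat(sprintf("  %-4s %d cells: %.4f%% +/- %.4f%%\n", g,
                x$subgroups[[g]]$n_cells, x$subgroups[[g]]$mean,
                x$subgroups[[g]]$sd))
  invisible(x)
}

#' Classify beta-cell mutations as candidate inherited
#'
#' A beta-cell mutation (position + alt base) also present in at least
#' one alpha cell of the same individual is a candidate inherited
#' mutation (presumed to predate lineage differentiation); the rest are
#' `other`. The percent inherited is reported per subgroup.
#'
#' @param beta_calls calls data.frame with a `subgroup` column.
#' @param alpha_calls calls data.frame for the alpha cells of the same
#'   individual.
#' @return List with `calls` (beta calls + `inherited_flag`) and
#'   `percent_table` (subgroup, n_mutations, n_inherited,
#'   percent_inherited).
#' @export
classify_inherited <- function(beta_calls, alpha_calls) {
  calls <- beta_calls
  if (is.null(alpha_calls) || nrow(alpha_calls) == 0) {
    warning("no alpha cells: inherited flags left unset", call. = FALSE)
    calls$inherited_flag <- "unset"
    return(list(calls = calls, percent_table = NULL))
  }
  key <- function(d) paste(d$pos, d$alt_base)
  calls$inherited_flag <- ifelse(key(calls) %in% key(alpha_calls),
                                 "candidate_inherited", "other")
  sg <- calls$subgroup %||% rep("all", nrow(calls))
  if (is.null(calls$subgroup)) calls$subgroup <- sg
  muts <- unique(calls[, c("subgroup", "pos", "alt_base",
                           "inherited_flag")])
  tab <- do.call(rbind, lapply(split(muts, muts$subgroup), function(d) {
    data.frame(subgroup = d$subgroup[1], n_mutations = nrow(d),
               n_inherited = sum(d$inherited_flag == "candidate_inherited"),
               stringsAsFactors = FALSE)
  }))
  tab$percent_inherited <- 100 * tab$n_inherited / tab$n_mutations
  rownames(tab) <- NULL
  list(calls = calls, percent_table = tab)
}

#' Unique and overlapping mutations between the HE and LE subgroups
#'
#' Mutations are keyed by (position, alt base); counts sum to the size
#' of the union of the two key sets.
#'
#' @param he_calls,le_calls calls data.frames.
#' @return Named integer vector `c(unique_HE, unique_LE, overlapping)`.
#' @export
unique_vs_overlapping <- function(he_calls, le_calls) {
  key <- function(d) unique(paste(d$pos, d$alt_base))
  he <- key(he_calls); le <- key(le_calls)
  ov <- intersect(he, le)
  c(unique_HE = length(setdiff(he, ov)),
    unique_LE = length(setdiff(le, ov)),
    overlapping = length(ov))
}

#' Descriptive summary of calls per subgroup
#'
#' Mean and SD of per-mutation frequency and of the per-cell mutation
#' count, per subgroup.
#'
#' @param calls calls data.frame with a `subgroup` column.
#' @return data.frame (subgroup, n_calls, mean_frequency, sd_frequency,
#'   mean_per_cell, sd_per_cell); empty subgroup levels yield a zero row
#'   flagged `empty = TRUE`.
#' @export
summarize_subgroup_mutations <- function(calls) {
  sgs <- levels(factor(calls$subgroup))
  if (!length(sgs)) stop_ctx("calls need a subgroup column")
  do.call(rbind, lapply(sgs, function(g) {
    d <- calls[calls$subgroup == g, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(subgroup = g, n_calls = 0L, mean_frequency = 0,
                        sd_frequency = 0, mean_per_cell = 0,
                        sd_per_cell = 0, empty = TRUE))
    per_cell <- table(d$cell)
    data.frame(subgroup = g, n_calls = nrow(d),
               mean_frequency = mean(d$frequency),
               sd_frequency = if (nrow(d) > 1) sd(d$frequency) else 0,
               mean_per_cell = mean(per_cell),
               sd_per_cell = if (length(per_cell) > 1) sd(per_cell) else 0,
               empty = FALSE, stringsAsFactors = FALSE)
  }))
}
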