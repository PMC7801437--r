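# One-config orchestration: qc -> clustering -> markers -> mutations ->
# conservation, with a single seed fanned out per stage and a JSON run
# summary. Each stage is also runnable standalone through the exported
# module functions.

#' Pipeline run configuration
#'
#' Inputs may be file paths (read through the io module) or in-memory
#' objects. Pileups and conservation track are optional; the dependent
#' stages are skipped with a notice when they are absent.
#'
#' @param counts path to a count matrix TSV (or `.mtx`) or a
#'   [count_matrix()].
#' @param counts_format `"tsv"` or `"mtx-triplet"` when `counts` is a
#'   path.
#' @param pileups directory of per-cell mpileup files, or a named list
#'   of pileup data.frames.
#' @param pileup_groups optional named vector cell -> subgroup for
#'   pileup cells absent from the expression matrix (e.g. a separate
#'   sequencing run); pileup cells present in the matrix take their
#'   clustering label.
#' @param alpha_pileups optional pileups of alpha cells (same forms)
#'   for inherited-mutation classification.
#' @param track conservation track path (bedGraph) or a
#'   [conservation_track()].
#' @param qc a [qc_config()].
#' @param variant_qc a [variant_qc_config()].
#' @param mt_genes mtDNA gene set used for PCA/labelling; defaults to
#'   [mtdna_gene_set()] for the platform of the first cell.
#' @param resolution_grid resolutions scanned for the HE/LE split.
#' @param snn_k SNN neighbours.
#' @param regress_total regress total counts during scaling.
#' @param marker_test `"bimod"` or `"negbinom"`.
#' @param n_repertoire_iter,repertoire_sample_size repertoire
#'   permutation sizes (1000 / 1000).
#' @param n_conservation_iter conservation permutation iterations
#'   (10000).
#' @param seed run seed; every stochastic stage consumes a seed derived
#'   from it and the stage name.
#' @param outdir output directory; `NULL` disables file output.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, counts_format = "tsv", pileups = NULL,
                       pileup_groups = NULL, alpha_pileups = NULL,
                       track = NULL, qc = qc_config(),
                       variant_qc = variant_qc_config(),
                       mt_genes = NULL,
                       resolution_grid = seq(0.1, 1, by = 0.1),
                       snn_k = 20, regress_total = TRUE,
                       marker_test = "bimod",
                       n_repertoire_iter = 1000,
                       repertoire_sample_size = 1000,
                       n_conservation_iter = 10000,
                       seed = 1L, outdir = NULL) {
  stopifnot(!is.null(seed))
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(...) message("[mitocell] ", ...)

load_pileup_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_pileup_dir(x) else x
}

write_tsv <- function(d, path) write.table(d, path, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, per-individual and pooled HE/LE
#' clustering with the retention statistic, marker detection, variant
#' calling with the repertoire permutation and sharing summaries, and
#' the conservation permutation test, in that order. A rerun with the
#' same config and seed reproduces every output. Any stage error aborts
#' with the stage name.
#'
#' @param cfg a [run_config()].
#' @return A `run_summary` list (counts per stage, HE/LE sizes,
#'   retention, headline test results, paths written), invisibly
#'   containing the stage objects under `$objects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$outdir))
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop_ctx("pipeline stage '", name, "' failed: ",
               conditionMessage(e)))
  }
  summary <- list(seed = cfg$seed, stages_skipped = character(0))
  obj <- list()

  # ---- qc ----
  m <- stage("io", {
    if (inherits(cfg$counts, "count_matrix")) cfg$counts
    else read_count_matrix(cfg$counts, cfg$counts_format)
  })
  summary$n_cells_input <- ncol(m$counts)
  summary$n_genes <- nrow(m$counts)
  rep <- stage("qc", {
    r <- compute_cell_qc(m, cfg$qc)
    apply_mtdna_fraction_rule(r, cfg$qc$mtdna_fraction_rule)
  })
  mf <- stage("qc", filter_cells(m, rep))
  pipeline_log("qc: ", ncol(mf$counts), "/", ncol(m$counts),
               " cells pass")
  summary$n_cells_pass_qc <- ncol(mf$counts)
  summary$removed_per_rule <- as.list(attr(rep, "removed_per_rule"))
  obj$qc_report <- rep; obj$matrix <- mf

  # ---- clustering ----
  mt_genes <- cfg$mt_genes %||%
    mtdna_gene_set(mf$cell_meta$platform[1])
  e <- stage("normalize", normalize_and_scale(mf, cfg$regress_total))
  cl_seed <- derive_seed(cfg$seed, "clustering")
  cluster_one <- function(cells, scope) {
    sub <- subset_cells(mf, cells)
    es <- normalize_and_scale(sub, cfg$regress_total)
    emb <- pca_mtdna(es, mt_genes)
    sc <- scan_resolutions(emb, cfg$resolution_grid, k = cfg$snn_k,
                           seed = cl_seed)
    a <- if (sc$two_cluster_found) sc$selected else {
      # no resolution yields exactly 2 communities: merge the
      # fewest-cluster (>= 2) solution into two super-groups by mean
      # mtDNA expression; flagged in the summary
      ncl <- sc$table$n_clusters
      cand <- which(ncl >= 2)
      if (!length(cand))
        stop_ctx("no resolution in the grid yields >= 2 clusters (",
                 scope, ")")
      pick <- cand[which.min(ncl[cand])]
      pipeline_log("clustering (", scope, "): no exact 2-cluster ",
                   "resolution; merging ", ncl[pick], " clusters")
      merge_to_two(sc$assignments[[pick]], es, mt_genes)
    }
    a <- label_he_le(a, es, mt_genes)
    a$scope <- scope
    a
  }
  pooled <- stage("clustering",
                  cluster_one(colnames(mf$counts), "pooled"))
  inds <- split(mf$cell_meta$cell, mf$cell_meta$individual)
  per_ind <- stage("clustering", lapply(inds, function(cells) {
    if (length(cells) <= cfg$snn_k + 1)
      stop_ctx("individual with too few cells for k = ", cfg$snn_k)
    cluster_one(cells, "per_individual")
  }))
  ret <- stage("clustering", cluster_retention(per_ind, pooled))
  labels <- pooled$he_le
  summary$he_le_sizes <- as.list(table(labels))
  summary$retention_fraction <- ret$fraction_retained
  pipeline_log("clustering: HE=", sum(labels == "HE"), " LE=",
               sum(labels == "LE"), ", retention ",
               sprintf("%.3f", ret$fraction_retained))
  markers <- stage("markers", {
    x <- if (cfg$marker_test == "negbinom") mf else e
    find_markers(x, labels, test = cfg$marker_test)
  })
  summary$n_significant_markers <- sum(markers$p_adjusted < 0.05)
  obj$expression <- e; obj$pooled <- pooled; obj$per_individual <- per_ind
  obj$retention <- ret; obj$markers <- markers

  # ---- mutations ----
  pile <- stage("io", load_pileup_input(cfg$pileups))
  if (is.null(pile)) {
    pipeline_log("no pileups configured: mutation and conservation ",
                 "stages skipped")
    summary$stages_skipped <- c(summary$stages_skipped, "mutations",
                                "conservation")
  } else {
    res <- stage("mutations", {
      elig <- eligible_cells(pile, cfg$variant_qc)
      if (!length(elig)) stop_ctx("no cell reaches the covered-position ",
                                  "eligibility threshold")
      pile <- pile[elig]
      grp <- labels[intersect(names(pile), names(labels))]
      extra <- setdiff(names(pile), names(grp))
      if (length(extra) && !is.null(cfg$pileup_groups))
        grp <- c(grp, cfg$pileup_groups[intersect(extra,
                                                  names(cfg$pileup_groups))])
      pile <- pile[names(pile) %in% names(grp)]
      if (!length(pile))
        stop_ctx("no eligible pileup cell has a subgroup label")
      calls <- call_variants(pile, cfg$variant_qc)
      calls$subgroup <- unname(grp[calls$cell])
      hq <- high_quality_positions(pile, cfg$variant_qc)
      repert <- repertoire_permutation(
        calls, hq, grp, n_iter = cfg$n_repertoire_iter,
        sample_size = cfg$repertoire_sample_size,
        seed = derive_seed(cfg$seed, "repertoire"))
      list(eligible = names(pile), groups = grp, calls = calls,
           hq = hq, repertoire = repert)
    })
    summary$n_eligible_cells <- length(res$eligible)
    summary$n_variant_calls <- nrow(res$calls)
    summary$repertoire_mean_pct <-
      lapply(res$repertoire$subgroups, `[[`, "mean")
    he_calls <- res$calls[res$calls$subgroup == "HE", , drop = FALSE]
    le_calls <- res$calls[res$calls$subgroup == "LE", , drop = FALSE]
    summary$unique_vs_overlapping <-
      as.list(unique_vs_overlapping(he_calls, le_calls))
    if (all(c("HE", "LE") %in% names(res$repertoire$subgroups))) {
      rp <- res$repertoire$subgroups
      av <- stage("mutations", anova_oneway(
        c(rp$HE$percent, rp$LE$percent),
        rep(c("HE", "LE"), c(length(rp$HE$percent),
                             length(rp$LE$percent)))))
      summary$repertoire_anova_p <- av$p_value
    }
    alpha <- stage("io", load_pileup_input(cfg$alpha_pileups))
    if (!is.null(alpha)) {
      acalls <- stage("mutations", call_variants(alpha, cfg$variant_qc))
      inh <- stage("mutations", classify_inherited(res$calls, acalls))
      res$inherited <- inh
      if (!is.null(inh$percent_table))
        summary$percent_inherited <-
          setNames(as.list(inh$percent_table$percent_inherited),
                   inh$percent_table$subgroup)
    }
    res$summary_table <- stage("mutations",
                               summarize_subgroup_mutations(res$calls))
    obj$mutations <- res
    pipeline_log("mutations: ", nrow(res$calls), " calls over ",
                 length(res$eligible), " eligible cells")

    # ---- conservation ----
    trk <- stage("io", {
      if (is.null(cfg$track)) NULL
      else if (inherits(cfg$track, "conservation_track")) cfg$track
      else read_conservation_track(cfg$track, "bedgraph")
    })
    if (is.null(trk)) {
      pipeline_log("no conservation track configured: stage skipped")
      summary$stages_skipped <- c(summary$stages_skipped, "conservation")
    } else {
      cons <- stage("conservation", {
        per_sg <- list(); cell_ratio <- numeric(0); cell_grp <- character(0)
        for (g in unique(res$calls$subgroup)) {
          gc <- res$calls[res$calls$subgroup == g, , drop = FALSE]
          if (!nrow(gc)) next
          gcells <- names(res$groups)[res$groups == g]
          pool <- sort(unique(unlist(res$hq[gcells])))
          per_sg[[g]] <- conservation_test(
            gc$pos, pool, trk, n_iter = cfg$n_conservation_iter,
            seed = derive_seed(cfg$seed, paste0("conservation_", g)))
          pm <- mean(track_score_at(trk, pool))
          for (cl in unique(gc$cell)) {
            obs <- observed_mean_score(gc$pos[gc$cell == cl], trk)
            cell_ratio <- c(cell_ratio, obs / pm)
            cell_grp <- c(cell_grp, g)
          }
        }
        av <- if (length(unique(cell_grp)) >= 2 &&
                  all(table(cell_grp) >= 2))
          anova_oneway(cell_ratio, cell_grp) else NULL
        list(per_subgroup = per_sg, cell_ratio = cell_ratio,
             cell_group = cell_grp, anova = av)
      })
      obj$conservation <- cons
      summary$conservation_ratio <-
        lapply(cons$per_subgroup, `[[`, "ratio")
      summary$conservation_p <-
        lapply(cons$per_subgroup, `[[`, "p_value")
      if (!is.null(cons$anova))
        summary$conservation_anova_p <- cons$anova$p_value
    }
  }

  # ---- outputs ----
  if (!is.null(cfg$outdir)) {
    od <- cfg$outdir
    write_tsv(as.data.frame(rep), file.path(od, "qc_report.tsv"))
    write_count_matrix(mf, file.path(od, "filtered_counts.tsv"))
    write_tsv(data.frame(cell = names(labels),
                         cluster = unname(pooled$cluster[names(labels)]),
                         he_le = unname(labels)),
              file.path(od, "labels.tsv"))
    write_tsv(data.frame(cell = rownames(pooled$embedding),
                         PC1 = pooled$embedding[, 1],
                         PC2 = pooled$embedding[, 2]),
              file.path(od, "embedding.tsv"))
    write_tsv(markers, file.path(od, "markers.tsv"))
    if (!is.null(obj$mutations)) {
      write_tsv(obj$mutations$calls, file.path(od, "calls.tsv"))
      rp <- obj$mutations$repertoire$subgroups
      write_tsv(data.frame(subgroup = names(rp),
                           n_cells = vapply(rp, `[[`, 0, "n_cells"),
                           mean_pct = vapply(rp, `[[`, 0, "mean"),
                           sd_pct = vapply(rp, `[[`, 0, "sd")),
                file.path(od, "repertoire.tsv"))
      if (!is.null(obj$mutations$inherited$percent_table))
        write_tsv(obj$mutations$inherited$percent_table,
                  file.path(od, "inherited.tsv"))
    }
    if (!is.null(obj$conservation)) {
      cs <- obj$conservation$per_subgroup
      write_tsv(data.frame(subgroup = names(cs),
                           observed = vapply(cs, `[[`, 0, "observed_mean"),
                           expected = vapply(cs, `[[`, 0, "expected_mean"),
                           ratio = vapply(cs, `[[`, 0, "ratio"),
                           p_value = vapply(cs, `[[`, 0, "p_value"),
                           direction = vapply(cs, `[[`, "", "direction")),
                file.path(od, "conservation.tsv"))
    }
    jsonlite::write_json(summary, file.path(od, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$outdir <- od
  }
  summary$objects <- obj
  class(summary) <- "run_summary"
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("mitocell run summary\n")
  cat(sprintf("  cells: %d in, %d pass QC\n", x$n_cells_input,
              x$n_cells_pass_qc))
  cat(sprintf("  HE/LE: %s, retention %.3f\n",
              paste(names(x$he_le_sizes), unlist(x$he_le_sizes),
                    sep = "=", collapse = " "),
              x$retention_fraction))
  if (!is.null(x$n_variant_calls))
    cat(sprintf("  variant calls: %d over %d eligible cells\n",
                x$n_variant_calls, x$n_eligible_cells))
  if (!is.null(x$conservation_ratio))
    cat(sprintf("  conservation ratio: %s\n",
                paste(names(x$conservation_ratio),
                      sprintf("%.3f", unlist(x$conservation_ratio)),
                      sep = "=", collapse = " ")))
  if (length(x$stages_skipped))
    cat("  skipped:", paste(unique(x$stages_skipped), collapse = ", "),
        "\n")
  invisible(x)
}
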