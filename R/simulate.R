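# Seeded generators producing count matrices, pileups and conservation
# tracks with planted ground truth. Defaults mirror the study design the
# analysis assumes: two beta-cell subgroups separated by a log-fold shift
# in mtDNA protein-coding gene expression, with co-shifted nuclear OXPHOS
# and insulin marker genes, negative-binomial counts and dropout.

HUMAN_MT_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                    "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                    "MT-ND5", "MT-ND6", "MT-CYB")

#' mtDNA protein-coding gene sets by platform
#'
#' All 13 mtDNA-encoded OXPHOS subunit genes are usable on full-length
#' platforms (Fluidigm C1, CEL-Seq2). The inDrops platform selects for
#' polyadenylated transcripts, so genes with short poly-A tails are
#' excluded: ND5, ND6, ND4L and ATP8 in human (9 genes remain); Nd4l,
#' Atp8 and Nd6 in mouse (10 genes remain).
#'
#' @param platform `"FluidigmC1"`, `"CelSeq2"` or `"inDrops"`.
#' @param organism `"human"` or `"mouse"`.
#' @return Character vector of gene ids.
#' @export
mtdna_gene_set <- function(platform = c("FluidigmC1", "CelSeq2", "inDrops"),
                           organism = c("human", "mouse")) {
  platform <- match.arg(platform)
  organism <- match.arg(organism)
  genes <- HUMAN_MT_GENES
  if (organism == "mouse") {
    cap <- function(x) paste0(substr(x, 1, 1), tolower(substring(x, 2)))
    genes <- paste0("mt-", cap(sub("MT-", "", genes)))
  }
  if (platform == "inDrops") {
    drop <- if (organism == "human") c("MT-ND5", "MT-ND6", "MT-ND4L",
                                       "MT-ATP8")
    else c("mt-Nd4l", "mt-Atp8", "mt-Nd6")
    genes <- setdiff(genes, drop)
  }
  genes
}

#' Configuration for the expression-matrix simulator
#'
#' @param n_cells_he,n_cells_le cells per subgroup.
#' @param n_mt_genes number of mtDNA protein-coding genes (max 13).
#' @param n_oxphos_genes nuclear OXPHOS genes co-shifted with the HE
#'   group.
#' @param n_marker_genes additional marker genes (first is INS)
#'   co-shifted with HE.
#' @param n_ribosomal_genes unshifted RPS/RPL genes (targets of the QC
#'   ribosomal-fraction rule).
#' @param n_background_genes unshifted background genes.
#' @param mt_logfc,oxphos_logfc,marker_logfc natural-log fold change of
#'   the HE group over LE for each gene class.
#' @param nb_dispersion negative-binomial dispersion (1/size); variance
#'   is `mu + dispersion * mu^2`.
#' @param dropout_rate probability an observed count is zeroed
#'   (independent Bernoulli dropout).
#' @param library_size_mean mean per-cell library-size factor
#'   (log-normal).
#' @param library_size_cv coefficient of variation of library-size
#'   factors.
#' @param n_individuals donors; cells are split evenly among them.
#' @param platform platform label written into the cell annotations.
#' @param seed integer seed; same seed, same matrix.
#' @return A `sim_expression_config` list.
#' @export
sim_expression_config <- function(n_cells_he = 200, n_cells_le = 200,
                                  n_mt_genes = 13, n_oxphos_genes = 20,
                                  n_marker_genes = 2,
                                  n_ribosomal_genes = 10,
                                  n_background_genes = 200,
                                  mt_logfc = 1.5, oxphos_logfc = 0.8,
                                  marker_logfc = 0.5,
                                  nb_dispersion = 0.3, dropout_rate = 0.2,
                                  library_size_mean = 1,
                                  library_size_cv = 0.3,
                                  n_individuals = 1,
                                  platform = "FluidigmC1", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_cells_he >= 1, n_cells_le >= 1, n_mt_genes >= 1,
            n_mt_genes <= 13, n_background_genes >= 1,
            nb_dispersion > 0, dropout_rate >= 0, dropout_rate < 1,
            is.finite(mt_logfc), is.finite(oxphos_logfc),
            is.finite(marker_logfc), n_individuals >= 1)
  structure(cfg, class = "sim_expression_config")
}

#' Simulate a count matrix with planted HE/LE structure
#'
#' Counts are negative binomial with group-specific means (HE means are
#' the LE means times `exp(logfc)` for mtDNA/OXPHOS/marker genes),
#' multiplied by per-cell log-normal library-size factors, then zeroed
#' independently with probability `dropout_rate`. mtDNA genes carry the
#' canonical `MT-` names so that platform gene sets resolve against the
#' matrix; `INS` and `GCG` are always present (GCG at low baseline in
#' these beta cells) so the doublet rule can be exercised.
#'
#' @param cfg a [sim_expression_config()].
#' @return `list(matrix = count_matrix, truth = list(cell_labels,
#'   gene_class, group_means, library_factors))`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_expression_config"))
  with_seed(cfg$seed, {
    mt <- HUMAN_MT_GENES[seq_len(cfg$n_mt_genes)]
    oxphos <- if (cfg$n_oxphos_genes > 0)
      sprintf("NDUFB%02d", seq_len(cfg$n_oxphos_genes)) else character(0)
    markers <- if (cfg$n_marker_genes > 0)
      c("INS", "IAPP", sprintf("MARK%02d", seq_len(max(0, cfg$n_marker_genes - 2L))))[seq_len(cfg$n_marker_genes)]
    else character(0)
    ribo <- if (cfg$n_ribosomal_genes > 0)
      sprintf("RPS%02d", seq_len(cfg$n_ribosomal_genes)) else character(0)
    bg <- sprintf("GENE%04d", seq_len(cfg$n_background_genes))
    genes <- c(mt, oxphos, markers, "GCG", ribo, bg)
    gene_class <- c(rep("mt", length(mt)), rep("oxphos", length(oxphos)),
                    rep("marker", length(markers)), "other_marker",
                    rep("ribosomal", length(ribo)),
                    rep("background", length(bg)))
    names(gene_class) <- genes

    n_he <- cfg$n_cells_he; n_le <- cfg$n_cells_le
    n <- n_he + n_le
    cells <- sprintf("cell%04d", seq_len(n))
    labels <- setNames(c(rep("HE", n_he), rep("LE", n_le)), cells)

    # baseline (LE) means: mtDNA genes dominate cellular mRNA content
    base <- setNames(numeric(length(genes)), genes)
    base[gene_class == "mt"] <- rlnorm(sum(gene_class == "mt"),
                                       log(6), 0.3)
    base[gene_class == "oxphos"] <- rlnorm(sum(gene_class == "oxphos"),
                                           log(8), 0.3)
    base[gene_class == "marker"] <- 80
    base["GCG"] <- 0.5   # beta cells: glucagon near-silent
    base[gene_class == "ribosomal"] <- rlnorm(sum(gene_class == "ribosomal"),
                                              log(10), 0.3)
    base[gene_class == "background"] <- rlnorm(sum(gene_class == "background"),
                                               log(3), 0.8)
    lfc <- setNames(numeric(length(genes)), genes)
    lfc[gene_class == "mt"] <- cfg$mt_logfc
    lfc[gene_class == "oxphos"] <- cfg$oxphos_logfc
    lfc[gene_class == "marker"] <- cfg$marker_logfc

    sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
    libf <- rlnorm(n, log(cfg$library_size_mean) - sdlog^2 / 2, sdlog)
    he <- labels == "HE"
    mu <- outer(base, libf)
    mu[, he] <- mu[, he] * exp(lfc)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / cfg$nb_dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, cells))
    if (cfg$dropout_rate > 0) {
      drop <- matrix(runif(length(counts)) < cfg$dropout_rate,
                     nrow = nrow(counts))
      counts[drop] <- 0L
    }
    meta <- data.frame(
      cell = cells,
      individual = sprintf("D%d", rep_len(seq_len(cfg$n_individuals), n)),
      cell_type = "beta", platform = cfg$platform,
      stringsAsFactors = FALSE)
    group_means <- cbind(HE = base * exp(lfc) * cfg$library_size_mean,
                         LE = base * cfg$library_size_mean)
    list(matrix = count_matrix(counts, meta),
         truth = list(cell_labels = labels, gene_class = gene_class,
                      group_means = group_means, library_factors = libf))
  })
}

#' Configuration for the pileup simulator
#'
#' @param mt_length mitochondrial genome length simulated.
#' @param coding_region integer `c(start, end)` of the protein-coding
#'   interval (1-based inclusive).
#' @param n_cells named counts per group, e.g. `c(HE = 20, LE = 20,
#'   alpha = 0)`.
#' @param coverage_mean,coverage_sd per-position read depth (normal,
#'   rounded, floored at 0).
#' @param planted_variants data.frame with columns `position`,
#'   `alt_base`, `frequency` in (0, 1\], `group` in
#'   `{"HE","LE","shared_alpha"}`, `strand_balance` in \[0, 1\] (fraction
#'   of alt reads on the forward strand). `shared_alpha` variants are
#'   planted in alpha cells and in both beta subgroups.
#' @param read_end_fraction fraction of reads flagged as terminating at
#'   the position.
#' @param seed integer seed.
#' @return A `sim_pileup_config` list.
#' @export
sim_pileup_config <- function(mt_length = 2000,
                              coding_region = c(101L, 1900L),
                              n_cells = c(HE = 10, LE = 10, alpha = 0),
                              coverage_mean = 600, coverage_sd = 80,
                              planted_variants = NULL,
                              read_end_fraction = 0.05, seed = 1L) {
  if (is.null(planted_variants))
    planted_variants <- data.frame(position = integer(0),
                                   alt_base = character(0),
                                   frequency = numeric(0),
                                   group = character(0),
                                   strand_balance = numeric(0))
  stopifnot(mt_length >= 10, length(coding_region) == 2,
            coding_region[2] <= mt_length,
            all(c("HE", "LE") %in% names(n_cells)),
            read_end_fraction >= 0, read_end_fraction <= 1)
  pv <- planted_variants
  if (nrow(pv)) {
    stopifnot(all(pv$frequency > 0), all(pv$frequency <= 1),
              all(pv$position >= 1), all(pv$position <= mt_length),
              all(pv$group %in% c("HE", "LE", "shared_alpha")),
              all(pv$strand_balance >= 0), all(pv$strand_balance <= 1))
    if (any(pv$frequency * coverage_mean < 1))
      warning("planted frequency x mean coverage < 1: variant likely ",
              "undetectable", call. = FALSE)
  }
  structure(list(mt_length = as.integer(mt_length),
                 coding_region = as.integer(coding_region),
                 n_cells = n_cells, coverage_mean = coverage_mean,
                 coverage_sd = coverage_sd, planted_variants = pv,
                 read_end_fraction = read_end_fraction,
                 seed = as.integer(seed)),
            class = "sim_pileup_config")
}

#' Simulate strand-resolved per-cell pileups with planted variants
#'
#' Every position gets a depth drawn from the configured coverage law.
#' At a planted position (for cells of the planted group) the alt-read
#' count is Binomial(depth, frequency), split across strands by
#' `strand_balance`; all remaining reads are reference, split evenly
#' across strands. Read-end flags are assigned per read at
#' `read_end_fraction`. All other positions are pure reference.
#'
#' @param cfg a [sim_pileup_config()].
#' @return `list(pileups = named list of pileup data.frames, truth =
#'   list(cell_groups, planted_variant_table, reference))`.
#' @export
simulate_pileups <- function(cfg) {
  stopifnot(inherits(cfg, "sim_pileup_config"))
  with_seed(cfg$seed, {
    L <- cfg$mt_length
    refseq <- sample(PILEUP_BASES, L, replace = TRUE)
    # the reference must differ from any planted alt allele
    for (vi in seq_len(nrow(cfg$planted_variants))) {
      p <- cfg$planted_variants$position[vi]
      if (refseq[p] == cfg$planted_variants$alt_base[vi])
        refseq[p] <- sample(setdiff(PILEUP_BASES, refseq[p]), 1L)
    }
    groups <- rep(names(cfg$n_cells), cfg$n_cells)
    cells <- sprintf("%s_cell%03d", groups, unlist(lapply(cfg$n_cells,
                                                          seq_len)))
    pv <- cfg$planted_variants
    pileups <- vector("list", length(cells))
    names(pileups) <- cells
    for (ci in seq_along(cells)) {
      grp <- groups[ci]
      depth <- pmax(0L, as.integer(round(rnorm(L, cfg$coverage_mean,
                                               cfg$coverage_sd))))
      cnt <- matrix(0L, nrow = L, ncol = 13L,
                    dimnames = list(NULL, pileup_count_cols()))
      # which planted variants apply to this cell's group
      use <- if (nrow(pv))
        pv$group == grp | (pv$group == "shared_alpha") else logical(0)
      alt_n <- integer(L)
      for (vi in which(use)) {
        p <- pv$position[vi]
        a <- rbinom(1L, depth[p], pv$frequency[vi])
        af <- rbinom(1L, a, pv$strand_balance[vi])
        cnt[p, paste0("fwd_", pv$alt_base[vi])] <-
          cnt[p, paste0("fwd_", pv$alt_base[vi])] + af
        cnt[p, paste0("rev_", pv$alt_base[vi])] <-
          cnt[p, paste0("rev_", pv$alt_base[vi])] + (a - af)
        alt_n[p] <- alt_n[p] + a
      }
      ref_n <- depth - alt_n
      ref_f <- rbinom(L, ref_n, 0.5)
      fi <- cbind(seq_len(L), match(paste0("fwd_", refseq),
                                    colnames(cnt)))
      cnt[fi] <- cnt[fi] + ref_f
      fi[, 2] <- match(paste0("rev_", refseq), colnames(cnt))
      cnt[fi] <- cnt[fi] + (ref_n - ref_f)
      if (cfg$read_end_fraction > 0) {
        for (b in PILEUP_BASES) {
          nb <- cnt[, paste0("fwd_", b)] + cnt[, paste0("rev_", b)]
          cnt[, paste0("end_", b)] <- rbinom(L, nb,
                                             cfg$read_end_fraction)
        }
      }
      df <- data.frame(cell = cells[ci], pos = seq_len(L), ref = refseq,
                       depth = depth, cnt, stringsAsFactors = FALSE)
      pileups[[ci]] <- df[df$depth > 0L, , drop = FALSE]
    }
    truth_tab <- pv
    if (nrow(truth_tab)) truth_tab$ref_base <- refseq[truth_tab$position]
    list(pileups = pileups,
         truth = list(cell_groups = setNames(groups, cells),
                      planted_variant_table = truth_tab,
                      reference = refseq))
  })
}

#' Simulate a piecewise-constant conservation track
#'
#' Divides `1..mt_length` into `length(block_scores)` equal blocks with
#' the given scores; optional beta-distributed jitter around each block
#' score keeps values in \[0, 1\].
#'
#' @param mt_length track length.
#' @param block_scores numeric scores in \[0, 1\], one per block.
#' @param seed integer seed (only used when `jitter_sd > 0`).
#' @param jitter_sd standard deviation of per-position jitter (0 =
#'   exactly piecewise constant).
#' @return A [conservation_track()].
#' @export
simulate_conservation_track <- function(mt_length, block_scores = 0.5,
                                        seed = 1L, jitter_sd = 0) {
  stopifnot(all(block_scores >= 0), all(block_scores <= 1), mt_length >= 1)
  idx <- ceiling(seq_len(mt_length) / mt_length * length(block_scores))
  score <- block_scores[idx]
  if (jitter_sd > 0) {
    score <- with_seed(seed, {
      m <- pmin(pmax(score, 1e-3), 1 - 1e-3)
      v <- pmin(jitter_sd^2, m * (1 - m) * 0.99)
      k <- m * (1 - m) / v - 1
      stats::rbeta(mt_length, m * k, (1 - m) * k)
    })
  }
  conservation_track(seq_len(mt_length), score)
}

#' Estimate the NB dispersion of background genes in a simulated matrix
#'
#' Maximum-likelihood per-gene dispersion (via [MASS::theta.ml()]) with
#' the gene mean as fitted value, averaged over genes. Used to check
#' parameter recovery of [simulate_counts()].
#'
#' @param m a [count_matrix()].
#' @param genes genes to use (defaults to `GENE*` background genes).
#' @return Mean estimated dispersion (1/theta).
#' @export
estimate_dispersion <- function(m, genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  genes <- genes %||% grep("^GENE", rownames(m$counts), value = TRUE)
  if (!length(genes)) stop_ctx("no genes to estimate dispersion from")
  disp <- vapply(genes, function(g) {
    y <- m$counts[g, ]
    if (mean(y) <= 0 || var(y) <= mean(y)) return(NA_real_)
    th <- tryCatch(
      suppressWarnings(MASS::theta.ml(y, rep(mean(y), length(y)),
                                      limit = 50)),
      error = function(e) NA_real_)
    if (is.na(th)) NA_real_ else 1 / th
  }, numeric(1))
  mean(disp, na.rm = TRUE)
}
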