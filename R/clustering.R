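# Sub-population discovery on the mtDNA protein-coding gene subspace:
# per-individual (or pooled) PCA, shared-nearest-neighbour graph
# community detection on the first two PCs, HE/LE labelling by mean
# normalized mtDNA expression, and a cross-scope retention statistic.

#' PCA of cells over the mtDNA protein-coding gene subspace
#'
#' Runs PCA on the per-gene scaled expression restricted to `mt_genes`
#' and returns the first two principal-component coordinates per cell.
#'
#' @param e an `expression_matrix` from [normalize_and_scale()].
#' @param mt_genes character vector of mtDNA gene ids (see
#'   [mtdna_gene_set()]).
#' @return Cells x 2 matrix of PC coordinates with attributes `sdev`
#'   (all component standard deviations) and `var_explained`.
#' @export
pca_mtdna <- function(e, mt_genes) {
  stopifnot(inherits(e, "expression_matrix"))
  mt_genes <- intersect(mt_genes, rownames(e$scaled))
  if (length(mt_genes) < 2) stop_ctx("need >= 2 mtDNA genes in the matrix")
  x <- t(e$scaled[mt_genes, , drop = FALSE])   # cells x genes
  if (nrow(x) < 3) stop_ctx("need >= 3 cells for PCA")
  if (all(apply(x, 2, sd) == 0))
    stop_ctx("constant expression across all cells: PCA undefined")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]
  if (k == 1L) emb <- cbind(emb, PC2 = 0)
  attr(emb, "sdev") <- pc$sdev
  attr(emb, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  emb
}

# k-nearest-neighbour indices by Euclidean distance (brute force; the
# embeddings here are 2-D and at most a few thousand cells).
knn_indices <- function(x, k) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# Shared-nearest-neighbour graph: edge weight = Jaccard overlap of the
# two cells' neighbour sets (self included), pruned below `prune`.
snn_graph <- function(emb, k = 20, prune = 1 / 15) {
  n <- nrow(emb)
  if (n <= k) stop_ctx("only ", n, " cells but k = ", k,
                       " neighbours requested; lower k")
  nn <- knn_indices(emb, k)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                              j = unlist(sets), x = 1, dims = c(n, n))
  shared <- as.matrix(adj %*% Matrix::t(adj))
  jac <- shared / (2 * (k + 1) - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::set_vertex_attr(g, "name", value = rownames(emb))
}

#' Density clustering of a 2-D embedding
#'
#' Builds a shared-nearest-neighbour graph (k-NN by Euclidean distance,
#' Jaccard edge weights) on the embedding and finds communities by
#' Louvain modularity optimization at the given resolution.
#' Deterministic given `seed`.
#'
#' @param embedding cells x 2 matrix (rownames = cell ids).
#' @param resolution modularity resolution in \[0.1, 1\].
#' @param k neighbours for the SNN graph.
#' @param seed integer seed for the community search.
#' @return A `cluster_assignment`: list with `cluster` (named integer
#'   vector), `he_le` (NA until [label_he_le()]), `embedding`,
#'   `resolution`, `scope`.
#' @export
density_cluster <- function(embedding, resolution = 0.8, k = 20,
                            seed = 1L) {
  stopifnot(is.matrix(embedding), ncol(embedding) == 2)
  if (is.null(rownames(embedding)))
    rownames(embedding) <- sprintf("cell%04d", seq_len(nrow(embedding)))
  g <- snn_graph(embedding, k = k)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  cl <- setNames(as.integer(igraph::membership(comm)), rownames(embedding))
  structure(list(cluster = cl,
                 he_le = setNames(rep(NA_character_, length(cl)),
                                  names(cl)),
                 embedding = embedding, resolution = resolution,
                 scope = "pooled", k = k, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d cells, %d clusters @ resolution %.2f\n",
              x$scope, length(x$cluster), length(unique(x$cluster)),
              x$resolution))
  if (!all(is.na(x$he_le)))
    print(table(x$he_le))
  invisible(x)
}

#' Cluster an embedding across a grid of resolutions
#'
#' Clusters once per grid value and selects, as the default assignment,
#' the smallest resolution yielding exactly two clusters (the HE/LE
#' split the downstream analysis expects); if no grid value does, the
#' result is flagged.
#'
#' @param embedding cells x 2 matrix.
#' @param grid resolutions within \[0.1, 1\].
#' @param k,seed passed to [density_cluster()].
#' @return List with `table` (data.frame resolution / n_clusters),
#'   `assignments` (one `cluster_assignment` per grid value),
#'   `selected` (the chosen assignment or `NULL`), `two_cluster_found`.
#' @export
scan_resolutions <- function(embedding, grid = seq(0.1, 1, by = 0.1),
                             k = 20, seed = 1L) {
  stopifnot(all(grid >= 0.1 - 1e-9), all(grid <= 1 + 1e-9))
  grid <- sort(grid)
  assignments <- lapply(grid, function(r)
    density_cluster(embedding, resolution = r, k = k, seed = seed))
  ncl <- vapply(assignments, function(a) length(unique(a$cluster)), 0L)
  tab <- data.frame(resolution = grid, n_clusters = ncl)
  sel <- which(ncl == 2L)
  list(table = tab, assignments = assignments,
       selected = if (length(sel)) assignments[[sel[1]]] else NULL,
       two_cluster_found = length(sel) > 0)
}

# Merge a >2-cluster assignment into two super-groups: clusters are
# ranked by mean normalized mtDNA expression and split at the largest
# gap between consecutive cluster means.
merge_to_two <- function(assignment, e, mt_genes) {
  ids <- sort(unique(assignment$cluster))
  if (length(ids) < 2) stop_ctx("cannot merge fewer than 2 clusters")
  mt_genes <- intersect(mt_genes, rownames(e$normalized))
  cells <- names(assignment$cluster)
  expr <- colMeans(e$normalized[mt_genes, cells, drop = FALSE])
  means <- vapply(ids, function(id)
    mean(expr[assignment$cluster == id]), numeric(1))
  o <- order(means)
  gap <- which.max(diff(means[o]))
  low <- ids[o][seq_len(gap)]
  assignment$cluster <- setNames(
    ifelse(assignment$cluster %in% low, 1L, 2L), cells)
  assignment$merged_from <- length(ids)
  assignment
}

#' Label two clusters as HE/LE by mean mtDNA expression
#'
#' The cluster with the higher mean normalized mtDNA-gene expression is
#' labelled HE (high expression), the other LE.
#'
#' @param assignment a two-cluster `cluster_assignment`.
#' @param e the `expression_matrix` the clustering was computed from.
#' @param mt_genes mtDNA gene ids.
#' @return The assignment with `he_le` filled in.
#' @export
label_he_le <- function(assignment, e, mt_genes) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(e, "expression_matrix"))
  ids <- sort(unique(assignment$cluster))
  if (length(ids) != 2)
    stop_ctx("HE/LE labelling needs exactly 2 clusters, got ",
             length(ids))
  mt_genes <- intersect(mt_genes, rownames(e$normalized))
  cells <- names(assignment$cluster)
  expr <- colMeans(e$normalized[mt_genes, cells, drop = FALSE])
  means <- vapply(ids, function(id)
    mean(expr[assignment$cluster == id]), numeric(1))
  if (abs(diff(means)) < .Machine$double.eps)
    stop_ctx("tie in cluster mean mtDNA expression: HE/LE undefined")
  he_id <- ids[which.max(means)]
  assignment$he_le <- setNames(
    ifelse(assignment$cluster == he_id, "HE", "LE"), cells)
  assignment$cluster_means <- setNames(means, ids)
  assignment
}

#' Fraction of cells retaining their HE/LE identity across scopes
#'
#' Compares the HE/LE label each cell received in its per-individual
#' clustering against its label in the pooled clustering (labels are
#' matched by the expression rule of [label_he_le()], not by cluster
#' id), and reports the retained fraction overall and per individual.
#'
#' @param per_individual list of labelled `cluster_assignment`s, one per
#'   individual.
#' @param pooled labelled pooled `cluster_assignment` over the same
#'   cells.
#' @return A `retention_result`: list with `fraction_retained`,
#'   `per_individual` breakdown, `retained_cells`.
#' @export
cluster_retention <- function(per_individual, pooled) {
  stopifnot(inherits(pooled, "cluster_assignment"))
  ind_labels <- do.call(c, unname(lapply(per_individual,
                                         function(a) a$he_le)))
  ind_of <- do.call(c, unname(lapply(seq_along(per_individual),
    function(i) setNames(rep(names(per_individual)[i] %||%
                               as.character(i),
                             length(per_individual[[i]]$he_le)),
                         names(per_individual[[i]]$he_le)))))
  cells <- names(pooled$he_le)
  if (!setequal(cells, names(ind_labels)))
    stop_ctx("per-individual and pooled scopes cover different cells")
  ind_labels <- ind_labels[cells]
  ind_of <- ind_of[cells]
  match_ok <- ind_labels == pooled$he_le[cells]
  per_ind <- tapply(match_ok, ind_of, mean)
  structure(list(fraction_retained = mean(match_ok),
                 per_individual = per_ind,
                 retained_cells = cells[match_ok]),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("retention: %.1f%% of cells keep their HE/LE identity\n",
              100 * x$fraction_retained))
  invisible(x)
}

#' Marker genes between two cell groups
#'
#' Tests every gene expressed (count > 0, or normalized value > 0) in
#' more than `min_expressed_fraction` of the cells of at least one group
#' with the chosen differential-expression test, and reports
#' BH-adjusted p-values and log-fold-changes.
#'
#' @param x a [count_matrix()] (required for `test = "negbinom"`) or an
#'   `expression_matrix` (for `test = "bimod"`).
#' @param labels named character vector (values `"HE"`/`"LE"` or any two
#'   group names) over the cells of `x`.
#' @param min_expressed_fraction detection-fraction threshold (strict
#'   >).
#' @param test `"negbinom"` or `"bimod"`.
#' @return A data.frame (gene, logfc, p_value, p_adjusted, pct_a,
#'   pct_b), sorted by p-value; empty with a warning if no gene passes
#'   the fraction filter.
#' @export
find_markers <- function(x, labels, min_expressed_fraction = 0.25,
                         test = c("bimod", "negbinom")) {
  test <- match.arg(test)
  if (test == "negbinom") {
    stopifnot(inherits(x, "count_matrix"))
    mat <- x$counts
  } else {
    stopifnot(inherits(x, "expression_matrix"))
    mat <- x$normalized
  }
  labels <- labels[colnames(mat)]
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop_ctx("need exactly two groups")
  a <- names(labels)[labels == groups[1]]
  b <- names(labels)[labels == groups[2]]
  if (!length(a) || !length(b)) stop_ctx("both groups must be non-empty")
  pct_a <- rowMeans(mat[, a, drop = FALSE] > 0)
  pct_b <- rowMeans(mat[, b, drop = FALSE] > 0)
  keep <- pct_a > min_expressed_fraction | pct_b > min_expressed_fraction
  if (!any(keep)) {
    warning("no gene passes the expressed-fraction filter", call. = FALSE)
    return(data.frame(gene = character(0), logfc = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0)))
  }
  genes <- rownames(mat)[keep]
  res <- lapply(genes, function(g) {
    va <- mat[g, a]; vb <- mat[g, b]
    r <- if (test == "negbinom") negbinom_lrt(va, vb) else bimod_lrt(va, vb)
    lfc <- if (test == "negbinom")
      log((mean(va) + 0.5) / (mean(vb) + 0.5)) else mean(va) - mean(vb)
    c(lfc = lfc, p = r$p_value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = genes, logfc = res[, "lfc"],
                    p_value = res[, "p"],
                    p_adjusted = bh_fdr(ifelse(is.na(res[, "p"]), 1,
                                               res[, "p"])),
                    pct_a = pct_a[keep], pct_b = pct_b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Random-gene significance control for a clustering
#'
#' Draws `n_genes` genes without replacement `n_resamples` times and
#' counts, per resample, how many are significant between the two
#' groups at `alpha` (raw p). The resulting null distribution is the
#' benchmark against which the mtDNA/OXPHOS marker counts are judged.
#'
#' @param x matrix container as in [find_markers()].
#' @param labels two-group named label vector.
#' @param n_genes genes per resample.
#' @param n_resamples number of resamples.
#' @param alpha significance level applied to raw p-values.
#' @param test `"bimod"` or `"negbinom"`.
#' @param seed integer seed.
#' @return List with `significant_counts` (one per resample), `n_genes`,
#'   `alpha`.
#' @export
random_gene_control <- function(x, labels, n_genes = 100,
                                n_resamples = 1000, alpha = 0.05,
                                test = c("bimod", "negbinom"), seed = 1L) {
  test <- match.arg(test)
  mat <- if (test == "negbinom") x$counts else x$normalized
  if (nrow(mat) < n_genes)
    stop_ctx("need >= ", n_genes, " genes, have ", nrow(mat))
  labels <- labels[colnames(mat)]
  groups <- sort(unique(labels))
  stopifnot(length(groups) == 2)
  a <- names(labels)[labels == groups[1]]
  b <- names(labels)[labels == groups[2]]
  counts <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    gs <- sample(rownames(mat), n_genes)
    ps <- vapply(gs, function(g) {
      r <- if (test == "negbinom") negbinom_lrt(mat[g, a], mat[g, b])
      else bimod_lrt(mat[g, a], mat[g, b])
      r$p_value
    }, numeric(1))
    sum(ps < alpha, na.rm = TRUE)
  }, 0L))
  list(significant_counts = counts, n_genes = n_genes, alpha = alpha,
       n_resamples = n_resamples)
}
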