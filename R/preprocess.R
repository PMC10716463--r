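#' QC thresholds for droplet single-cell data
#'
#' Defaults follow the standard droplet QC rule used for nucleus/cell calling
#' in brain-tumor snRNA-seq: cells with fewer than 2,000 UMI counts, fewer
#' than 200 detected genes, or more than 10% mitochondrial counts are removed.
#' Boundary cells sitting exactly at a threshold are retained ("fewer than"
#' and "more than" are strict).
#'
#' @param min_umi minimum UMI total (inclusive).
#' @param min_genes minimum detected genes (inclusive).
#' @param max_mito_fraction maximum mitochondrial fraction (inclusive).
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(min_umi = 2000, min_genes = 200,
                          max_mito_fraction = 0.10) {
  stopifnot(min_umi > 0, min_genes > 0, max_mito_fraction > 0,
            max_mito_fraction <= 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "QCThresholds")
}

#' Filter cells failing QC
#'
#' Retains exactly the cells with `total >= min_umi`, `n_genes >= min_genes`
#' and `mito_frac <= max_mito_fraction`. Full-length TPM data bypasses
#' filtering with a warning (those cells are taken as quality-passed upstream).
#'
#' @param ds an `ExpressionDataset` (raw droplet counts).
#' @param thr a [qc_thresholds()].
#' @return the filtered `ExpressionDataset` with recomputed `qc_stats`.
#' @export
qc_filter <- function(ds, thr = qc_thresholds()) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(thr, "QCThresholds"))
  if (ds$platform == "full-length-tpm") {
    warning("full-length-tpm data bypasses QC filtering (quality-passed cells)")
    return(ds)
  }
  qc <- ds$qc_stats
  keep <- qc$total >= thr$min_umi & qc$n_genes >= thr$min_genes &
    qc$mito_frac <= thr$max_mito_fraction
  if (!any(keep)) stop("all cells filtered by QC thresholds")
  subset_dataset(ds, cells = keep)
}

#' Normalize expression
#'
#' Droplet counts: per-cell scaling to `scale_factor` total followed by
#' natural-log `log1p`. Full-length TPM: `log2(x + 1)`. Re-normalizing an
#' already-normalized dataset is an error.
#'
#' @param ds an `ExpressionDataset`.
#' @param scale_factor per-cell library-size target for droplet data.
#' @return the normalized `ExpressionDataset` (`normalized = TRUE`).
#' @export
normalize_expression <- function(ds, scale_factor = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$normalized) stop("dataset is already normalized")
  m <- ds$matrix
  if (ds$platform == "droplet-count") {
    tot <- rowSums(m)
    m <- log1p(m / pmax(tot, 1e-12) * scale_factor)
    m[tot == 0, ] <- 0
  } else {
    m <- log2(m + 1)
  }
  ds$matrix <- m
  ds$normalized <- TRUE
  ds
}

# z-score genes (columns) across cells; sd=0 genes map to 0
zscore_genes <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  z <- sweep(m, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  z
}

# top-n highly variable genes of a normalized dataset (by variance)
select_hvgs <- function(ds, n = 2000) {
  v <- apply(ds$matrix, 2, stats::var)
  ds$gene_ids[order(v, decreasing = TRUE)[seq_len(min(n, length(v)))]]
}

# PCA scores (cells x n_pcs) on z-scored selected genes
run_pca <- function(m, n_pcs = 15) {
  n_pcs <- min(n_pcs, nrow(m) - 1, ncol(m))
  if (nrow(m) <= n_pcs) stop("fewer cells than requested principal components")
  p <- stats::prcomp(zscore_genes(m), center = FALSE, scale. = FALSE)
  p$x[, seq_len(n_pcs), drop = FALSE]
}

# shared-nearest-neighbor graph (Jaccard weights) from an embedding
snn_graph <- function(emb, k = 20, prune = 1 / 15) {
  n <- nrow(emb)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(emb))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- 1L
  shared <- adj %*% t(adj)
  union_sz <- 2 * k - shared
  w <- shared / union_sz
  w[w < prune] <- 0
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "max", weighted = TRUE)
}

# community detection on the SNN graph; Leiden (default) or Louvain
cluster_graph <- function(g, resolution, algorithm = c("leiden", "louvain"),
                          seed = 0L) {
  algorithm <- match.arg(algorithm)
  set.seed(seed)
  memb <- if (algorithm == "leiden")
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5))
  else
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  as.integer(memb)
}

#' Single-run graph clustering of a normalized dataset
#'
#' Top variable genes, PCA, shared-nearest-neighbor graph, community
#' detection. This is the first-run building block of [two_run_cluster()] and
#' is also used stand-alone by the lineage-transfer and meta-clustering steps.
#'
#' @param ds a normalized `ExpressionDataset`.
#' @param resolution community-detection resolution.
#' @param n_pcs principal components kept (default 15).
#' @param n_hvg highly variable genes used for PCA.
#' @param k neighbors for the SNN graph.
#' @param genes optional explicit gene set used instead of HVG selection (all
#'   given genes enter PCA).
#' @param algorithm "leiden" (default) or "louvain".
#' @param seed RNG seed for community detection.
#' @return a `ClusterModel`: integer `labels` per cell, `embedding`
#'   (PC scores), `resolution`, `n_pcs`.
#' @export
cluster_cells <- function(ds, resolution = 0.8, n_pcs = 15, n_hvg = 2000,
                          k = 20, genes = NULL,
                          algorithm = c("leiden", "louvain"), seed = 0L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!ds$normalized) stop("cluster_cells expects normalized data")
  use_genes <- genes %||% select_hvgs(ds, n_hvg)
  m <- ds$matrix[, intersect(use_genes, ds$gene_ids), drop = FALSE]
  emb <- run_pca(m, n_pcs)
  labels <- cluster_graph(snn_graph(emb, k = k), resolution,
                          algorithm = match.arg(algorithm), seed = seed)
  structure(list(labels = stats::setNames(labels, ds$cell_ids),
                 embedding = emb, resolution = resolution,
                 n_pcs = ncol(emb), k = k),
            class = "ClusterModel")
}

#' Two-run clustering with mini-cluster contaminant purge
#'
#' First run: coarse clusters via [cluster_cells()] at `resolution_first`,
#' annotated to major cell types with `panel` (highest mean z-scored panel
#' expression). Second run: each coarse type is re-clustered at a very high
#' resolution (`resolution_mini`, default 50) into mini-clusters; a
#' mini-cluster is purged as contaminant when its mean expression of another
#' type's marker panel exceeds that of its own type's panel (cross-panel
#' dominance rule).
#'
#' @param ds normalized `ExpressionDataset`.
#' @param resolution_first coarse resolution.
#' @param resolution_mini mini-cluster resolution (default 50).
#' @param panel named list: cell type -> marker genes; NULL skips annotation
#'   and purging (coarse clustering only).
#' @param ... passed to [cluster_cells()].
#' @return a `ClusterModel` over the retained cells; `labels` are the coarse
#'   type (or cluster id when `panel` is NULL), plus `purged` cell ids.
#' @export
two_run_cluster <- function(ds, resolution_first = 0.3, resolution_mini = 50,
                            panel = NULL, ...) {
  first <- cluster_cells(ds, resolution = resolution_first, ...)
  if (is.null(panel)) {
    first$purged <- character(0)
    return(first)
  }
  type_of_cluster <- annotate_clusters_to_types(ds, first$labels, panel)
  cell_type <- type_of_cluster[as.character(first$labels)]
  names(cell_type) <- ds$cell_ids
  z <- zscore_genes(ds$matrix)
  panel_mean <- vapply(panel, function(gs) {
    gs <- intersect(gs, ds$gene_ids)
    if (!length(gs)) return(rep(NA_real_, nrow(z)))
    rowMeans(z[, gs, drop = FALSE])
  }, numeric(nrow(z)))  # cells x types
  purged <- character(0)
  for (tp in unique(cell_type)) {
    idx <- which(cell_type == tp)
    if (length(idx) < 5) next
    sub <- subset_dataset(ds, cells = idx)
    mini <- tryCatch(
      cluster_cells(sub, resolution = resolution_mini,
                    n_pcs = min(15, length(idx) - 1),
                    k = min(20, length(idx) - 1)),
      error = function(e) NULL)
    if (is.null(mini)) next
    for (mc in unique(mini$labels)) {
      cells_mc <- idx[mini$labels == mc]
      means <- colMeans(panel_mean[cells_mc, , drop = FALSE])
      own <- means[tp]
      if (any(means[setdiff(names(means), tp)] > own, na.rm = TRUE))
        purged <- c(purged, ds$cell_ids[cells_mc])
    }
  }
  keep <- !(ds$cell_ids %in% purged)
  structure(list(labels = cell_type[keep],
                 embedding = first$embedding[keep, , drop = FALSE],
                 resolution = resolution_first, n_pcs = first$n_pcs,
                 purged = purged),
            class = "ClusterModel")
}

# per-cluster type assignment: highest mean z-scored panel expression;
# ties -> larger panel coverage, then lexicographic type name
annotate_clusters_to_types <- function(ds, labels, panel) {
  z <- zscore_genes(ds$matrix)
  coverage <- vapply(panel, function(gs)
    length(intersect(gs, ds$gene_ids)), integer(1))
  out <- character(0)
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    score <- vapply(panel, function(gs) {
      gs <- intersect(gs, ds$gene_ids)
      if (!length(gs)) return(-Inf)
      mean(z[in_cl, gs, drop = FALSE])
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1) best <- best[order(-coverage[best],
                                             names(score)[best])][1]
    out[as.character(cl)] <- names(score)[best]
  }
  out
}

#' Cluster-based annotation of cells
#'
#' Assigns every cell the type of its cluster, where each cluster gets the
#' type whose marker panel has the highest mean z-scored expression in that
#' cluster (ties: larger panel coverage, then lexicographic).
#'
#' @param model a `ClusterModel` over `ds`.
#' @param panel named list: cell type -> marker genes (each non-empty).
#' @param ds the normalized `ExpressionDataset` the model was fit on.
#' @return named character vector of per-cell type labels.
#' @export
annotate_cluster_based <- function(model, panel, ds) {
  stopifnot(inherits(model, "ClusterModel"))
  if (any(lengths(panel) == 0)) stop("empty marker panel")
  cells <- names(model$labels)
  ds2 <- subset_dataset(ds, cells = match(cells, ds$cell_ids))
  map <- annotate_clusters_to_types(ds2, model$labels, panel)
  stats::setNames(map[as.character(model$labels)], cells)
}

#' Positive-selection annotation from a single marker
#'
#' A cell is labeled positive for the type iff its marker expression exceeds
#' the dataset-wide mean of that marker.
#'
#' @param ds normalized `ExpressionDataset`.
#' @param marker single gene id.
#' @return named logical vector (TRUE = positive).
#' @export
annotate_positive_selection <- function(ds, marker) {
  if (!marker %in% ds$gene_ids) stop("marker gene absent: ", marker)
  x <- ds$matrix[, marker]
  stats::setNames(x > mean(x), ds$cell_ids)
}

#' Compare cluster-based vs positive-selection annotation
#'
#' For each cell type: number of cells called, mean expression of the type's
#' markers in the called cells, and mean marker-pathway enrichment score
#' ([sample_set_score()] of the panel) — under both methods. Positive
#' selection uses the first marker of each panel.
#'
#' @param ds normalized `ExpressionDataset`.
#' @param panel named list: cell type -> marker genes.
#' @param model optional precomputed `ClusterModel`; fitted at resolution 0.3
#'   when absent.
#' @return data.frame(method, cell_type, n_cells, mean_marker_expr,
#'   mean_pathway_score).
#' @export
compare_annotation_methods <- function(ds, panel, model = NULL) {
  model <- model %||% cluster_cells(ds, resolution = 0.3)
  cb <- annotate_cluster_based(model, panel, ds)
  rows <- list()
  for (tp in names(panel)) {
    gs <- intersect(panel[[tp]], ds$gene_ids)
    path_score <- sample_set_score(ds, gs)
    for (method in c("cluster_based", "positive_selection")) {
      cells <- if (method == "cluster_based") names(cb)[cb == tp]
        else {
          pos <- annotate_positive_selection(ds, panel[[tp]][1])
          names(pos)[pos]
        }
      idx <- match(cells, ds$cell_ids)
      rows[[paste(method, tp)]] <- data.frame(
        method = method, cell_type = tp, n_cells = length(cells),
        mean_marker_expr = if (length(cells))
          mean(ds$matrix[idx, gs, drop = FALSE]) else NA_real_,
        mean_pathway_score = if (length(cells))
          mean(path_score[idx]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
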