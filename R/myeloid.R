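#' Davies-Bouldin index
#'
#' Centroid-based, Euclidean: per-cluster scatter S_i is the mean distance of
#' points to their centroid; the index is the mean over clusters of
#' max_{j != i} (S_i + S_j) / d(c_i, c_j). Lower is better. Requires >= 2
#' clusters.
#'
#' @param x points x dims numeric matrix.
#' @param labels per-point cluster labels.
#' @return the DBI (numeric scalar).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("DBI undefined for a single cluster")
  cent <- t(vapply(cl, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
  s <- vapply(seq_along(cl), function(i) {
    pts <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(cent))
  r <- vapply(seq_along(cl), function(i) {
    max(vapply(setdiff(seq_along(cl), i), function(j)
      (s[i] + s[j]) / m[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Cross-dataset informative-gene ranking
#'
#' Five-step informative-gene selection across datasets: per dataset, a
#' one-way ANOVA of each gene's (normalized) expression across that dataset's
#' clusters yields an F value; F values are converted to within-dataset
#' percentile ranks (largest F maps to 1.0); per gene the median percentile
#' across datasets where the gene is detected is taken; ribosomal,
#' cell-cycle and heat-shock families are excluded; the final set is the top
#' `n_top` genes by median percentile among genes detected in more than half
#' of the datasets. A dataset with a single cluster (F undefined) is skipped
#' with a warning.
#'
#' @param datasets list of normalized `ExpressionDataset`s.
#' @param labels optional list of per-dataset cluster labels; defaults to
#'   each dataset's `cell_label`.
#' @param exclusion_lists named list of gene families to exclude (defaults to
#'   the universe's ribosomal / cell-cycle / heat-shock families).
#' @param n_top maximum size of the informative set (default 2000).
#' @param rank_direction "largest_F" (default: highest-F genes selected) or
#'   "smallest_F" (the opposite reading of the ascending-median ordering).
#' @return an `InformativeGeneRanking`: `table` (gene, median_rank,
#'   n_detected) and `informative` (character vector, length <= n_top).
#' @export
rank_informative_genes <- function(datasets, labels = NULL,
                                   exclusion_lists = NULL, n_top = 2000,
                                   rank_direction = c("largest_F",
                                                      "smallest_F")) {
  rank_direction <- match.arg(rank_direction)
  if (is.null(exclusion_lists)) {
    fam <- gene_universe(0)$families
    exclusion_lists <- fam[c("ribosomal", "cell_cycle", "heat_shock")]
  }
  labels <- labels %||% lapply(datasets, function(d) d$cell_label)
  n_ds <- length(datasets)
  ranks <- list(); detected <- list()
  used <- 0
  for (i in seq_len(n_ds)) {
    d <- datasets[[i]]; lb <- labels[[i]]
    if (length(unique(lb)) < 2) {
      warning("dataset ", i, " has a single cluster; skipped (F undefined)")
      next
    }
    used <- used + 1
    det <- colSums(d$matrix > 0) > 0
    f <- anova_f(d$matrix, lb)
    f[!det] <- NA
    pr <- rank(f, ties.method = "average", na.last = "keep") / sum(det)
    ranks[[length(ranks) + 1]] <- stats::setNames(pr, d$gene_ids)
    detected[[length(detected) + 1]] <-
      stats::setNames(det, d$gene_ids)
  }
  if (!used) stop("no dataset with >= 2 clusters")
  all_genes <- unique(unlist(lapply(ranks, names)))
  rk <- vapply(ranks, function(r) r[all_genes], numeric(length(all_genes)))
  dt <- vapply(detected, function(r) {
    v <- r[all_genes]; v[is.na(v)] <- FALSE; v
  }, logical(length(all_genes)))
  med <- apply(as.matrix(rk), 1, stats::median, na.rm = TRUE)
  n_det <- rowSums(as.matrix(dt))
  tab <- data.frame(gene = all_genes, median_rank = med, n_detected = n_det,
                    row.names = NULL)
  excl <- unique(unlist(exclusion_lists, use.names = FALSE))
  elig <- tab[!(tab$gene %in% excl) & tab$n_detected > floor(n_ds / 2) &
              !is.na(tab$median_rank), , drop = FALSE]
  ord <- if (rank_direction == "largest_F")
    order(-elig$median_rank) else order(elig$median_rank)
  informative <- elig$gene[ord][seq_len(min(n_top, nrow(elig)))]
  structure(list(table = tab, informative = informative, n_top = n_top,
                 exclusion = excl, rank_direction = rank_direction),
            class = "InformativeGeneRanking")
}

# vectorized one-way ANOVA F per gene (columns of m), grouping by `labels`;
# constant genes get F = 0
anova_f <- function(m, labels) {
  labels <- as.factor(labels)
  n <- nrow(m); k <- nlevels(labels)
  grand <- colMeans(m)
  ssb <- 0; ssw <- 0
  for (lv in levels(labels)) {
    idx <- labels == lv
    mu <- colMeans(m[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (mu - grand)^2
    ssw <- ssw + colSums(sweep(m[idx, , drop = FALSE], 2, mu)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  f
}

#' DBI-driven cluster-number selection
#'
#' Restricts PCA to the informative genes, clusters at every resolution of
#' the grid, computes the Davies-Bouldin index in PC space per resolution,
#' and returns the model at the DBI minimum. Resolutions yielding a single
#' cluster are recorded with DBI = NA and cannot be selected.
#'
#' @param ds normalized `ExpressionDataset`, or cells x genes matrix.
#' @param informative informative gene set (used as the HVG set for PCA).
#' @param resolutions resolution grid (default seq(0.1, 2, by = 0.1)).
#' @param n_pcs,k PCA / SNN parameters.
#' @param seed RNG seed for community detection.
#' @return list with `trace` (a `DBITrace` data.frame: resolution, k, dbi),
#'   `model` (the selected `ClusterModel`), `selected_resolution`,
#'   `selected_k`.
#' @export
select_cluster_number <- function(ds, informative,
                                  resolutions = seq(0.1, 2, by = 0.1),
                                  n_pcs = 15, k = 20, seed = 0L) {
  if (!inherits(ds, "ExpressionDataset")) {
    m <- as.matrix(ds)
    ds <- expression_dataset(pmax(m, 0), gene_ids = colnames(m),
                             cell_ids = rownames(m) %||%
                               sprintf("c%05d", seq_len(nrow(m))),
                             platform = "full-length-tpm", normalized = TRUE)
  }
  genes <- intersect(informative, ds$gene_ids)
  emb <- run_pca(ds$matrix[, genes, drop = FALSE],
                 min(n_pcs, length(genes) - 1))
  g <- snn_graph(emb, k = min(k, nrow(emb) - 1))
  trace <- data.frame(resolution = resolutions, k = NA_integer_,
                      dbi = NA_real_)
  models <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    lab <- cluster_graph(g, resolutions[i], seed = seed)
    trace$k[i] <- length(unique(lab))
    if (trace$k[i] >= 2) trace$dbi[i] <- davies_bouldin(emb, lab)
    models[[i]] <- lab
  }
  if (all(is.na(trace$dbi)))
    stop("no resolution produced >= 2 clusters; DBI undefined everywhere")
  best <- which.min(trace$dbi)
  model <- structure(list(labels = stats::setNames(models[[best]],
                                                   ds$cell_ids),
                          embedding = emb,
                          resolution = resolutions[best], n_pcs = ncol(emb)),
                     class = "ClusterModel")
  class(trace) <- c("DBITrace", "data.frame")
  list(trace = trace, model = model,
       selected_resolution = resolutions[best], selected_k = trace$k[best])
}

#' Per-dataset z-scored concatenation on shared genes
#'
#' The integration stand-in used before meta-clustering: each dataset's
#' normalized matrix is gene-z-scored within the dataset, matrices are then
#' row-bound on the shared gene space.
#'
#' @param datasets list of normalized `ExpressionDataset`s.
#' @return cells x shared-genes matrix with dataset-prefixed cell ids.
#' @export
combine_zscore <- function(datasets) {
  shared <- Reduce(intersect, lapply(datasets, function(d) d$gene_ids))
  blocks <- lapply(datasets, function(d)
    zscore_genes(d$matrix[, shared, drop = FALSE]))
  do.call(rbind, blocks)
}

#' Per-cluster mean profiles of z-scored expression
#'
#' Genes are z-scored across cells, then averaged per cluster.
#'
#' @param ds normalized `ExpressionDataset`.
#' @param labels per-cell cluster labels.
#' @param prefix prefix for the output column names (e.g. tumor type).
#' @return genes x clusters matrix, columns named `<prefix>.<cluster>`.
#' @export
cluster_mean_profiles <- function(ds, labels, prefix = ds$tumor_type) {
  z <- zscore_genes(ds$matrix)
  cl <- sort(unique(labels))
  out <- vapply(cl, function(k)
    colMeans(z[labels == k, , drop = FALSE]), numeric(ncol(z)))
  colnames(out) <- paste(prefix, cl, sep = ".")
  rownames(out) <- ds$gene_ids
  out
}

#' Cross-tumor cluster-similarity dendrogram
#'
#' Column-binds per-tumor-type cluster mean profiles on the genes present in
#' all inputs and hierarchically clusters the columns with 1 - Pearson
#' correlation distance and average linkage.
#'
#' @param profiles named list of genes x clusters matrices (one per tumor
#'   type, e.g. from [cluster_mean_profiles()]).
#' @param method linkage method (default "average").
#' @return an `hclust` tree over all clusters (leaf per cluster).
#' @export
cluster_similarity_dendrogram <- function(profiles, method = "average") {
  shared <- Reduce(intersect, lapply(profiles, rownames))
  if (length(shared) < 3) stop("too few genes shared across all inputs")
  comb <- do.call(cbind, lapply(profiles, function(p)
    p[shared, , drop = FALSE]))
  d <- stats::as.dist(1 - stats::cor(comb, method = "pearson"))
  stats::hclust(d, method = method)
}
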