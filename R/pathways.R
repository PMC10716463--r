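#' One-vs-rest marker genes per cluster (Wilcoxon rank-sum)
#'
#' For every cluster and gene: Wilcoxon rank-sum p (in-cluster vs rest),
#' BH-adjusted within cluster, log fold change defined as the natural log of
#' (mean expm1 normalized expression + 1) in-cluster over out-cluster (the
#' dominant single-cell convention), and detection fractions pct_in / pct_out.
#' Threshold filters are strict inequalities.
#'
#' @param ds normalized `ExpressionDataset`, or a cells x genes matrix.
#' @param labels per-cell group labels (defaults to `ds$cell_label`).
#' @param logfc_min,p_adj_max,min_pct strict filter thresholds; set
#'   `filter = FALSE` to return the full table.
#' @param groups restrict to these clusters (default: all).
#' @param filter apply the threshold triple (default TRUE).
#' @return a `MarkerTable` data.frame: cluster, gene, logFC, pct_in, pct_out,
#'   p, p_adj.
#' @export
find_markers <- function(ds, labels = NULL, logfc_min = 0.25,
                         p_adj_max = 0.01, min_pct = 0.1, groups = NULL,
                         filter = TRUE) {
  m <- if (inherits(ds, "ExpressionDataset")) ds$matrix else as.matrix(ds)
  labels <- labels %||% ds$cell_label
  stopifnot(length(labels) == nrow(m))
  groups <- groups %||% sort(unique(labels))
  rows <- list()
  for (cl in groups) {
    inside <- labels == cl
    if (!any(inside) || all(inside)) next
    min_g <- m[inside, , drop = FALSE]
    mout_g <- m[!inside, , drop = FALSE]
    mu_in <- colMeans(expm1(min_g))
    mu_out <- colMeans(expm1(mout_g))
    logfc <- log((mu_in + 1) / (mu_out + 1))
    pct_in <- colMeans(min_g > 0)
    pct_out <- colMeans(mout_g > 0)
    p <- vapply(seq_len(ncol(m)), function(g) {
      xi <- min_g[, g]; xo <- mout_g[, g]
      if (all(xi == xi[1]) && all(xo == xi[1])) return(1)
      # exact when sizes permit and no ties; normal approximation otherwise
      suppressWarnings(stats::wilcox.test(xi, xo)$p.value)
    }, numeric(1))
    rows[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = colnames(m), logFC = logfc,
      pct_in = pct_in, pct_out = pct_out, p = p,
      p_adj = bh_adjust(p), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (filter && !is.null(out))
    out <- out[out$logFC > logfc_min & out$p_adj < p_adj_max &
               out$pct_in > min_pct, , drop = FALSE]
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test of marker/set overlap against a
#' gene universe, BH-adjusted across sets. The enrichment score used for
#' ranking pathways is -log10(q).
#'
#' @param markers character vector of query genes.
#' @param collection `GeneSetCollection` (or named list of gene vectors).
#' @param universe background gene universe.
#' @return data.frame: set, overlap, set_size, n_markers, p, q, score.
#' @export
hypergeometric_enrichment <- function(markers, collection, universe) {
  markers <- intersect(unique(markers), universe)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    k <- length(intersect(markers, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(markers), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               n_markers = length(markers), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$score <- -log10(pmax(out$q, .Machine$double.xmin))
  out
}

# core ssGSEA-style statistic for one sample (vector of expression x over all
# genes): weighted Kolmogorov-Smirnov running-sum, weight = rank^alpha,
# centered by its expectation under random set placement so random sets score
# ~0, and scaled by 1/N.
ssgsea_one <- function(x, in_set, alpha = 0.25) {
  N <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  w <- r[ord]^alpha
  in_ord <- in_set[ord]
  n_in <- sum(in_set)
  # member running-sum normalized by its EXPECTED mass (n_in * mean weight)
  # rather than the realized set mass: the statistic is then linear in the
  # membership indicators and exactly mean-zero under random set placement
  # once the analytic null expectation below is subtracted
  cdf_in <- cumsum(w * in_ord) / (n_in * mean(w))
  cdf_out <- cumsum(!in_ord) / (N - n_in)
  es <- sum(cdf_in - cdf_out)
  e_null <- sum(cumsum(w) / sum(w) - seq_len(N) / N)
  (es - e_null) / N
}

#' Single-sample gene-set score (rank-based running sum)
#'
#' Per cell (or sample) the genes are ranked by expression and a weighted
#' Kolmogorov-Smirnov running-sum statistic (weight exponent `alpha` = 0.25)
#' is accumulated over the ranking; the score is centered by its expectation
#' under random set placement, so random sets score approximately zero. The
#' score depends only on within-cell ranks and is therefore invariant to any
#' monotone per-cell transform of expression.
#'
#' @param ds `ExpressionDataset` (cells x genes) or a genes x samples matrix.
#' @param set character vector of set member genes.
#' @param alpha rank-weight exponent.
#' @return named numeric vector of per-cell/per-sample scores.
#' @export
sample_set_score <- function(ds, set, alpha = 0.25) {
  if (inherits(ds, "ExpressionDataset")) {
    m <- t(ds$matrix)  # genes x cells
  } else m <- as.matrix(ds)
  in_set <- rownames(m) %in% set
  if (!any(in_set)) stop("no set members present in the matrix")
  if (all(in_set)) stop("set covers the whole gene universe")
  apply(m, 2, ssgsea_one, in_set = in_set, alpha = alpha)
}

#' Differential pathway activity per cluster
#'
#' One-vs-rest moderated t-tests on a sets x cells pathway-score matrix via
#' limma's empirical-Bayes machinery (`use_limma = TRUE`, default) or plain
#' Welch t-tests. `logFC` is the in-cluster minus out-cluster mean score.
#'
#' @param scores sets x cells numeric matrix (e.g. from
#'   [sample_set_score()] stacked over sets).
#' @param labels per-cell cluster labels.
#' @param logfc_min,p_adj_max strict filter thresholds (defaults 0 / 0.05).
#' @param use_limma moderated t (TRUE) or Welch t (FALSE).
#' @param filter apply thresholds (default TRUE).
#' @return data.frame: cluster, set, logFC, p, p_adj.
#' @export
differential_pathways <- function(scores, labels, logfc_min = 0,
                                  p_adj_max = 0.05, use_limma = TRUE,
                                  filter = TRUE) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == length(labels))
  rows <- list()
  for (cl in sort(unique(labels))) {
    inside <- labels == cl
    if (use_limma) {
      design <- cbind(Intercept = 1, inside = as.numeric(inside))
      fit <- limma::eBayes(limma::lmFit(scores, design))
      tt <- limma::topTable(fit, coef = "inside", number = Inf,
                            sort.by = "none")
      df <- data.frame(cluster = cl, set = rownames(scores),
                       logFC = tt$logFC, p = tt$P.Value,
                       p_adj = bh_adjust(tt$P.Value))
    } else {
      res <- t(apply(scores, 1, function(s) {
        ht <- stats::t.test(s[inside], s[!inside])
        c(lfc = mean(s[inside]) - mean(s[!inside]), p = ht$p.value)
      }))
      df <- data.frame(cluster = cl, set = rownames(scores),
                       logFC = res[, "lfc"], p = res[, "p"],
                       p_adj = bh_adjust(res[, "p"]))
    }
    rows[[as.character(cl)]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (filter) out <- out[out$logFC > logfc_min & out$p_adj < p_adj_max, ,
                         drop = FALSE]
  out
}

#' Marker-pathway determination for a cluster
#'
#' Intersects the cluster's enriched pathways (hypergeometric q below
#' `enrich_q_max`) with its differentially active pathways, ranks the
#' intersection by enrichment score (-log10 q; ties broken by smaller set
#' size then lexicographic name), and calls the first pathway containing at
#' least one of the cluster's top-10 markers by logFC. The called marker gene
#' is the pathway member with maximal logFC among the cluster's markers.
#' When no intersected pathway contains a top-10 marker, an explicit no-call
#' is returned.
#'
#' @param cluster cluster id.
#' @param enrichment output of [hypergeometric_enrichment()] for this
#'   cluster's markers.
#' @param differential output of [differential_pathways()] (filtered).
#' @param markers `MarkerTable` (filtered) for all clusters.
#' @param collection the `GeneSetCollection` (to test marker membership).
#' @param enrich_q_max enrichment significance cutoff.
#' @return a `MarkerPathwayCall` list: cluster, pathway (NA when no call),
#'   q, score, marker_gene, called (logical).
#' @export
marker_pathway <- function(cluster, enrichment, differential, markers,
                           collection, enrich_q_max = 0.05) {
  mk <- markers[markers$cluster == cluster, , drop = FALSE]
  mk <- mk[order(-mk$logFC), , drop = FALSE]
  top10 <- utils::head(mk$gene, 10)
  enriched <- enrichment[enrichment$q < enrich_q_max, , drop = FALSE]
  diff_sets <- differential$set[differential$cluster == cluster]
  cand <- enriched[enriched$set %in% diff_sets, , drop = FALSE]
  no_call <- list(cluster = cluster, pathway = NA_character_, q = NA_real_,
                  score = NA_real_, marker_gene = NA_character_,
                  called = FALSE)
  class(no_call) <- "MarkerPathwayCall"
  if (!nrow(cand)) return(no_call)
  cand <- cand[order(-cand$score, cand$set_size, cand$set), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    members <- collection[[cand$set[i]]]
    if (any(top10 %in% members)) {
      in_path <- mk[mk$gene %in% members, , drop = FALSE]
      out <- list(cluster = cluster, pathway = cand$set[i], q = cand$q[i],
                  score = cand$score[i],
                  marker_gene = in_path$gene[which.max(in_path$logFC)],
                  called = TRUE)
      class(out) <- "MarkerPathwayCall"
      return(out)
    }
  }
  no_call
}

#' Two-axis polarization scores per cluster
#'
#' Mean single-sample set score of two signature axes (e.g. M1 vs M2, or
#' angiogenic vs phagocytic) per cluster; butterfly-plot-ready.
#'
#' @param ds normalized `ExpressionDataset`.
#' @param labels per-cell cluster labels.
#' @param set1,set2 the two signature gene sets.
#' @param axis_names column names for the two axes.
#' @return data.frame: cluster, n_cells, <axis1>, <axis2>.
#' @export
polarization_scores <- function(ds, labels, set1, set2,
                                axis_names = c("axis1", "axis2")) {
  s1 <- sample_set_score(ds, set1)
  s2 <- sample_set_score(ds, set2)
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    data.frame(cluster = cl, n_cells = sum(idx),
               a1 = mean(s1[idx]), a2 = mean(s2[idx]))
  }))
  names(out)[3:4] <- axis_names
  out
}
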