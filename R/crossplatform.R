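#' Label a full-length reference dataset as MG / BMDM
#'
#' Clusters the (normalized) full-length dataset at the given resolution and
#' assigns each cluster microglia (MG) or bone-marrow-derived macrophage
#' (BMDM) by the higher mean z-scored expression of the respective marker
#' set. A cluster whose two marker-set means tie is labeled "ambiguous" and
#' later excluded from classifier training.
#'
#' @param ds normalized full-length `ExpressionDataset`.
#' @param mg_markers,bmdm_markers marker gene sets.
#' @param resolution clustering resolution (default 0.3).
#' @param ... passed to [cluster_cells()].
#' @return the dataset with `cell_label` set to "MG"/"BMDM"/"ambiguous".
#' @export
label_reference <- function(ds, mg_markers, bmdm_markers, resolution = 0.3,
                            ...) {
  model <- cluster_cells(ds, resolution = resolution, ...)
  z <- zscore_genes(ds$matrix)
  score_set <- function(cells, gs) {
    gs <- intersect(gs, ds$gene_ids)
    mean(z[cells, gs, drop = FALSE])
  }
  lab <- character(length(ds$cell_ids))
  for (cl in unique(model$labels)) {
    idx <- which(model$labels == cl)
    mg <- score_set(idx, mg_markers)
    bm <- score_set(idx, bmdm_markers)
    lab[idx] <- if (mg > bm) "MG" else if (bm > mg) "BMDM" else "ambiguous"
  }
  ds$cell_label <- lab
  ds
}

#' Train a random-forest MG/BMDM lineage classifier
#'
#' Trains a forest (500 trees, sqrt(p) features per split — the randomForest
#' defaults) on the normalized expression of MG/BMDM-labeled cells pooled
#' across the reference datasets, on the inner-join gene space.
#'
#' Features are z-scored per gene within each dataset before pooling, and
#' [predict_lineage()] applies the same within-dataset standardization — the
#' harmonization that lets a forest trained on full-length TPM data transfer
#' to droplet counts despite the platforms' different expression scales.
#'
#' @param datasets list of labeled, normalized `ExpressionDataset`s.
#' @param feature_genes optional explicit feature gene list; defaults to the
#'   inner join of all datasets' genes.
#' @param ntree number of trees (default 500).
#' @return a `LineageClassifier`: forest, feature_genes, classes, oob_error,
#'   training source names.
#' @export
train_lineage_classifier <- function(datasets, feature_genes = NULL,
                                     ntree = 500) {
  shared <- Reduce(intersect, lapply(datasets, function(d) d$gene_ids))
  if (!is.null(feature_genes)) {
    missing <- setdiff(feature_genes, shared)
    if (length(missing))
      warning("feature genes absent from some training dataset, dropped: ",
              paste(missing, collapse = ", "))
    shared <- intersect(feature_genes, shared)
  }
  xs <- list(); ys <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    keep <- d$cell_label %in% c("MG", "BMDM")
    xs[[i]] <- zscore_genes(d$matrix[, shared, drop = FALSE])[keep, ,
                                                              drop = FALSE]
    ys[[i]] <- d$cell_label[keep]
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = c("MG", "BMDM"))
  if (nlevels(droplevels(y)) < 2) stop("single-class training data")
  colnames(x) <- make.names(shared)  # forest-safe names; originals kept below
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    proximity = TRUE)
  structure(list(forest = fit, feature_genes = shared,
                 classes = levels(y),
                 oob_error = mean(fit$err.rate[ntree, "OOB"]),
                 sources = names(datasets) %||% seq_along(datasets)),
            class = "LineageClassifier")
}

#' Predict MG/BMDM lineage on a droplet dataset
#'
#' Every cell receives the argmax class; exact probability ties are labeled
#' "ambiguous". A droplet dataset missing any classifier feature gene is an
#' error naming the genes.
#'
#' @param clf a `LineageClassifier`.
#' @param ds normalized droplet `ExpressionDataset`.
#' @return list with `labels` (named character) and `prob` (cells x classes).
#' @export
predict_lineage <- function(clf, ds) {
  missing <- setdiff(clf$feature_genes, ds$gene_ids)
  if (length(missing))
    stop("dataset is missing classifier feature gene(s): ",
         paste(missing, collapse = ", "))
  x <- zscore_genes(ds$matrix[, clf$feature_genes, drop = FALSE])
  colnames(x) <- make.names(clf$feature_genes)
  prob <- stats::predict(clf$forest, x, type = "prob")
  lab <- clf$classes[max.col(prob, ties.method = "first")]
  lab[prob[, 1] == prob[, 2]] <- "ambiguous"
  list(labels = stats::setNames(lab, ds$cell_ids), prob = prob)
}

#' Conserved MG/BMDM differential genes across tumor types
#'
#' Runs per-type MG-vs-BMDM marker detection ([find_markers()]) and keeps the
#' direction-consistent intersection: genes up in MG (resp. BMDM) at
#' logFC > `logfc_min` and adjusted p < `p_adj_max` in every tumor type.
#'
#' @param datasets named list of labeled (MG/BMDM), normalized datasets, one
#'   per tumor type.
#' @param logfc_min,p_adj_max thresholds (defaults 0.25 / 0.01).
#' @return a `ConservedDEGSet`: `up_mg`, `up_bmdm` (disjoint), and the
#'   per-source marker tables.
#' @export
conserved_degs <- function(datasets, logfc_min = 0.25, p_adj_max = 0.01) {
  per_source <- lapply(datasets, function(d) {
    keep <- d$cell_label %in% c("MG", "BMDM")
    sub <- subset_dataset(d, cells = keep)
    find_markers(sub, labels = sub$cell_label, logfc_min = logfc_min,
                 p_adj_max = p_adj_max, min_pct = 0)
  })
  up <- function(tb, cl) tb$gene[tb$cluster == cl]
  up_mg <- Reduce(intersect, lapply(per_source, up, cl = "MG"))
  up_bmdm <- Reduce(intersect, lapply(per_source, up, cl = "BMDM"))
  structure(list(up_mg = sort(up_mg), up_bmdm = sort(up_bmdm),
                 per_source = per_source),
            class = "ConservedDEGSet")
}

#' Recluster a droplet dataset on the conserved DEG space
#'
#' Subsets the matrix to the conserved DEGs, runs PCA on all of them (they
#' act as the HVG set), clusters at `resolution` (default 0.2), and annotates
#' each cluster MG or BMDM by majority vote of the per-cell classifier
#' predictions.
#'
#' @param ds normalized droplet `ExpressionDataset`.
#' @param conserved a `ConservedDEGSet`.
#' @param clf a `LineageClassifier` for the annotation vote.
#' @param resolution clustering resolution (default 0.2).
#' @param ... passed to [cluster_cells()].
#' @return a `ClusterModel` with per-cell MG/BMDM labels in `lineage`.
#' @export
recluster_on_conserved <- function(ds, conserved, clf, resolution = 0.2,
                                   ...) {
  genes <- intersect(c(conserved$up_mg, conserved$up_bmdm), ds$gene_ids)
  if (length(genes) < 3) stop("too few conserved DEGs present in dataset")
  model <- cluster_cells(ds, resolution = resolution, genes = genes,
                         n_pcs = min(15, length(genes) - 1), ...)
  pred <- predict_lineage(clf, ds)
  lineage <- character(length(model$labels))
  for (cl in unique(model$labels)) {
    idx <- model$labels == cl
    votes <- table(pred$labels[idx])
    votes <- votes[names(votes) != "ambiguous"]
    lineage[idx] <- if (length(votes)) names(votes)[which.max(votes)]
                    else "ambiguous"
  }
  model$lineage <- stats::setNames(lineage, names(model$labels))
  model
}

#' Classical MDS embedding of the forest proximity matrix
#'
#' Mirrors the evaluation of the lineage classifier by classical
#' multidimensional scaling of the out-of-bag proximity matrix.
#'
#' @param clf a `LineageClassifier` trained with proximity = TRUE.
#' @param k embedding dimension.
#' @return matrix of MDS coordinates (training cells x k).
#' @export
classifier_mds <- function(clf, k = 2) {
  if (is.null(clf$forest$proximity)) stop("forest trained without proximity")
  stats::cmdscale(1 - clf$forest$proximity, k = k)
}
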