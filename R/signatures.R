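#' Platform- and stringency-specific marker thresholds for scFes
#'
#' Rigorous thresholds for common cell types, looser for subpopulations of
#' major types; both differ by platform. The adjusted-p cutoffs are config
#' values (the "10e-20"-style notation of the source pipelines is read as
#' 1e-20 / 1e-10 by default).
#'
#' @param platform "droplet-count" or "full-length-tpm".
#' @param stringency "common" or "subpopulation".
#' @return list(p_adj_max, min_pct, logfc_min).
#' @export
scfes_thresholds <- function(platform, stringency = c("common",
                                                      "subpopulation")) {
  stringency <- match.arg(stringency)
  if (platform == "full-length-tpm") {
    if (stringency == "common")
      list(p_adj_max = 1e-20, min_pct = 0.3, logfc_min = 1)
    else list(p_adj_max = 1e-10, min_pct = 0.3, logfc_min = 1)
  } else {
    list(p_adj_max = 1e-10, min_pct = 0.1, logfc_min = 0.25)
  }
}

#' Derive a single-cell gene feature (scFes) for a cell type
#'
#' Per labeled dataset, one-vs-rest markers of `cell_type` are found with the
#' platform- and stringency-specific threshold triple; the per-dataset sets
#' are then combined by the stringency's rule: intersection over all datasets
#' ("common"/"subpopulation"), a three-quarters quorum ("quorum-3/4", used
#' for cytotoxic CD8 T cells), or — for tumor features ("tumor-conserved") —
#' genes passing the common-type thresholds in at least two tumor types.
#'
#' @param datasets named list of labeled, normalized `ExpressionDataset`s.
#' @param cell_type the `cell_label` value to derive the feature for.
#' @param stringency one of "common", "subpopulation", "quorum-3/4",
#'   "tumor-conserved".
#' @param name signature name (defaults to the cell type).
#' @return a `SignatureSet`: name, cell_type, genes, stringency, provenance
#'   (per-dataset passing sets and thresholds used).
#' @export
derive_scfes <- function(datasets, cell_type,
                         stringency = c("common", "subpopulation",
                                        "quorum-3/4", "tumor-conserved"),
                         name = cell_type) {
  stringency <- match.arg(stringency)
  thr_str <- if (stringency == "subpopulation") "subpopulation" else "common"
  has_type <- vapply(datasets, function(d)
    cell_type %in% d$cell_label, logical(1))
  if (stringency %in% c("common", "subpopulation") && !all(has_type))
    stop("cell_type '", cell_type, "' absent from dataset(s): ",
         paste(names(datasets)[!has_type], collapse = ", "))
  use <- datasets[has_type]
  per_set <- lapply(use, function(d) {
    thr <- scfes_thresholds(d$platform, thr_str)
    mk <- find_markers(d, labels = d$cell_label, groups = cell_type,
                       logfc_min = thr$logfc_min, p_adj_max = thr$p_adj_max,
                       min_pct = thr$min_pct)
    mk$gene
  })
  genes <- switch(stringency,
    common = ,
    subpopulation = Reduce(intersect, per_set),
    `quorum-3/4` = {
      cnt <- table(unlist(per_set))
      names(cnt)[cnt >= ceiling(3 / 4 * length(per_set))]
    },
    `tumor-conserved` = {
      types <- vapply(use, function(d) d$tumor_type, character(1))
      by_type <- lapply(split(per_set, types), function(sets)
        unique(unlist(sets)))
      cnt <- table(unlist(by_type))
      names(cnt)[cnt >= 2]
    })
  genes <- sort(unname(genes))
  if (!length(genes)) stop("no gene passes the '", stringency,
                           "' rule for ", cell_type)
  structure(list(name = name, cell_type = cell_type, genes = genes,
                 stringency = stringency,
                 provenance = list(per_dataset = per_set,
                                   datasets = names(use),
                                   thresholds = thr_str)),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet '%s' (%s, %s): %d genes\n", x$name,
              x$cell_type, x$stringency, length(x$genes)))
  invisible(x)
}

#' Derive tumor immune-recruitment gene features
#'
#' Spearman correlation of every tumor-expressed gene with per-sample immune
#' content across the tumor-cell pseudobulk: positive-IR genes have
#' rho > `rho_min` and BH q < `q_max`; negative-IR genes symmetrically with
#' rho < -`rho_min`. The two lists are disjoint by construction.
#'
#' @param pseudobulk genes x samples matrix (log2) of tumor-component
#'   pseudobulk expression.
#' @param immune_content per-sample immune content proxy (e.g. mean
#'   normalized PTPRC/CD45, or the planted immune fraction).
#' @param rho_min,q_max thresholds (defaults 0.5 / 0.1).
#' @return an `IRFeatures`: `positive`, `negative` gene lists and the
#'   per-gene correlation table.
#' @export
derive_ir_features <- function(pseudobulk, immune_content, rho_min = 0.5,
                               q_max = 0.1) {
  pseudobulk <- as.matrix(pseudobulk)
  if (ncol(pseudobulk) < 8) stop("need >= 8 samples")
  stopifnot(ncol(pseudobulk) == length(immune_content))
  res <- t(apply(pseudobulk, 1, function(x) {
    if (stats::sd(x) == 0) return(c(rho = 0, p = 1))
    ct <- suppressWarnings(stats::cor.test(x, immune_content,
                                           method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }))
  tab <- data.frame(gene = rownames(pseudobulk), rho = res[, "rho"],
                    p = res[, "p"], q = bh_adjust(res[, "p"]),
                    row.names = NULL)
  pos <- tab$gene[tab$rho > rho_min & tab$q < q_max]
  neg <- tab$gene[tab$rho < -rho_min & tab$q < q_max]
  structure(list(positive = pos, negative = neg, table = tab,
                 rho_min = rho_min, q_max = q_max),
            class = "IRFeatures")
}

#' Score a gene signature on a matrix or cohort
#'
#' Default method: mean of per-gene z-scored expression over the signature
#' members present in the matrix (genes with zero variance contribute 0, with
#' a warning when the whole matrix is degenerate). The alternative
#' rank-based method delegates to [sample_set_score()]. An empty overlap
#' between signature and matrix is an error; the missing-gene fraction is
#' attached as an attribute.
#'
#' @param x genes x samples matrix (log2), a `BulkCohort`, or an
#'   `ExpressionDataset` (cells scored).
#' @param set a `SignatureSet` or plain character vector of genes.
#' @param method "zscore" (default) or "rank".
#' @return named numeric vector of per-sample (or per-cell) scores, with
#'   attribute `missing_frac`.
#' @export
score_signature <- function(x, set, method = c("zscore", "rank")) {
  method <- match.arg(method)
  genes <- if (inherits(set, "SignatureSet")) set$genes else set
  m <- if (inherits(x, "BulkCohort")) x$matrix
       else if (inherits(x, "ExpressionDataset")) t(x$matrix)
       else as.matrix(x)
  present <- intersect(genes, rownames(m))
  if (!length(present)) stop("no signature gene present in the matrix")
  missing_frac <- 1 - length(present) / length(genes)
  if (method == "rank") {
    sc <- sample_set_score(m, present)
  } else {
    sub <- m[present, , drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    if (all(sd == 0)) warning("all signature genes are constant; scores are 0")
    z <- sweep(sub, 1, mu, "-") / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    sc <- colMeans(z)
  }
  attr(sc, "missing_frac") <- missing_frac
  sc
}

#' Export signatures as GMT with a provenance sidecar
#'
#' @param sigs list of `SignatureSet`s.
#' @param path GMT output path; provenance JSON written alongside when
#'   jsonlite is available.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  sets <- lapply(sigs, function(s) s$genes)
  names(sets) <- vapply(sigs, function(s) s$name, character(1))
  desc <- vapply(sigs, function(s)
    paste0(s$cell_type, "|", s$stringency), character(1))
  names(desc) <- names(sets)
  write_gmt(gene_set_collection(sets, descriptions = desc), path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    prov <- lapply(sigs, function(s) s$provenance[c("datasets", "thresholds")])
    names(prov) <- names(sets)
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
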