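#' Single-cell expression dataset container
#'
#' Lightweight container for one single-cell expression matrix with platform,
#' tumor-type and per-cell metadata. The matrix is cells x genes; droplet
#' ("droplet-count") matrices hold integer UMI counts, full-length
#' ("full-length-tpm") matrices hold non-negative TPM-scale reals stored
#' pre-log.
#'
#' @param matrix numeric matrix, cells x genes, non-negative.
#' @param gene_ids unique gene identifiers (length = ncol).
#' @param cell_ids unique cell identifiers (length = nrow).
#' @param platform "droplet-count" or "full-length-tpm".
#' @param tumor_type tumor-type tag for the dataset.
#' @param donor per-cell donor id (recycled if length 1).
#' @param cell_label optional per-cell ground-truth / annotation label.
#' @param normalized logical; TRUE once [normalize_expression()] has run.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(matrix, gene_ids, cell_ids,
                               platform = c("droplet-count", "full-length-tpm"),
                               tumor_type = "unknown", donor = "d1",
                               cell_label = NULL, normalized = FALSE) {
  platform <- match.arg(platform)
  matrix <- as.matrix(matrix)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (ncol(matrix) != length(gene_ids) || nrow(matrix) != length(cell_ids))
    stop("matrix dimensions do not match gene_ids/cell_ids")
  if (any(matrix < 0)) stop("expression values must be non-negative")
  if (platform == "droplet-count" && !normalized &&
      any(abs(matrix - round(matrix)) > 1e-8))
    stop("droplet-count matrices must be integer-valued")
  dimnames(matrix) <- list(cell_ids, gene_ids)
  donor <- rep_len(donor, length(cell_ids))
  ds <- structure(list(
    matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
    platform = platform, tumor_type = tumor_type, donor = donor,
    cell_label = cell_label, normalized = normalized, qc_stats = NULL
  ), class = "ExpressionDataset")
  ds$qc_stats <- compute_qc_stats(ds)
  ds
}

#' Per-cell QC statistics
#'
#' Total signal (UMI counts or TPM sum), detected-gene count and mitochondrial
#' fraction (genes with an "MT-" prefix) per cell.
#'
#' @param ds an `ExpressionDataset`.
#' @return data.frame with columns `cell_id`, `total`, `n_genes`, `mito_frac`.
#' @export
compute_qc_stats <- function(ds) {
  m <- ds$matrix
  total <- rowSums(m)
  n_genes <- rowSums(m > 0)
  mito <- grepl("^MT-", ds$gene_ids)
  mito_frac <- if (any(mito)) rowSums(m[, mito, drop = FALSE]) / pmax(total, 1)
               else rep(0, nrow(m))
  data.frame(cell_id = ds$cell_ids, total = total, n_genes = n_genes,
             mito_frac = mito_frac, row.names = NULL)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes [%s, %s]%s\n",
              nrow(x$matrix), ncol(x$matrix), x$platform, x$tumor_type,
              if (x$normalized) " (normalized)" else ""))
  if (!is.null(x$cell_label)) {
    tb <- table(x$cell_label)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# subset an ExpressionDataset by cell index/mask and/or gene ids
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_along(ds$cell_ids)
  if (is.logical(cells)) cells <- which(cells)
  gi <- if (is.null(genes)) seq_along(ds$gene_ids)
        else match(genes, ds$gene_ids)
  if (anyNA(gi)) stop("genes absent from dataset: ",
                      paste(genes[is.na(gi)], collapse = ", "))
  ds2 <- ds
  ds2$matrix <- ds$matrix[cells, gi, drop = FALSE]
  ds2$cell_ids <- ds$cell_ids[cells]
  ds2$gene_ids <- ds$gene_ids[gi]
  ds2$donor <- ds$donor[cells]
  if (!is.null(ds$cell_label)) ds2$cell_label <- ds$cell_label[cells]
  ds2$qc_stats <- compute_qc_stats(ds2)
  ds2
}

#' Bulk expression cohort container
#'
#' Genes x samples matrix on the log2 scale, with per-sample tumor type and
#' right-censored survival metadata.
#'
#' @param matrix numeric matrix, genes x samples, log2 scale.
#' @param samples data.frame with columns `sample_id`, `tumor_type`,
#'   `time_months` (> 0) and `event` (0/1).
#' @return an object of class `BulkCohort`.
#' @export
bulk_cohort <- function(matrix, samples) {
  matrix <- as.matrix(matrix)
  stopifnot(all(c("sample_id", "tumor_type", "time_months", "event") %in%
                names(samples)))
  if (ncol(matrix) != nrow(samples))
    stop("sample metadata does not match matrix columns")
  if (any(samples$time_months <= 0)) stop("survival_time must be > 0")
  if (!all(samples$event %in% c(0, 1))) stop("event must be 0/1")
  colnames(matrix) <- samples$sample_id
  structure(list(matrix = matrix, samples = samples), class = "BulkCohort")
}

#' @export
print.BulkCohort <- function(x, ...) {
  cat(sprintf("BulkCohort: %d genes x %d samples (%d events)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$samples$event)))
  invisible(x)
}
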