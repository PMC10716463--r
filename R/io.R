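#' Write an ExpressionDataset as MTX triplet plus TSV sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, genes x cells, 1-based),
#' `genes.tsv`, `barcodes.tsv` (barcode, donor, cell_label) and `dataset.tsv`
#' (platform, tumor_type, normalized) into `dir`.
#'
#' @param ds an `ExpressionDataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$matrix), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = ds$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bc <- data.frame(barcode = ds$cell_ids, donor = ds$donor,
                   cell_label = if (is.null(ds$cell_label)) NA
                                else ds$cell_label)
  utils::write.table(bc, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  utils::write.table(data.frame(platform = ds$platform,
                                tumor_type = ds$tumor_type,
                                normalized = ds$normalized),
                     file.path(dir, "dataset.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(dir)
}

#' Read an ExpressionDataset written by [write_expression_mtx()]
#'
#' @param dir directory holding matrix.mtx + sidecar TSVs.
#' @return an `ExpressionDataset`; round-trips all fields.
#' @export
read_expression_mtx <- function(dir) {
  f <- file.path(dir, "matrix.mtx")
  if (!file.exists(f)) stop("missing matrix.mtx in ", dir)
  m <- as.matrix(Matrix::readMM(f))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = FALSE)[[1]]
  bc <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                          header = TRUE)
  meta <- utils::read.table(file.path(dir, "dataset.tsv"), sep = "\t",
                            header = TRUE)
  if (nrow(m) != length(genes) || ncol(m) != nrow(bc))
    stop("dimension mismatch between matrix.mtx and sidecars in ", dir)
  labels <- if (all(is.na(bc$cell_label))) NULL else as.character(bc$cell_label)
  expression_dataset(t(m), gene_ids = as.character(genes),
                     cell_ids = as.character(bc$barcode),
                     platform = meta$platform, tumor_type = meta$tumor_type,
                     donor = as.character(bc$donor), cell_label = labels,
                     normalized = meta$normalized)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, members. Member reading
#' delegates to `fgsea::gmtPathways`; descriptions are retained from the second
#' column.
#'
#' @param path GMT file.
#' @return a `GeneSetCollection`: named list of gene vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- readLines(path)
  desc <- vapply(strsplit(lines, "\t"), function(x) x[2], character(1))
  names(desc) <- vapply(strsplit(lines, "\t"), function(x) x[1], character(1))
  gene_set_collection(sets, descriptions = desc[names(sets)])
}

#' Construct / validate a gene-set collection
#'
#' @param sets named list of non-empty, duplicate-free gene vectors.
#' @param descriptions optional per-set description strings.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) stop("empty gene set: ", nm)
    if (anyDuplicated(sets[[nm]])) stop("duplicate members in set: ", nm)
  }
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets)); names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `GeneSetCollection` (or plain named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) {
    desc <- rep("na", length(collection)); names(desc) <- names(collection)
  }
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a dendrogram / tree in newick format
#'
#' @param tree an `hclust` or `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a bulk cohort as TSV pair
#'
#' `cohort.tsv` holds genes x samples log2 expression with a leading `gene`
#' column; `samples.tsv` holds sample metadata (sample_id, tumor_type,
#' time_months, event, plus any extra columns such as planted archetype).
#'
#' @param cohort a `BulkCohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bulk_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene = rownames(cohort$matrix), cohort$matrix,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bulk_cohort
#' @export
read_bulk_cohort <- function(dir) {
  df <- utils::read.table(file.path(dir, "cohort.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  samples <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                               header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  bulk_cohort(m, samples)
}
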