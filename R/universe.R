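#' Gene universe and cell-type expression programs for simulation
#'
#' Builds the fixed gene universe used by all simulators: canonical marker
#' panels for the major tumor-microenvironment cell types, the mitochondrial /
#' ribosomal / cell-cycle / heat-shock housekeeping families (so QC rules and
#' informative-gene exclusion lists are exercised literally), conserved
#' microglia/BMDM core programs that survive platform dropout, planted tumor
#' programs (shared tumor, positive and negative immune-recruitment, hypoxia),
#' and anonymous filler genes.
#'
#' @param n_filler number of anonymous background genes (G0001, ...).
#' @return list with `genes` (character vector, unique), `families` (named list
#'   of gene-family character vectors) and `panels` (named list of cell-type
#'   marker panels).
#' @export
gene_universe <- function(n_filler = 600) {
  fam <- list(
    mito = c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-CO3",
             "MT-ATP6", "MT-ATP8", "MT-CYB", "MT-ND4", "MT-ND5"),
    ribosomal = c(sprintf("RPS%d", 2:11), sprintf("RPL%d", 3:12)),
    cell_cycle = c("MKI67", "TOP2A", "CDK1", "CCNB1", "PCNA", "MCM2",
                   "AURKA", "BUB1"),
    heat_shock = c("HSPA1A", "HSPA1B", "HSPB1", "HSP90AA1", "HSPH1", "DNAJB1")
  )
  panels <- list(
    Tcell  = c("CD3D", "CD3E", "CD3G", "CD2", "TRAC", "CD7", "LCK"),
    CD4    = c("CD4", "CD40LG", "IL7R"),
    CD8    = c("CD8A", "CD8B", "GZMK"),
    CD8cyto = c("GZMB", "PRF1", "NKG7", "GNLY", "KLRD1"),
    Bcell  = c("CD79A", "CD79B", "MS4A1", "IGHG1", "MZB1"),
    NK     = c("KLRB1", "NCR1", "KLRF1"),
    Myeloid = c("ITGAM", "CD68", "CSF1R", "AIF1", "LYZ", "TYROBP", "FCER1G"),
    MG_canonical   = c("P2RY12", "TMEM119", "CX3CR1", "SALL1"),
    BMDM_canonical = c("ITGA4", "SELL", "F13A1", "CRIP1"),
    MG_core   = sprintf("MGC%02d", 1:10),
    BMDM_core = sprintf("BMC%02d", 1:10),
    OG = c("MBP", "MOG", "PLP1", "MAG", "CNP", "SOX10"),
    Tumor = sprintf("TUM%02d", 1:15),
    posIR = sprintf("PIR%02d", 1:12),
    negIR = sprintf("NIR%02d", 1:12),
    Hypoxia = c("VEGFA", "SLC2A1", sprintf("HYP%02d", 1:8)),
    M1 = c("TNF", "IL1B", "CXCL9", "CXCL10", "NOS2", "IL6"),
    M2 = c("MRC1", "CD163", "MSR1", "CCL22", "IL10", "TGFB1")
  )
  common <- c("PTPRC")
  filler <- sprintf("G%04d", seq_len(n_filler))
  genes <- unique(c(unlist(fam, use.names = FALSE),
                    unlist(panels, use.names = FALSE), common, filler))
  # disjoint filler blocks: each simulated type's broader expression program
  # beyond its canonical markers (real cell types differ in hundreds of genes)
  block_types <- c("Tcell", "CD4T", "CD8T", "CD8cyto", "Bcell", "NK",
                   "Myeloid", "MG", "BMDM", "OG", "Tumor", "TumorPosIR",
                   "TumorNegIR", "MyeloidHypoxia")
  block_size <- max(0L, min(40L, floor(n_filler / length(block_types))))
  blocks <- stats::setNames(vector("list", length(block_types)), block_types)
  for (i in seq_along(block_types)) {
    idx <- if (block_size > 0) ((i - 1) * block_size + 1):(i * block_size)
           else integer(0)
    blocks[[i]] <- filler[idx]
  }
  list(genes = genes, families = fam, panels = panels, blocks = blocks)
}

#' Marker panel of a cell type
#'
#' The genes a cell type over-expresses in the simulation, used both by the
#' generator (to plant programs) and by the annotation tests (as ground truth).
#'
#' @param universe result of [gene_universe()].
#' @param cell_type one of the simulated types, e.g. "Tcell", "Myeloid", "MG",
#'   "BMDM", "OG", "Bcell", "NK", "Tumor", "CD4T", "CD8T".
#' @return character vector of marker genes.
#' @export
type_program_genes <- function(universe, cell_type) {
  p <- universe$panels
  b <- universe$blocks
  core <- switch(cell_type,
    Tcell  = c(p$Tcell, "PTPRC", b$Tcell),
    CD4T   = c(p$Tcell, p$CD4, "PTPRC", b$Tcell, b$CD4T),
    CD8T   = c(p$Tcell, p$CD8, "PTPRC", b$Tcell, b$CD8T),
    CD8cyto = c(p$Tcell, p$CD8, p$CD8cyto, "PTPRC", b$Tcell, b$CD8T,
                b$CD8cyto),
    Bcell  = c(p$Bcell, "PTPRC", b$Bcell),
    NK     = c(p$NK, "PTPRC", b$NK),
    Myeloid = c(p$Myeloid, "PTPRC", b$Myeloid),
    MG     = c(p$Myeloid, p$MG_canonical, p$MG_core, "PTPRC", b$Myeloid,
               b$MG),
    BMDM   = c(p$Myeloid, p$BMDM_canonical, p$BMDM_core, "PTPRC", b$Myeloid,
               b$BMDM),
    OG     = c(p$OG, b$OG),
    Tumor  = c(p$Tumor, b$Tumor),
    TumorPosIR = c(p$Tumor, p$posIR, b$Tumor, b$TumorPosIR),
    TumorNegIR = c(p$Tumor, p$negIR, b$Tumor, b$TumorNegIR),
    MyeloidHypoxia = c(p$Myeloid, p$Hypoxia, "PTPRC", b$Myeloid,
                       b$MyeloidHypoxia),
    stop("unknown simulated cell type: ", cell_type)
  )
  unique(core)
}

# Baseline log2 mean expression per gene, drawn once per universe from `seed`.
# Marker boosts are added on top of this baseline by the simulators.
base_log2_means <- function(universe, seed) {
  set.seed(seed)
  mu <- stats::rnorm(length(universe$genes), mean = 1.0, sd = 0.8)
  names(mu) <- universe$genes
  # housekeeping families are broadly expressed in every cell type
  hk <- unlist(universe$families[c("mito", "ribosomal")], use.names = FALSE)
  mu[hk] <- mu[hk] + 2.5
  mu
}
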