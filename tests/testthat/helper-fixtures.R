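# Shared fixture builders. All data is generated in code at test time; the
# configurations below are the package's standard desk-scale study
# conditions.

# mixed-type droplet dataset (coarse cell types)
fixture_mixed_config <- function(seed = 1, n_cells = 300,
                                 proportions = c(Tcell = 0.4, Myeloid = 0.4,
                                                 OG = 0.2)) {
  simulation_config(list(
    list(name = "d1", platform = "droplet-count", tumor_type = "MB",
         n_cells = n_cells, proportions = proportions)), seed = seed)
}

fixture_mixed_dataset <- function(seed = 1, ...) {
  ds <- simulate_single_cell(fixture_mixed_config(seed, ...))[[1]]
  normalize_expression(qc_filter(ds))
}

# paired-platform MG/BMDM configuration for the lineage-transfer pipeline
fixture_lineage_config <- function(seed = 1, n_fl = 200, n_dr = 200) {
  simulation_config(list(
    list(name = "ss_epn", platform = "full-length-tpm", tumor_type = "EPN",
         n_cells = n_fl, proportions = c(MG = 0.6, BMDM = 0.4)),
    list(name = "ss_gbm", platform = "full-length-tpm", tumor_type = "GBM",
         n_cells = n_fl, proportions = c(MG = 0.5, BMDM = 0.5)),
    list(name = "x_epn", platform = "droplet-count", tumor_type = "EPN",
         n_cells = n_dr, proportions = c(MG = 0.6, BMDM = 0.4))),
    seed = seed)
}

fixture_lineage_sets <- function(seed = 1, ...) {
  sets <- simulate_single_cell(fixture_lineage_config(seed, ...))
  lapply(sets, function(d)
    if (d$platform == "droplet-count") normalize_expression(qc_filter(d))
    else normalize_expression(d))
}

# four-dataset (2 tumor types x 2 platforms) configuration for scFes
fixture_scfes_config <- function(seed = 5, n_cells = 400) {
  props <- c(Tcell = 0.3, Myeloid = 0.3, OG = 0.2, Bcell = 0.2)
  simulation_config(list(
    list(name = "mb10x", platform = "droplet-count", tumor_type = "MB",
         n_cells = n_cells, proportions = props),
    list(name = "mbss", platform = "full-length-tpm", tumor_type = "MB",
         n_cells = n_cells, proportions = props),
    list(name = "epn10x", platform = "droplet-count", tumor_type = "EPN",
         n_cells = n_cells, proportions = props),
    list(name = "epnss", platform = "full-length-tpm", tumor_type = "EPN",
         n_cells = n_cells, proportions = props)), seed = seed)
}

fixture_scfes_sets <- function(seed = 5, ...) {
  lapply(simulate_single_cell(fixture_scfes_config(seed, ...)), function(d)
    if (d$platform == "droplet-count") normalize_expression(qc_filter(d))
    else normalize_expression(d))
}

# myeloid meta-clustering: 3 datasets sharing 5 planted subtypes
fixture_myeloid_config <- function(seed = 7) {
  props <- c(MG = 0.25, BMDM = 0.2, Myeloid = 0.2, MyeloidHypoxia = 0.2,
             Tcell = 0.15)
  simulation_config(list(
    list(name = "a", platform = "droplet-count", tumor_type = "MB",
         n_cells = 250, proportions = props),
    list(name = "b", platform = "droplet-count", tumor_type = "EPN",
         n_cells = 250, proportions = props),
    list(name = "c", platform = "full-length-tpm", tumor_type = "GBM",
         n_cells = 200,
         proportions = c(MG = 0.3, BMDM = 0.25, Myeloid = 0.25,
                         MyeloidHypoxia = 0.2))), seed = seed)
}

fixture_myeloid_sets <- function(seed = 7) {
  lapply(simulate_single_cell(fixture_myeloid_config(seed)), function(d)
    if (d$platform == "droplet-count") normalize_expression(qc_filter(d))
    else normalize_expression(d))
}

# small crafted droplet dataset with explicit per-cell QC properties
fixture_crafted_qc <- function() {
  genes <- c(paste0("MT-", 1:2), sprintf("g%03d", 1:498))
  base <- matrix(5L, nrow = 4, ncol = 500)
  # cell 1: 1999 UMIs, 500 genes, <1% mito -> fails min_umi only
  base[1, ] <- 4L; base[1, 1:2] <- c(4L, 3L)
  stopifnot(sum(base[1, ]) == 1999, sum(base[1, ] > 0) == 500)
  # cell 2: exactly 2000 UMIs, 200 detected genes, exactly 10% mito -> retained
  base[2, ] <- 0L
  base[2, 1:2] <- c(100L, 100L)          # 200 mito counts
  base[2, 3:200] <- 9L                   # 198 genes x 9 = 1782
  base[2, 200] <- 9L + 18L               # top up to 2000 total
  stopifnot(sum(base[2, ]) == 2000, sum(base[2, ] > 0) == 200,
            sum(base[2, 1:2]) / sum(base[2, ]) == 0.10)
  # cell 3: high mito (falls over 10%)
  base[3, 1] <- 2000L
  # cell 4: comfortable pass
  base[4, ] <- 10L; base[4, 1:2] <- 1L
  expression_dataset(base, gene_ids = genes,
                     cell_ids = paste0("c", 1:4), platform = "droplet-count")
}
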