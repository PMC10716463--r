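test_that("QC boundaries are strict on violations, inclusive on ties", {
  ds <- fixture_crafted_qc()
  kept <- qc_filter(ds)
  # cell 1: 1999 UMIs (just under), plenty of genes, low mito -> removed
  expect_false("c1" %in% kept$cell_ids)
  # cell 2 sits exactly at 2000 UMIs / 200 genes / 10% mito -> retained
  expect_true("c2" %in% kept$cell_ids)
  # cell 3: mito fraction far over 10% -> removed; cell 4 passes
  expect_false("c3" %in% kept$cell_ids)
  expect_true("c4" %in% kept$cell_ids)
})

test_that("qc_filter equals the brute-force boolean mask", {
  for (seed in 1:3) {
    cfg <- simulation_config(list(
      list(name = "d", platform = "droplet-count", tumor_type = "MB",
           n_cells = 100, proportions = c(Tcell = 0.5, Myeloid = 0.5))),
      seed = seed, qc_violations = 10L)
    ds <- simulate_single_cell(cfg)[[1]]
    qc <- ds$qc_stats
    mask <- qc$total >= 2000 & qc$n_genes >= 200 & qc$mito_frac <= 0.10
    kept <- qc_filter(ds)
    expect_identical(kept$cell_ids, ds$cell_ids[mask])
    expect_identical(nrow(kept$matrix), 90L)  # 10 planted violations
  }
})

test_that("qc_filter contract errors and TPM bypass", {
  ds <- fixture_crafted_qc()
  expect_error(qc_filter(ds, qc_thresholds(min_umi = 1e9)), "all cells")
  tpm <- expression_dataset(matrix(runif(20), 4, 5),
                            gene_ids = paste0("g", 1:5),
                            cell_ids = paste0("c", 1:4),
                            platform = "full-length-tpm")
  expect_warning(out <- qc_filter(tpm), "bypass")
  expect_identical(out$cell_ids, tpm$cell_ids)
})

test_that("normalization follows the platform rules exactly", {
  # droplet: per-cell rescale to 1e4 then natural log1p
  dr <- expression_dataset(rbind(c(10, 90, 0), c(0, 0, 0)),
                           gene_ids = paste0("g", 1:3),
                           cell_ids = c("c1", "c2"),
                           platform = "droplet-count")
  out <- normalize_expression(dr)
  expect_equal(unname(out$matrix[1, ]), c(log(1001), log(9001), 0))
  expect_equal(unname(out$matrix[2, ]), c(0, 0, 0))  # all-zero stays zero
  # full-length: log2(x + 1)
  fl <- expression_dataset(matrix(3, 1, 1), gene_ids = "g1",
                           cell_ids = "c1", platform = "full-length-tpm")
  expect_equal(unname(normalize_expression(fl)$matrix[1, 1]), 2)
  expect_error(normalize_expression(out), "already normalized")
})

test_that("two-run clustering recovers well-separated planted types", {
  ds <- fixture_mixed_dataset(seed = 1,
                              proportions = c(Tcell = 0.5, Myeloid = 0.5))
  model <- two_run_cluster(ds, resolution_first = 0.3)
  expect_gte(length(unique(model$labels)), 2)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(model$labels, ds$cell_label)
  expect_equal(ari, 1)
})

test_that("a homogeneous population yields one cluster at low resolution", {
  cfg <- simulation_config(list(
    list(name = "d", platform = "droplet-count", tumor_type = "MB",
         n_cells = 120, proportions = c(Tcell = 1),
         allow_single_type = TRUE)), seed = 4)
  ds <- normalize_expression(qc_filter(simulate_single_cell(cfg)[[1]]))
  model <- cluster_cells(ds, resolution = 0.01)
  expect_identical(length(unique(model$labels)), 1L)
})

test_that("mini-cluster purge removes planted contaminants from myeloid", {
  uni <- gene_universe(600)
  cfg <- simulation_config(list(
    list(name = "d", platform = "droplet-count", tumor_type = "MB",
         n_cells = 400,
         proportions = c(MG = 0.49, BMDM = 0.49, Tcell = 0.02))), seed = 8)
  ds <- normalize_expression(qc_filter(simulate_single_cell(cfg)[[1]]))
  panel <- list(Myeloid = uni$panels$Myeloid, Tcell = uni$panels$Tcell)
  model <- two_run_cluster(ds, resolution_first = 0.3, panel = panel)
  truth <- ds$cell_label[match(names(model$labels), ds$cell_ids)]
  # no true T cell survives inside the myeloid compartment
  expect_false(any(truth == "Tcell" & model$labels == "Myeloid"))
})

test_that("positive selection is a strict dataset-mean rule", {
  m <- matrix(1, nrow = 10, ncol = 2)
  m[, 2] <- c(rep(10, 3), rep(0.1, 7))
  ds <- expression_dataset(m, gene_ids = c("FLAT", "MBP"),
                           cell_ids = paste0("c", 1:10),
                           platform = "full-length-tpm", normalized = TRUE)
  # constant marker: nothing exceeds the mean
  expect_identical(sum(annotate_positive_selection(ds, "FLAT")), 0L)
  # bimodal marker: exactly the planted high mode
  pos <- annotate_positive_selection(ds, "MBP")
  expect_identical(unname(which(pos)), 1:3)
  # common positive rescaling of the marker leaves the positive set unchanged
  ds2 <- ds; ds2$matrix[, "MBP"] <- 7.5 * ds2$matrix[, "MBP"]
  expect_identical(annotate_positive_selection(ds2, "MBP"), pos)
  expect_error(annotate_positive_selection(ds, "NOPE"), "absent")
})

test_that("cluster-based annotation and the method comparison table agree", {
  uni <- gene_universe(600)
  ds <- fixture_mixed_dataset(seed = 2)
  panel <- list(Tcell = uni$panels$Tcell, Myeloid = uni$panels$Myeloid,
                OG = uni$panels$OG)
  model <- cluster_cells(ds, resolution = 0.3)
  ann <- annotate_cluster_based(model, panel, ds)
  expect_true(all(ann == ds$cell_label))
  tab <- compare_annotation_methods(ds, panel, model = model)
  expect_setequal(unique(tab$method),
                  c("cluster_based", "positive_selection"))
  cb <- tab[tab$method == "cluster_based", ]
  expect_equal(sum(cb$n_cells), length(ds$cell_ids))
  expect_true(all(is.finite(cb$mean_pathway_score)))
})
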