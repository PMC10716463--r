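uni <- gene_universe(600)

test_that("reference labeling and resubstitution bound hold", {
  sets <- fixture_lineage_sets(seed = 3)
  ref <- label_reference(sets$ss_epn, uni$panels$MG_canonical,
                         uni$panels$BMDM_canonical)
  expect_gte(mean(ref$cell_label == sets$ss_epn$cell_label), 0.95)
  clf <- train_lineage_classifier(list(ref))
  self <- predict_lineage(clf, ref)
  resub_acc <- mean(self$labels == ref$cell_label)
  expect_gte(resub_acc, 1 - clf$oob_error)
})

test_that("cross-platform transfer recovers planted lineages under dropout", {
  accs <- vapply(1:3, function(seed) {
    sets <- fixture_lineage_sets(seed = seed)
    refs <- lapply(sets[c("ss_epn", "ss_gbm")], label_reference,
                   mg_markers = uni$panels$MG_canonical,
                   bmdm_markers = uni$panels$BMDM_canonical)
    clf <- train_lineage_classifier(refs)
    pr <- predict_lineage(clf, sets$x_epn)
    mean(pr$labels == sets$x_epn$cell_label)
  }, numeric(1))
  expect_true(all(accs > 0.9))
})

test_that("canonical markers really drop out on the droplet platform", {
  sets <- fixture_lineage_sets(seed = 4)
  canon <- c(uni$panels$MG_canonical, uni$panels$BMDM_canonical)
  det_dr <- mean(sets$x_epn$matrix[, canon] > 0)
  det_fl <- mean(sets$ss_epn$matrix[, canon] > 0)
  expect_lt(det_dr, 0.5 * det_fl)
})

test_that("prediction on a dataset missing a feature gene names it", {
  sets <- fixture_lineage_sets(seed = 3)
  ref <- label_reference(sets$ss_epn, uni$panels$MG_canonical,
                         uni$panels$BMDM_canonical)
  clf <- train_lineage_classifier(list(ref))
  crippled <- subset_dataset(sets$x_epn,
                             genes = setdiff(sets$x_epn$gene_ids, "MGC01"))
  expect_error(predict_lineage(clf, crippled), "MGC01")
  expect_error(train_lineage_classifier(list(
    subset_dataset(ref, cells = ref$cell_label == "MG"))), "single-class")
})

test_that("conserved DEGs intersect across types and are order-invariant", {
  sets <- fixture_lineage_sets(seed = 5)
  refs <- lapply(sets[c("ss_epn", "ss_gbm")], label_reference,
                 mg_markers = uni$panels$MG_canonical,
                 bmdm_markers = uni$panels$BMDM_canonical)
  cd <- conserved_degs(refs)
  # planted core programs recovered, up-sets disjoint
  expect_true(all(uni$panels$MG_core %in% cd$up_mg))
  expect_true(all(uni$panels$BMDM_core %in% cd$up_bmdm))
  expect_length(intersect(cd$up_mg, cd$up_bmdm), 0)
  # duplicated dataset: intersection equals the single-dataset set
  cd_dup <- conserved_degs(list(a = refs[[1]], b = refs[[1]]))
  cd_single_mg <- cd_dup$per_source[[1]]
  expect_setequal(cd_dup$up_mg,
                  cd_single_mg$gene[cd_single_mg$cluster == "MG"])
  # order invariance
  cd_rev <- conserved_degs(rev(refs))
  expect_setequal(cd$up_mg, cd_rev$up_mg)
  expect_setequal(cd$up_bmdm, cd_rev$up_bmdm)
  # a gene silenced in one source type is excluded from the intersection
  mut <- refs[[2]]
  mut$matrix[, "MGC01"] <- 0
  cd_mut <- conserved_degs(list(refs[[1]], mut))
  expect_false("MGC01" %in% cd_mut$up_mg)
})

test_that("conserved-gene reclustering annotates lineages by vote", {
  sets <- fixture_lineage_sets(seed = 3)
  refs <- lapply(sets[c("ss_epn", "ss_gbm")], label_reference,
                 mg_markers = uni$panels$MG_canonical,
                 bmdm_markers = uni$panels$BMDM_canonical)
  clf <- train_lineage_classifier(refs)
  cd <- conserved_degs(refs)
  rc <- recluster_on_conserved(sets$x_epn, cd, clf)
  expect_gte(mean(rc$lineage == sets$x_epn$cell_label), 0.9)
})

test_that("zero-dropout same-platform transfer is perfect", {
  for (seed in 1:2) {
    cfg <- simulation_config(list(
      list(name = "tr", platform = "full-length-tpm", tumor_type = "EPN",
           n_cells = 150, proportions = c(MG = 0.5, BMDM = 0.5)),
      list(name = "te", platform = "full-length-tpm", tumor_type = "GBM",
           n_cells = 150, proportions = c(MG = 0.5, BMDM = 0.5))),
      seed = seed,
      dropout = c("droplet-count" = 0, "full-length-tpm" = 0),
      marker_dropout = 0)
    sets <- lapply(simulate_single_cell(cfg), normalize_expression)
    clf <- train_lineage_classifier(sets["tr"])
    pr <- predict_lineage(clf, sets$te)
    expect_equal(mean(pr$labels == sets$te$cell_label), 1)
  }
})

test_that("MDS of the forest proximity separates the planted classes", {
  skip_if_not_installed("cluster")
  sets <- fixture_lineage_sets(seed = 3)
  ref <- label_reference(sets$ss_epn, uni$panels$MG_canonical,
                         uni$panels$BMDM_canonical)
  clf <- train_lineage_classifier(list(ref))
  emb <- classifier_mds(clf)
  y <- ref$cell_label[ref$cell_label %in% c("MG", "BMDM")]
  sil <- cluster::silhouette(as.integer(factor(y)), stats::dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
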