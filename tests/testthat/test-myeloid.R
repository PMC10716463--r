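test_that("Davies-Bouldin equals the from-definition oracle", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(30:200, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * 3), ncol = 3)
    labels <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(davies_bouldin(x, labels), dbi_oracle(x, labels),
                 tolerance = 1e-9)
  }
  expect_error(davies_bouldin(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "single cluster")
})

test_that("informative-gene ranking honors exclusions, quorum and cap", {
  uni <- gene_universe(600)
  sets <- fixture_myeloid_sets(seed = 7)
  rk <- rank_informative_genes(sets)
  excl <- unlist(uni$families[c("ribosomal", "cell_cycle", "heat_shock")],
                 use.names = FALSE)
  expect_length(intersect(rk$informative, excl), 0)
  expect_lte(length(rk$informative), 2000)
  # planted myeloid-subtype discriminating genes all make the cut
  discr <- c(uni$panels$MG_core, uni$panels$BMDM_core,
             uni$panels$Hypoxia)
  expect_true(all(discr %in% rk$informative))
  # constant gene: F = 0, never informative
  mut <- sets
  mut[[1]]$matrix[, "G0599"] <- 1
  mut[[2]]$matrix[, "G0599"] <- 1
  mut[[3]]$matrix[, "G0599"] <- 1
  rk2 <- rank_informative_genes(mut)
  tab <- rk2$table
  expect_false("G0599" %in% rk2$informative[
    seq_len(min(100, length(rk2$informative)))])
  # detection quorum: a gene zeroed in 2 of 3 datasets is excluded
  mut2 <- sets
  mut2[[1]]$matrix[, "MGC01"] <- 0
  mut2[[2]]$matrix[, "MGC01"] <- 0
  rk3 <- rank_informative_genes(mut2)
  expect_false("MGC01" %in% rk3$informative)
  # n_top cap binds
  rk4 <- rank_informative_genes(sets, n_top = 10)
  expect_length(rk4$informative, 10)
})

test_that("single-cluster datasets are skipped with a warning", {
  sets <- fixture_myeloid_sets(seed = 7)
  labels <- lapply(sets, function(d) d$cell_label)
  labels[[2]] <- rep("only", length(labels[[2]]))
  expect_warning(rk <- rank_informative_genes(sets, labels = labels),
                 "single cluster")
  expect_gt(length(rk$informative), 0)
  expect_error(
    suppressWarnings(rank_informative_genes(
      sets[1], labels = list(rep("only", nrow(sets[[1]]$matrix))))),
    "no dataset")
})

test_that("DBI selects the planted cluster number", {
  uni <- gene_universe(600)
  sets <- fixture_myeloid_sets(seed = 7)
  # cap scaled to the simulated universe so the informative filter binds
  rk <- rank_informative_genes(sets, n_top = 200)
  comb <- combine_zscore(sets)
  sel <- select_cluster_number(comb, rk$informative)
  expect_identical(sel$selected_k, 5L)  # five planted myeloid-area subtypes
  # the binding cap removes the platform-dropout-biased canonical markers
  # while keeping the conserved discriminating programs
  canon <- c(uni$panels$MG_canonical, uni$panels$BMDM_canonical)
  expect_length(intersect(canon, rk$informative), 0)
  expect_true(all(c(uni$panels$MG_core, uni$panels$BMDM_core) %in%
                  rk$informative))
  expect_identical(sel$trace$dbi[sel$trace$resolution ==
                                 sel$selected_resolution],
                   min(sel$trace$dbi, na.rm = TRUE))
  skip_if_not_installed("mclust")
  truth <- unlist(lapply(sets, function(d) d$cell_label))
  expect_gte(mclust::adjustedRandIndex(sel$model$labels, truth), 0.9)
})

test_that("DBI is invariant to exact duplication of every point", {
  set.seed(21)
  x <- matrix(rnorm(150 * 4), ncol = 4)
  labels <- sample(1:4, 150, replace = TRUE)
  expect_equal(davies_bouldin(rbind(x, x), c(labels, labels)),
               davies_bouldin(x, labels), tolerance = 1e-12)
})

test_that("a single-resolution grid selects that resolution", {
  sets <- fixture_myeloid_sets(seed = 9)
  rk <- rank_informative_genes(sets)
  comb <- combine_zscore(sets)
  rownames(comb) <- sprintf("cell%05d", seq_len(nrow(comb)))
  one <- select_cluster_number(comb, rk$informative, resolutions = 0.5)
  expect_identical(one$selected_resolution, 0.5)
})

test_that("cluster dendrogram groups the shared hypoxia program", {
  sets <- fixture_myeloid_sets(seed = 7)
  profs <- lapply(sets, function(d)
    cluster_mean_profiles(d, d$cell_label, prefix = d$tumor_type))
  hc <- cluster_similarity_dendrogram(profs)
  total_clusters <- sum(vapply(profs, ncol, integer(1)))
  expect_length(hc$labels, total_clusters)  # leaf conservation
  # the three tumor types' hypoxia clusters form their own clade
  hyp <- grep("MyeloidHypoxia", hc$labels, value = TRUE)
  expect_length(hyp, 3)
  k_cut <- stats::cutree(hc, k = 5)
  expect_identical(length(unique(k_cut[hyp])), 1L)
  # identical profiles merge at height ~0
  twice <- list(A = profs[[1]], B = profs[[1]])
  hc2 <- cluster_similarity_dendrogram(twice)
  expect_lt(min(hc2$height), 1e-10)
  # input order does not change the topology
  hc_rev <- cluster_similarity_dendrogram(rev(profs))
  co <- stats::cophenetic(hc)
  co_rev <- stats::cophenetic(hc_rev)
  lb <- labels(co)
  m1 <- as.matrix(co); m2 <- as.matrix(co_rev)[lb, lb]
  expect_equal(m1, m2, tolerance = 1e-12)
})
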