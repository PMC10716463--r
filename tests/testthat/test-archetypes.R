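uni <- gene_universe(600)
sigs3 <- list(myeloid = c("ITGAM", uni$panels$Myeloid),
              tcell = c("CD3D", uni$panels$Tcell),
              og = c("MAG", uni$panels$OG))

test_that("archetype discovery selects the planted cluster number", {
  co <- simulate_bulk_cohort(fixture_mixed_config(seed = 11))
  sc <- score_feature_matrix(co, sigs3)
  expect_equal(unname(colMeans(sc)), rep(0, 3), tolerance = 1e-10)
  am <- discover_archetypes(sc, k_range = 2:8)
  expect_identical(am$k, 4L)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(am$labels, co$samples$archetype), 0.9)
})

test_that("discovery guards: k-range bounds and duplicated samples", {
  co <- simulate_bulk_cohort(fixture_mixed_config(seed = 11),
                             default_archetype_plan(n_per_archetype = 5))
  sc <- score_feature_matrix(co, sigs3)
  expect_error(discover_archetypes(sc, k_range = 2:30), "n_samples")
  expect_error(discover_archetypes(sc, k_range = 1:4), "k = 1")
  dup <- rbind(sc, sc)
  rownames(dup) <- sprintf("s%03d", seq_len(nrow(dup)))
  am <- discover_archetypes(dup, k_range = 2:6)
  half <- nrow(sc)
  expect_identical(unname(am$labels[seq_len(half)]),
                   unname(am$labels[half + seq_len(half)]))
})

test_that("archetype gene features obey intersection, CV cap and detection", {
  co <- simulate_bulk_cohort(fixture_mixed_config(seed = 11))
  feats <- archetype_gene_features(co, co$samples$archetype)
  expect_true(all(lengths(feats) <= 20))
  for (a in names(feats)) {
    in_a <- co$samples$archetype == a
    for (g in feats[[a]]) {
      expect_gte(mean(co$matrix[g, in_a] > 0), 0.8)
    }
  }
  # the immune-desert archetype's feature consists entirely of its planted
  # identity programs (negative-IR plus the elevated shared tumor program)
  planted <- c(uni$panels$negIR, uni$blocks$TumorNegIR,
               uni$panels$Tumor, uni$blocks$Tumor)
  expect_true(all(feats$immune_desert %in% planted))
})

test_that("25-gene intersections are cut to the 20 lowest-CV genes", {
  set.seed(36)
  n_per <- 20
  genes <- c(sprintf("de%02d", 1:25), sprintf("bg%02d", 1:30))
  m <- matrix(rnorm(length(genes) * 2 * n_per, mean = 5, sd = 0.2),
              nrow = length(genes),
              dimnames = list(genes, NULL))
  # 25 genes strongly up in archetype A with gene-specific within-A spread
  spreads <- seq(0.05, 2, length.out = 25)
  for (i in 1:25)
    m[i, seq_len(n_per)] <- rnorm(n_per, mean = 12, sd = spreads[i])
  co <- bulk_cohort(m, data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_per)),
    tumor_type = "X", time_months = 10, event = 1))
  labels <- rep(c("A", "B"), each = n_per)
  # B has no up-regulated genes by construction; its empty-feature warning is
  # exercised in the dedicated test below
  feats <- suppressWarnings(archetype_gene_features(co, labels))
  expect_length(feats$A, 20)
  expect_true(all(feats$A %in% sprintf("de%02d", 1:25)))
  # the dropped five are those with the largest within-A CV
  lin <- 2^m[sprintf("de%02d", 1:25), seq_len(n_per)] - 1
  cv <- apply(lin, 1, sd) / rowMeans(lin)
  expect_setequal(feats$A, names(sort(cv))[1:20])
})

test_that("an archetype without exclusive genes gets an empty feature", {
  set.seed(37)
  m <- matrix(rnorm(40 * 30, 5), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  labels <- rep(c("A", "B", "C"), each = 10)
  m[1:5, labels == "C"] <- m[1:5, labels == "C"] + 6
  co <- bulk_cohort(m, data.frame(sample_id = sprintf("s%02d", 1:30),
                                  tumor_type = "X", time_months = 10,
                                  event = 1))
  expect_warning(feats <- archetype_gene_features(co, labels),
                 "empty gene feature")
  expect_length(feats$A, 0)
  expect_gt(length(feats$C), 0)
})

test_that("projection reproduces training labels and flags thin margins", {
  co <- simulate_bulk_cohort(fixture_mixed_config(seed = 13))
  sc <- score_feature_matrix(co, sigs3)
  am <- discover_archetypes(sc, k_range = 2:8)
  feats <- archetype_gene_features(co, am$labels)
  proj <- project_archetypes(co, feats)
  tab <- table(proj, am$labels)
  agreement <- sum(apply(tab, 2, max)) / length(proj)
  expect_gte(agreement, 0.9)
  # an impossibly wide margin threshold sends everything to "unassigned"
  proj_t <- project_archetypes(co, feats, tau = 1e6)
  expect_true(all(proj_t == "unassigned"))
})

test_that("survival association: null uniformity, planted HR, guards", {
  set.seed(38)
  ps <- vapply(1:20, function(i) {
    samples <- data.frame(time_months = rexp(80, 1 / 30),
                          event = rbinom(80, 1, 0.8))
    survival_association(rep(c("a", "b"), 40), samples)$logrank_p
  }, numeric(1))
  expect_gt(stats::median(ps), 0.2)
  plan <- list(
    list(name = "a_good", n = 200, hazard = 1 / 60,
         composition = c(Tcell = 0.5, Myeloid = 0.5)),
    list(name = "b_bad", n = 200, hazard = 3 / 60,
         composition = c(Tumor = 0.7, OG = 0.3)))
  co <- simulate_bulk_cohort(fixture_mixed_config(seed = 14), plan)
  res <- survival_association(co$samples$archetype, co$samples)
  expect_true(res$cox$HR > 2 && res$cox$HR < 4.5)
  expect_lt(res$logrank_p, 0.01)
  expect_error(survival_association(
    rep(c("a", "b"), 5),
    data.frame(time_months = rexp(10, 1), event = rep(0, 10))), "no events")
})
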