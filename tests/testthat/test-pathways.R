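test_that("marker detection handles exclusive genes and planted effects", {
  set.seed(30)
  n <- 60
  m <- matrix(rexp(n * 5, 1), nrow = n)
  colnames(m) <- paste0("g", 1:5)
  labels <- rep(c("A", "B"), each = n / 2)
  m[labels == "B", 1] <- 0                     # g1 exclusive to A
  m[labels == "A", 2] <- m[labels == "A", 2] + 4  # strong planted marker
  tab <- find_markers(m, labels, filter = FALSE)
  g1 <- tab[tab$cluster == "A" & tab$gene == "g1", ]
  expect_gt(g1$logFC, 0)
  expect_identical(g1$pct_out, 0)
  g2 <- tab[tab$cluster == "A" & tab$gene == "g2", ]
  expect_gt(g2$logFC, 0.25)
  expect_lt(g2$p_adj, 1e-5)
  expect_gt(g2$pct_in, 0.3)
})

test_that("a planted two-fold marker passes the droplet threshold triple", {
  ds <- fixture_mixed_dataset(seed = 3)
  mk <- find_markers(ds, ds$cell_label, logfc_min = 0.25,
                     p_adj_max = 1e-10, min_pct = 0.1, groups = "Tcell")
  expect_true("CD3D" %in% mk$gene)
  expect_true(all(mk$logFC > 0.25 & mk$p_adj < 1e-10 & mk$pct_in > 0.1))
})

test_that("permuted labels produce no markers at stringent thresholds", {
  ds <- fixture_mixed_dataset(seed = 3)
  set.seed(31)
  for (perm in 1:5) {
    lab <- sample(ds$cell_label)
    mk <- find_markers(ds, lab, logfc_min = 0.25, p_adj_max = 1e-10,
                       min_pct = 0.1)
    expect_identical(nrow(mk), 0L)
  }
})

test_that("Wilcoxon p matches exact enumeration for small groups", {
  set.seed(32)
  for (rep in 1:15) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)  # continuous, tie-free
    m <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "g"))
    tab <- find_markers(m, rep(c("A", "B"), c(nx, ny)), filter = FALSE)
    expect_equal(tab$p[tab$cluster == "A"], wilcox_p_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- paste0("u", 1:1000)
  col <- gene_set_collection(list(
    hit = universe[1:10], other = universe[501:530],
    disjoint = universe[900:950]))
  res <- hypergeometric_enrichment(universe[1:10], col, universe)
  expect_equal(res$p[res$set == "hit"],
               hyper_tail_oracle(10, 10, 1000, 10), tolerance = 1e-12)
  expect_identical(res$overlap[res$set == "disjoint"], 0L)
  expect_equal(res$p[res$set == "disjoint"], 1)
  # markers = whole universe: every set hits p = 1 (overlap is forced)
  res_all <- hypergeometric_enrichment(universe, col, universe)
  expect_true(all(res_all$p == 1))
})

test_that("rank-based set score: extremes, invariance, centered null", {
  set.seed(33)
  x <- sample(500)
  names(x) <- paste0("g", 1:500)
  mm <- matrix(x, ncol = 1, dimnames = list(names(x), "c1"))
  top <- names(sort(x, decreasing = TRUE))[1:20]
  s_top <- sample_set_score(mm, top)
  rand_scores <- replicate(200,
    sample_set_score(mm, sample(names(x), 20)))
  expect_gt(s_top, max(rand_scores))
  # invariance to a monotone per-cell transform
  big <- matrix(rexp(500 * 30), nrow = 500,
                dimnames = list(names(x), paste0("c", 1:30)))
  expect_equal(sample_set_score(big, top),
               sample_set_score(exp(big / 50), top), tolerance = 1e-12)
  # null: random 20-gene set on shuffled data scores ~0
  null_m <- matrix(rexp(500 * 1000), nrow = 500,
                   dimnames = list(names(x), NULL))
  sc <- sample_set_score(null_m, sample(names(x), 20))
  expect_lt(abs(mean(sc)), 3 * stats::sd(sc) / sqrt(length(sc)))
  expect_error(sample_set_score(big, "nope"), "no set member")
})

test_that("differential pathway calls find the planted active set", {
  set.seed(34)
  n <- 80
  scores <- matrix(rnorm(5 * n), nrow = 5,
                   dimnames = list(paste0("path", 1:5), NULL))
  labels <- rep(c("A", "B"), each = n / 2)
  scores[1, labels == "A"] <- scores[1, labels == "A"] + 2
  for (use_limma in c(TRUE, FALSE)) {
    dp <- differential_pathways(scores, labels, use_limma = use_limma)
    expect_true("path1" %in% dp$set[dp$cluster == "A"])
    expect_false("path1" %in% dp$set[dp$cluster == "B"])
  }
  # the two testing routes agree on effect sizes exactly
  a <- differential_pathways(scores, labels, use_limma = TRUE,
                             filter = FALSE)
  b <- differential_pathways(scores, labels, use_limma = FALSE,
                             filter = FALSE)
  expect_equal(a$logFC, b$logFC, tolerance = 1e-9)
})

test_that("marker-pathway determination applies rank and tie-break rules", {
  markers <- data.frame(cluster = "c1",
                        gene = paste0("g", 1:12),
                        logFC = seq(2, 0.9, length.out = 12),
                        pct_in = 0.9, pct_out = 0.1,
                        p = 1e-12, p_adj = 1e-10)
  col <- gene_set_collection(list(
    small = c(paste0("g", 1:3), paste0("x", 1:27)),
    big = c(paste0("g", 1:3), paste0("y", 1:197)),
    no_marker = paste0("z", 1:30)))
  enr <- data.frame(set = c("small", "big", "no_marker"),
                    overlap = c(3, 3, 0), set_size = c(30, 200, 30),
                    n_markers = 12, p = c(1e-6, 1e-6, 1),
                    q = c(1e-5, 1e-5, 1), score = c(5, 5, 0))
  diff <- data.frame(cluster = "c1", set = c("small", "big", "no_marker"),
                     logFC = 1, p = 1e-4, p_adj = 1e-3)
  call <- marker_pathway("c1", enr, diff, markers, col)
  expect_true(call$called)
  expect_identical(call$pathway, "small")  # equal q: smaller set wins
  expect_identical(call$marker_gene, "g1")
  # single candidate containing the top marker
  call2 <- marker_pathway("c1", enr[enr$set == "big", ], diff, markers, col)
  expect_identical(call2$pathway, "big")
  # no intersected pathway contains a top-10 marker -> explicit no-call
  call3 <- marker_pathway("c1", enr[enr$set == "no_marker", ],
                          diff, markers, col)
  expect_false(call3$called)
  expect_true(is.na(call3$pathway))
})

test_that("polarization scores separate planted program axes", {
  uni <- gene_universe(600)
  cfg <- simulation_config(list(
    list(name = "d", platform = "droplet-count", tumor_type = "EPN",
         n_cells = 200,
         proportions = c(Myeloid = 0.5, MyeloidHypoxia = 0.5))), seed = 12)
  ds <- normalize_expression(qc_filter(simulate_single_cell(cfg)[[1]]))
  pol <- polarization_scores(ds, ds$cell_label,
                             set1 = uni$panels$Hypoxia,
                             set2 = uni$panels$M1,
                             axis_names = c("hypoxia", "m1"))
  expect_gt(pol$hypoxia[pol$cluster == "MyeloidHypoxia"],
            pol$hypoxia[pol$cluster == "Myeloid"])
  expect_identical(sum(pol$n_cells), length(ds$cell_ids))
})
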