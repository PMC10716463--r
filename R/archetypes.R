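#' Samples x features signature-score matrix for a bulk cohort
#'
#' Scores every signature on the cohort ([score_signature()]) and z-scores
#' each feature column across samples. The 3-feature archetype run uses the
#' myeloid (ITGAM-anchored), T-cell (CD3-anchored) and oligodendroglia
#' (MAG-anchored) scFes; the 9-feature run adds CD4, CD8, MG, BMDM and the
#' positive/negative immune-recruitment features.
#'
#' @param cohort a `BulkCohort`.
#' @param sigs named list of `SignatureSet`s (or plain gene vectors).
#' @param method scoring method passed to [score_signature()].
#' @return samples x features numeric matrix (z-scored columns).
#' @export
score_feature_matrix <- function(cohort, sigs, method = "zscore") {
  sc <- vapply(sigs, function(s)
    score_signature(cohort, s, method = method),
    numeric(ncol(cohort$matrix)))
  rownames(sc) <- cohort$samples$sample_id
  scale(sc)
}

#' Archetype discovery by k-means with DBI cluster-number selection
#'
#' Runs k-means (20 restarts, fixed seed) on the z-scored feature-score
#' matrix for each k in `k_range`, computes the Davies-Bouldin index per k,
#' and keeps the model at the DBI minimum. Near-duplicate centroids (within
#' `dup_tol`) are flagged.
#'
#' @param scores samples x features matrix (from [score_feature_matrix()]).
#' @param k_range candidate cluster numbers (default 2:10; must stay below
#'   the sample count).
#' @param nstart k-means restarts.
#' @param seed RNG seed.
#' @param dup_tol centroid-duplication warning tolerance.
#' @return an `ArchetypeModel`: scores, labels, k, centers, trace
#'   (k vs DBI), features used.
#' @export
discover_archetypes <- function(scores, k_range = 2:10, nstart = 20,
                                seed = 0L, dup_tol = 1e-6) {
  scores <- as.matrix(scores)
  if (max(k_range) > nrow(scores) - 1)
    stop("k_range exceeds n_samples - 1")
  if (min(k_range) < 2) stop("DBI is undefined at k = 1; k_range starts at 2")
  fits <- list()
  trace <- data.frame(k = k_range, dbi = NA_real_)
  for (i in seq_along(k_range)) {
    set.seed(seed)
    km <- stats::kmeans(scores, centers = k_range[i], nstart = nstart,
                        iter.max = 50)
    fits[[i]] <- km
    trace$dbi[i] <- davies_bouldin(scores, km$cluster)
  }
  best <- which.min(trace$dbi)
  km <- fits[[best]]
  if (min(stats::dist(km$centers)) < dup_tol)
    warning("near-duplicate centroids in the selected clustering")
  structure(list(scores = scores,
                 labels = stats::setNames(km$cluster, rownames(scores)),
                 k = k_range[best], centers = km$centers, trace = trace,
                 features = colnames(scores)),
            class = "ArchetypeModel")
}

#' @export
print.ArchetypeModel <- function(x, ...) {
  cat(sprintf("ArchetypeModel: k = %d over %d samples x %d features\n",
              x$k, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Per-archetype gene features from pairwise differential expression
#'
#' For archetype A against each of the other k-1 archetypes: per-gene Welch
#' t-test on the log2 cohort values (p < `p_max`, logFC > `logfc_min`), top
#' `top_n_logfc` passing genes by logFC; the k-1 lists are intersected. If
#' the intersection exceeds `max_genes`, the `max_genes` genes with the
#' lowest coefficient of variation within A that are detected (expression
#' > 0) in at least `detect_frac` of A's samples are kept; otherwise the
#' intersection is kept as is. An empty intersection yields an explicit
#' empty feature with a warning.
#'
#' @param cohort a `BulkCohort`.
#' @param labels per-sample archetype labels (aligned with cohort samples).
#' @param p_max,logfc_min pairwise DEG thresholds (defaults 0.05 / 1).
#' @param top_n_logfc per-contrast cap (default 3000).
#' @param max_genes feature size cap (default 20).
#' @param detect_frac required detection fraction within the archetype.
#' @return named list: archetype -> character vector of feature genes
#'   (possibly empty).
#' @export
archetype_gene_features <- function(cohort, labels, p_max = 0.05,
                                    logfc_min = 1, top_n_logfc = 3000,
                                    max_genes = 20, detect_frac = 0.8) {
  m <- cohort$matrix
  stopifnot(ncol(m) == length(labels))
  archs <- sort(unique(labels))
  out <- list()
  for (a in archs) {
    in_a <- labels == a
    lists <- list()
    for (b in setdiff(archs, a)) {
      in_b <- labels == b
      lfc <- rowMeans(m[, in_a, drop = FALSE]) -
        rowMeans(m[, in_b, drop = FALSE])
      p <- welch_p_rows(m[, in_a, drop = FALSE], m[, in_b, drop = FALSE])
      pass <- which(p < p_max & lfc > logfc_min)
      pass <- pass[order(-lfc[pass])]
      lists[[as.character(b)]] <-
        rownames(m)[utils::head(pass, top_n_logfc)]
    }
    feat <- Reduce(intersect, lists)
    if (!length(feat)) {
      warning("empty gene feature for archetype ", a,
              "; archetype kept with parent feature scores")
      out[[as.character(a)]] <- character(0)
      next
    }
    if (length(feat) > max_genes) {
      sub <- m[feat, in_a, drop = FALSE]
      detected <- rowMeans(sub > 0) >= detect_frac
      lin <- 2^sub - 1
      cv <- apply(lin, 1, stats::sd) / pmax(rowMeans(lin), 1e-12)
      cand <- feat[detected]
      cand <- cand[order(cv[match(cand, feat)])]
      feat <- utils::head(cand, max_genes)
    }
    out[[as.character(a)]] <- feat
  }
  out
}

# vectorized Welch t p-values across rows of two column-blocks
welch_p_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)),
                     1e-300)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1
  p
}

#' Project archetype labels onto an external cohort
#'
#' Scores external samples on every archetype's gene feature (mean z-score)
#' and assigns the argmax archetype; a sample whose top-two score margin
#' falls below `tau` is labeled "unassigned". Archetypes with empty features
#' are skipped.
#'
#' @param external a `BulkCohort`.
#' @param features named list archetype -> gene feature (from
#'   [archetype_gene_features()]).
#' @param tau unassigned margin (default 0.1).
#' @return named character vector of per-sample archetype labels.
#' @export
project_archetypes <- function(external, features, tau = 0.1) {
  features <- features[lengths(features) > 0]
  if (!length(features)) stop("no non-empty archetype feature to project")
  sc <- vapply(features, function(gs)
    score_signature(external, gs), numeric(ncol(external$matrix)))
  lab <- colnames(sc)[max.col(sc, ties.method = "first")]
  if (ncol(sc) > 1) {
    margin <- apply(sc, 1, function(r) {
      s <- sort(r, decreasing = TRUE); s[1] - s[2]
    })
    lab[margin < tau] <- "unassigned"
  }
  stats::setNames(lab, external$samples$sample_id)
}

#' Survival association of groups or scores
#'
#' Kaplan-Meier curves and log-rank p across groups, or a univariate Cox
#' model (hazard ratio with 95% CI) for a continuous score. Input with no
#' events is an error.
#'
#' @param x per-sample group labels (character/factor) or numeric scores.
#' @param samples data.frame with `time_months` and `event`.
#' @return a `SurvivalResult`: `km` (survfit, groups only), `logrank_p`
#'   (groups only), `cox` (data.frame HR, lo, hi, p).
#' @export
survival_association <- function(x, samples) {
  stopifnot(all(c("time_months", "event") %in% names(samples)))
  if (sum(samples$event) == 0) stop("no events in the survival data")
  surv <- survival::Surv(samples$time_months, samples$event)
  if (is.numeric(x)) {
    cx <- survival::coxph(surv ~ x)
    s <- summary(cx)
    res <- structure(list(km = NULL, logrank_p = NA_real_,
                          cox = data.frame(HR = s$conf.int[1, "exp(coef)"],
                                           lo = s$conf.int[1, "lower .95"],
                                           hi = s$conf.int[1, "upper .95"],
                                           p = s$coefficients[1, "Pr(>|z|)"])),
                     class = "SurvivalResult")
    return(res)
  }
  g <- factor(x)
  df <- data.frame(time = samples$time_months, event = samples$event, g = g)
  km <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1,
                             lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ g, data = df)
  s <- summary(cx)
  structure(list(km = km, logrank_p = logrank_p,
                 cox = data.frame(term = rownames(s$conf.int),
                                  HR = s$conf.int[, "exp(coef)"],
                                  lo = s$conf.int[, "lower .95"],
                                  hi = s$conf.int[, "upper .95"],
                                  p = s$coefficients[, "Pr(>|z|)"],
                                  row.names = NULL)),
            class = "SurvivalResult")
}
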