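#' Simulation configuration for synthetic single-cell datasets
#'
#' Describes a set of single-cell datasets to simulate: one entry per dataset
#' with platform, tumor type, cell count and cell-type proportions. Droplet
#' datasets are drawn as negative-binomial UMI counts (gene-level means from
#' log-normal programs, dispersion 0.5) with Bernoulli dropout; full-length
#' datasets as exponentiated Gaussian programs rescaled per cell to TPM
#' (1e6 total) and stored pre-log. Microglia (MG) and bone-marrow-derived
#' macrophage (BMDM) types share conserved core-gene programs across platforms
#' while their canonical markers suffer extra dropout on the droplet platform,
#' emulating the platform gap that motivates cross-platform label transfer.
#'
#' @param datasets list of per-dataset specs; each a list with `name`,
#'   `platform` ("droplet-count"/"full-length-tpm"), `tumor_type`, `n_cells`,
#'   `proportions` (named, summing to 1) and optionally `donors`.
#' @param seed integer; fixes all randomness end-to-end.
#' @param n_filler anonymous background genes in the universe.
#' @param boost log2 over-expression of a type's program genes.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param target_total expected UMI total per droplet cell.
#' @param dropout baseline Bernoulli dropout rate per platform (named vector).
#' @param marker_dropout extra dropout applied to canonical MG/BMDM markers on
#'   the droplet platform only.
#' @param noise_sd per-cell-per-gene Gaussian sd (log2) for full-length data.
#' @param assignment "exact" (deterministic type counts via largest remainder)
#'   or "multinomial".
#' @param qc_violations number of cells per droplet dataset deliberately made
#'   to fail one QC rule each (cycling low-UMI / few-genes / high-mito).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(datasets, seed = 1L, n_filler = 600,
                              boost = 3, dispersion = 0.5,
                              target_total = 6000,
                              dropout = c("droplet-count" = 0.10,
                                          "full-length-tpm" = 0.02),
                              marker_dropout = 0.8, noise_sd = 1.0,
                              assignment = c("exact", "multinomial"),
                              qc_violations = 0L) {
  assignment <- match.arg(assignment)
  for (d in datasets) {
    stopifnot(!is.null(d$name), !is.null(d$platform), !is.null(d$n_cells))
    if (d$n_cells <= 0) stop("non-positive cell count in dataset ", d$name)
    if (abs(sum(d$proportions) - 1) > 1e-8)
      stop("proportions do not sum to 1 in dataset ", d$name)
  }
  structure(list(datasets = datasets, seed = as.integer(seed),
                 n_filler = n_filler, boost = boost, dispersion = dispersion,
                 target_total = target_total, dropout = dropout,
                 marker_dropout = marker_dropout, noise_sd = noise_sd,
                 assignment = assignment,
                 qc_violations = as.integer(qc_violations)),
            class = "SimulationConfig")
}

# log2 mean program of one cell type: baseline + boost on its program genes;
# a type's own program genes are floored to a moderate baseline first (marker
# and program genes are, by construction, expressed genes in their type)
type_log2_means <- function(universe, base, cell_type, boost) {
  mu <- base
  pg <- type_program_genes(universe, cell_type)
  mu[pg] <- pmax(mu[pg], 1) + boost
  mu
}

# deterministic per-type counts by largest remainder
exact_type_counts <- function(proportions, n) {
  raw <- proportions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

#' Simulate multi-platform single-cell datasets with planted cell types
#'
#' @param config a [simulation_config()].
#' @return named list of [expression_dataset()] objects with `cell_label`
#'   holding the planted ground-truth type per cell.
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  uni <- gene_universe(config$n_filler)
  base <- base_log2_means(uni, config$seed)
  canon <- c(uni$panels$MG_canonical, uni$panels$BMDM_canonical)
  out <- list()
  for (i in seq_along(config$datasets)) {
    d <- config$datasets[[i]]
    set.seed(config$seed + 1000L * i)
    n <- d$n_cells
    types <- names(d$proportions)
    if (length(types) < 2 && is.null(d$allow_single_type))
      stop("need >=2 cell types per dataset (", d$name, ")")
    counts_per_type <- if (config$assignment == "exact")
      exact_type_counts(d$proportions, n)
    else as.vector(stats::rmultinom(1, n, d$proportions))
    labels <- rep(types, counts_per_type)
    G <- length(uni$genes)
    mat <- matrix(0, nrow = n, ncol = G)
    drop_rate <- unname(config$dropout[d$platform])
    for (t in types) {
      idx <- which(labels == t)
      if (!length(idx)) next
      mu <- type_log2_means(uni, base, t, config$boost)
      if (d$platform == "droplet-count") {
        lam <- 2^mu
        lam <- lam / sum(lam) * config$target_total
        sf <- exp(stats::rnorm(length(idx), 0, 0.25))
        block <- matrix(
          stats::rnbinom(length(idx) * G,
                         mu = rep(sf, times = G) * rep(lam, each = length(idx)),
                         size = 1 / config$dispersion),
          nrow = length(idx), ncol = G)
      } else {
        block <- 2^(matrix(stats::rnorm(length(idx) * G, 0, config$noise_sd),
                           nrow = length(idx)) +
                    matrix(mu, nrow = length(idx), ncol = G, byrow = TRUE))
      }
      mat[idx, ] <- block
    }
    if (drop_rate > 0)
      mat <- mat * matrix(stats::rbinom(n * G, 1, 1 - drop_rate), n, G)
    if (d$platform == "droplet-count" && config$marker_dropout > 0) {
      ci <- match(canon, uni$genes)
      keep <- matrix(stats::rbinom(n * length(ci), 1,
                                   1 - config$marker_dropout), n, length(ci))
      mat[, ci] <- mat[, ci] * keep
    }
    if (d$platform == "full-length-tpm") {
      tot <- rowSums(mat)
      mat <- mat / pmax(tot, 1e-9) * 1e6
    }
    if (d$platform == "droplet-count" && config$qc_violations > 0) {
      nv <- min(config$qc_violations, n)
      modes <- rep(c("low_umi", "few_genes", "high_mito"), length.out = nv)
      mt1 <- match("MT-ND1", uni$genes)
      for (j in seq_len(nv)) {
        v <- mat[j, ]
        if (modes[j] == "low_umi") {
          v <- floor(v * (900 / max(sum(v), 1)))
        } else if (modes[j] == "few_genes") {
          keep_g <- order(v, decreasing = TRUE)[seq_len(150)]
          v[-keep_g] <- 0
          v[keep_g] <- v[keep_g] + 20  # keep the UMI total comfortably high
        } else {
          v[mt1] <- v[mt1] + ceiling(sum(v) * 0.5)
        }
        mat[j, ] <- v
      }
    }
    donors <- d$donors %||% paste0(d$name, "_don", 1:3)
    out[[d$name]] <- expression_dataset(
      matrix = mat, gene_ids = uni$genes,
      cell_ids = sprintf("%s_c%05d", d$name, seq_len(n)),
      platform = d$platform, tumor_type = d$tumor_type %||% "unknown",
      donor = rep_len(donors, n), cell_label = labels)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default archetype plan for the pseudo-bulk cohort
#'
#' Four immune-stromal-tumor archetypes with distinct planted compositions
#' (mixture weights over the simulated cell-type programs) and
#' exponential-survival hazards: an immune-rich archetype with good prognosis,
#' an immune-desert archetype dominated by tumor cells carrying the
#' negative immune-recruitment program, a stromal (oligodendroglia) archetype,
#' and a myeloid-centric archetype.
#'
#' @param n_per_archetype samples per archetype.
#' @return list of archetype specs (name, n, hazard per month, composition,
#'   tumor_type).
#' @export
default_archetype_plan <- function(n_per_archetype = 60) {
  list(
    list(name = "immune_rich", n = n_per_archetype, hazard = 1 / 45,
         tumor_type = "MB",
         composition = c(Tcell = 0.20, CD4T = 0.10, CD8T = 0.10,
                         Myeloid = 0.20, MG = 0.05, BMDM = 0.05, OG = 0.05,
                         TumorPosIR = 0.25)),
    list(name = "immune_desert", n = n_per_archetype, hazard = 1 / 15,
         tumor_type = "EPN",
         composition = c(Tumor = 0.50, TumorNegIR = 0.30, OG = 0.05,
                         Myeloid = 0.10, Tcell = 0.05)),
    list(name = "stromal_rich", n = n_per_archetype, hazard = 1 / 30,
         tumor_type = "PIDHM",
         composition = c(OG = 0.50, Tumor = 0.25, Tcell = 0.10,
                         Myeloid = 0.15)),
    list(name = "myeloid_centric", n = n_per_archetype, hazard = 1 / 22,
         tumor_type = "DIPG",
         composition = c(MG = 0.35, BMDM = 0.20, Myeloid = 0.15,
                         Tumor = 0.25, Tcell = 0.05))
  )
}

#' Simulate a pseudo-bulk cohort with planted archetypes and survival
#'
#' Per-sample expression is a mixture of cell-type programs weighted by the
#' sample's archetype composition, with Gaussian noise on the log2 scale.
#' Survival times are exponential with the archetype-specific hazard and
#' independent exponential censoring (administrative cap 120 months).
#'
#' @param config a [simulation_config()] (supplies universe, seed, programs).
#' @param archetype_plan list of archetype specs, see
#'   [default_archetype_plan()].
#' @param noise_sd log2-scale Gaussian noise sd.
#' @param censor_rate rate of the independent censoring distribution.
#' @return a [bulk_cohort()] whose `samples` carries a `archetype` column with
#'   the planted ground truth.
#' @export
simulate_bulk_cohort <- function(config, archetype_plan = default_archetype_plan(),
                                 noise_sd = 0.3, censor_rate = 1 / 80) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!length(archetype_plan)) stop("empty archetype plan")
  uni <- gene_universe(config$n_filler)
  base <- base_log2_means(uni, config$seed)
  set.seed(config$seed + 777L)
  cols <- list(); meta <- list()
  for (a in archetype_plan) {
    if (is.null(a$composition) || !length(a$composition)) stop("empty archetype")
    lin <- 0
    for (t in names(a$composition))
      lin <- lin + a$composition[[t]] * 2^type_log2_means(uni, base, t, config$boost)
    y0 <- log2(lin + 1)
    block <- matrix(y0, nrow = length(y0), ncol = a$n) +
      matrix(stats::rnorm(length(y0) * a$n, 0, noise_sd), ncol = a$n)
    block[block < 0] <- 0
    tt <- stats::rexp(a$n, rate = a$hazard)
    cc <- pmin(stats::rexp(a$n, rate = censor_rate), 120)
    cols[[a$name]] <- block
    meta[[a$name]] <- data.frame(
      archetype = a$name, tumor_type = a$tumor_type %||% "unknown",
      time_months = pmin(tt, cc), event = as.integer(tt <= cc))
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- uni$genes
  samples <- do.call(rbind, meta)
  samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  rownames(samples) <- NULL
  bulk_cohort(mat, samples[, c("sample_id", "tumor_type", "time_months",
                               "event", "archetype")])
}

#' Simulate a sorted purified-cell compendium
#'
#' Pure per-type expression profiles (log2 scale, program mean plus Gaussian
#' noise), emulating a compendium of sorted immune / stromal / tumor cell
#' populations used to check signature specificity.
#'
#' @param config a [simulation_config()].
#' @param types cell types to include.
#' @param n_per_type profiles per type.
#' @param noise_sd log2 noise sd.
#' @return list with `matrix` (genes x profiles, log2) and `cell_type`.
#' @export
simulate_sorted_compendium <- function(config,
                                       types = c("Tcell", "CD4T", "CD8T",
                                                 "Bcell", "NK", "Myeloid",
                                                 "MG", "BMDM", "OG", "Tumor"),
                                       n_per_type = 12, noise_sd = 0.6) {
  uni <- gene_universe(config$n_filler)
  base <- base_log2_means(uni, config$seed)
  set.seed(config$seed + 555L)
  blocks <- lapply(types, function(t) {
    mu <- type_log2_means(uni, base, t, config$boost)
    matrix(mu, nrow = length(mu), ncol = n_per_type) +
      matrix(stats::rnorm(length(mu) * n_per_type, 0, noise_sd),
             ncol = n_per_type)
  })
  mat <- do.call(cbind, blocks)
  mat[mat < 0] <- 0
  rownames(mat) <- uni$genes
  colnames(mat) <- sprintf("%s_p%02d", rep(types, each = n_per_type),
                           rep(seq_len(n_per_type), length(types)))
  list(matrix = mat, cell_type = rep(types, each = n_per_type))
}

#' Simulate tumor-cell pseudobulk with planted immune-recruitment programs
#'
#' Generates per-sample tumor-component pseudobulk expression where the
#' positive-IR program increases monotonically with immune content and the
#' negative-IR program decreases with it; all other genes are noise.
#'
#' @param config a [simulation_config()].
#' @param n_samples number of samples.
#' @param effect slope (log2 units per unit immune content) of the IR programs.
#' @param noise_sd residual log2 noise sd.
#' @return list with `matrix` (genes x samples, log2), `immune_content`
#'   (per-sample, in 0..1) and the planted `pos_genes` / `neg_genes`.
#' @export
simulate_ir_pseudobulk <- function(config, n_samples = 40, effect = 3,
                                   noise_sd = 0.5) {
  uni <- gene_universe(config$n_filler)
  base <- base_log2_means(uni, config$seed)
  set.seed(config$seed + 333L)
  u <- stats::runif(n_samples)
  G <- length(uni$genes)
  pos <- uni$panels$posIR; neg <- uni$panels$negIR
  # IR programs are well-expressed tumor genes: raise their baseline so the
  # planted monotone relation is not flattened by truncation at zero
  base[c(pos, neg)] <- base[c(pos, neg)] + 3
  mat <- matrix(base, nrow = G, ncol = n_samples) +
    matrix(stats::rnorm(G * n_samples, 0, noise_sd), ncol = n_samples)
  mat[match(pos, uni$genes), ] <- mat[match(pos, uni$genes), ] +
    matrix(effect * u, nrow = length(pos), ncol = n_samples, byrow = TRUE)
  mat[match(neg, uni$genes), ] <- mat[match(neg, uni$genes), ] -
    matrix(effect * u, nrow = length(neg), ncol = n_samples, byrow = TRUE)
  mat[mat < 0] <- 0
  rownames(mat) <- uni$genes
  colnames(mat) <- sprintf("ps%03d", seq_len(n_samples))
  list(matrix = mat, immune_content = u, pos_genes = pos, neg_genes = neg)
}
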