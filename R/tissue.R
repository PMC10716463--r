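#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: q_i = min over k >= rank(i) of
#' (m/k) p_(k), capped at 1. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Tissue-preference odds ratios for cell subsets
#'
#' For every (subset i, tissue j) a 2x2 contingency table is built: a = cells
#' of subset i in tissue j, b = subset i elsewhere, c = non-i cells in j,
#' d = non-i elsewhere. The sample odds ratio OR = (a d)/(b c) quantifies the
#' preference (Haldane 0.5 correction applied, and flagged, only when some
#' table cell is zero); the two-sided Fisher exact test gives p, adjusted by
#' Benjamini-Hochberg across all (i, j) pairs. OR above `or_high` labels the
#' pair "enriched", below `or_low` "depleted", otherwise "none". The
#' companion Ro/e statistic (observed over expected count) is also reported.
#'
#' @param cells data.frame with columns `subset` and `tissue`, one row per
#'   cell.
#' @param or_high enrichment OR threshold (default 1.5).
#' @param or_low depletion OR threshold (default 0.5).
#' @return a `PreferenceTable` data.frame: subset, tissue, a, b, c, d, OR,
#'   haldane, p, q, label, roe.
#' @export
tissue_preference <- function(cells, or_high = 1.5, or_low = 0.5) {
  stopifnot(all(c("subset", "tissue") %in% names(cells)))
  tab <- table(cells$subset, cells$tissue)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 subsets and 2 tissues")
  if (any(rowSums(tab) == 0)) stop("a subset has zero cells")
  if (any(colSums(tab) == 0)) stop("a tissue has zero cells")
  total <- sum(tab)
  rows <- list()
  for (i in rownames(tab)) for (j in colnames(tab)) {
    a <- tab[i, j]
    b <- sum(tab[i, ]) - a
    c_ <- sum(tab[, j]) - a
    d <- total - a - b - c_
    haldane <- any(c(a, b, c_, d) == 0)
    or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
          else (a * d) / (b * c_)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                   byrow = TRUE))$p.value
    roe <- a / (sum(tab[i, ]) * sum(tab[, j]) / total)
    rows[[paste(i, j)]] <- data.frame(
      subset = i, tissue = j, a = a, b = b, c = c_, d = d,
      OR = or, haldane = haldane, p = p, roe = roe)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$label <- ifelse(out$OR > or_high, "enriched",
                      ifelse(out$OR < or_low, "depleted", "none"))
  class(out) <- c("PreferenceTable", "data.frame")
  out[, c("subset", "tissue", "a", "b", "c", "d", "OR", "haldane",
          "p", "q", "label", "roe")]
}
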