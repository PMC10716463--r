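# Independent oracles, written from the definitions and kept free of any
# package internals they are used to check.

# two-sided Fisher exact p for table rbind(c(a,b),c(c,d)): sum of the
# probabilities of all tables with the same margins whose probability does
# not exceed the observed one (up to fisher.test's relative tolerance)
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total (subset i)
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# naive O(m^2) BH step-up: q_i = min over k with p_(k) >= p_i of m p_(k) / k
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:m, function(k) m * p[ord[k]] / k, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Davies-Bouldin from the definition, plain loops throughout
dbi_oracle <- function(x, labels) {
  x <- as.matrix(x)
  cl <- sort(unique(labels))
  cents <- list(); scat <- numeric(length(cl))
  for (i in seq_along(cl)) {
    pts <- x[labels == cl[i], , drop = FALSE]
    cents[[i]] <- apply(pts, 2, mean)
    dsum <- 0
    for (r in seq_len(nrow(pts)))
      dsum <- dsum + sqrt(sum((pts[r, ] - cents[[i]])^2))
    scat[i] <- dsum / nrow(pts)
  }
  total <- 0
  for (i in seq_along(cl)) {
    worst <- -Inf
    for (j in seq_along(cl)) {
      if (i == j) next
      sep <- sqrt(sum((cents[[i]] - cents[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / sep)
    }
    total <- total + worst
  }
  total / length(cl)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (tie-free data), matching the doubled-tail convention
wilcox_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# closed-form hypergeometric upper tail P(X >= k)
hyper_tail_oracle <- function(k, set_size, universe_size, n_draw) {
  sum(stats::dhyper(k:min(set_size, n_draw), set_size,
                    universe_size - set_size, n_draw))
}
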