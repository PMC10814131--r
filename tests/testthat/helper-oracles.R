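# Independent, loop-based oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's vectorised
# code paths.

# Build a ct_table from a bare matrix, one donor cycle per condition block.
make_table <- function(m, conditions, donors = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- paste0("smp", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("G", seq_len(ncol(m)))
  if (is.null(donors)) donors <- paste0("D", seq_len(nrow(m)))
  ct_table(m, data.frame(sample = rownames(m), donor = donors,
                         condition = conditions, stringsAsFactors = FALSE))
}

# Mean over partner genes of the SD of pairwise Ct differences, by
# explicit loops (comparative delta-Ct / geNorm M building block).
oracle_pairwise_mean_sd <- function(m, sdfun = stats::sd) {
  g <- ncol(m)
  out <- numeric(g)
  for (i in seq_len(g)) {
    acc <- 0
    for (j in seq_len(g)) {
      if (j == i) next
      diffs <- numeric(nrow(m))
      for (s in seq_len(nrow(m))) diffs[s] <- m[s, i] - m[s, j]
      acc <- acc + sdfun(diffs)
    }
    out[i] <- acc / (g - 1)
  }
  names(out) <- colnames(m)
  out
}

# Literal step-by-step transcription of the ungrouped model-based
# variance decomposition: double-centred residuals, per-gene residual
# mean square, finite-panel bias correction, sqrt floored at zero.
oracle_normfinder <- function(m) {
  g <- ncol(m); n <- nrow(m)
  z <- numeric(g)
  for (i in seq_len(g)) {
    ss <- 0
    for (s in seq_len(n)) {
      r <- m[s, i] - mean(m[, i]) - mean(m[s, ]) + mean(m)
      ss <- ss + r^2
    }
    z[i] <- ss / (n - 1)
  }
  v <- numeric(g)
  for (i in seq_len(g)) v[i] <- (z[i] - sum(z) / ((g - 1) * g)) * g / (g - 2)
  out <- sqrt(pmax(v, 0))
  names(out) <- colnames(m)
  out
}

# Brute-force UPGMA: returns the cophenetic distance matrix. Average
# linkage distance between clusters = mean over all original leaf pairs.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  cluster_dist <- function(a, b) {
    tot <- 0
    for (x in a) for (y in b) tot <- tot + d[x, y]
    tot / (length(a) * length(b))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    for (x in a) for (y in b) coph[x, y] <- coph[y, x] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters <- clusters[-best[2]]
  }
  dimnames(coph) <- dimnames(d)
  coph
}
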