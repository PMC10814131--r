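# Four reference-gene stability algorithms plus descriptive statistics.
# All operate on a complete Ct matrix for a chosen sample subset and
# return a stability_result: per-gene value (lower = more stable) + rank.

.stab_matrix <- function(table, min_genes = 2, min_samples = 2) {
  stopifnot(is.ct_table(table))
  m <- table$ct
  if (anyNA(m))
    stop("missing Ct cells present; stability methods require a complete ",
         "matrix (collapse or remove incomplete samples first)", call. = FALSE)
  if (ncol(m) < min_genes)
    stop("need at least ", min_genes, " genes", call. = FALSE)
  if (nrow(m) < min_samples)
    stop("need at least ", min_samples, " samples", call. = FALSE)
  m
}

.stability_result <- function(method, values, samples, genorm_pair = NULL,
                              ranks = NULL) {
  if (is.null(ranks)) ranks <- rank(values, ties.method = "average")
  out <- data.frame(gene = names(values), value = unname(values),
                    rank = unname(ranks), stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  structure(out, method = method, samples = samples,
            genorm_pair = genorm_pair,
            class = c("stability_result", "data.frame"))
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> method = %s, %d samples\n",
              attr(x, "method"), length(attr(x, "samples"))))
  if (!is.null(attr(x, "genorm_pair")))
    cat("final pair:", paste(attr(x, "genorm_pair"), collapse = " | "), "\n")
  print.data.frame(x)
  invisible(x)
}

#' Per-gene descriptive statistics of a Ct table
#'
#' Mean, population standard deviation (n denominator), minimum, maximum
#' and range of each gene's Ct values across all samples of the table —
#' the first, model-free look at how much each candidate fluctuates.
#'
#' @param table A complete `ct_table` with at least 2 samples.
#' @return data.frame with columns `gene`, `mean`, `sd`, `min`, `max`,
#'   `range` (all in cycles).
#' @examples
#' ct_descriptives(asc_ct())
#' @export
ct_descriptives <- function(table) {
  m <- .stab_matrix(table, min_genes = 1, min_samples = 2)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(
    gene = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, pop_sd),
    min = apply(m, 2, min),
    max = apply(m, 2, max),
    range = apply(m, 2, function(x) max(x) - min(x)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Comparative delta-Ct stability
#'
#' For every ordered pair of genes (i, j) the per-sample difference
#' \eqn{\Delta Ct_{ij}} is formed; gene i's stability value is the mean,
#' over all partners j, of the sample standard deviation (n - 1
#' denominator) of that difference series. A gene that co-varies tightly
#' with every other candidate scores low.
#'
#' @param table A complete `ct_table` with >= 2 genes and >= 3 samples.
#' @return A `stability_result` (values in cycles; rank 1 = most stable).
#' @examples
#' delta_ct_stability(subset_conditions(asc_ct(), "F"))
#' @export
delta_ct_stability <- function(table) {
  m <- .stab_matrix(table, min_genes = 2, min_samples = 3)
  g <- ncol(m)
  vals <- vapply(seq_len(g), function(i) {
    mean(vapply(setdiff(seq_len(g), i),
                function(j) stats::sd(m[, i] - m[, j]), numeric(1)))
  }, numeric(1))
  names(vals) <- colnames(m)
  .stability_result("delta_ct", vals, rownames(m))
}

#' BestKeeper descriptive stability
#'
#' Reports, per gene, the mean absolute deviation (MAD) of its Ct values
#' from their arithmetic mean — the dispersion statistic the BestKeeper
#' tool prints as its "SD" column — and ranks genes by it. The BestKeeper
#' index (per-sample arithmetic mean Ct across all candidates) and each
#' gene's Pearson correlation with the index are attached for inspection
#' but do not enter the ranking. A `variant = "geometric"` flag computes
#' deviations from the per-gene geometric mean of linearised quantities
#' (the original tool's convention), which differs negligibly at typical
#' Ct magnitudes.
#'
#' @param table A complete `ct_table` with >= 3 samples.
#' @param variant `"arithmetic"` (default) or `"geometric"` central value.
#' @return A `stability_result` with attributes `index` (per-sample mean
#'   Ct) and `index_cor` (per-gene Pearson r with the index; `NA` for a
#'   constant gene).
#' @examples
#' bestkeeper(subset_conditions(asc_ct(), "F"))
#' @export
bestkeeper <- function(table, variant = c("arithmetic", "geometric")) {
  variant <- match.arg(variant)
  m <- .stab_matrix(table, min_genes = 1, min_samples = 3)
  central <- if (variant == "arithmetic") colMeans(m) else
    -log2(colMeans(2^(-m)))   # Ct of the geometric-mean quantity
  vals <- colMeans(abs(sweep(m, 2, central)))
  names(vals) <- colnames(m)
  index <- rowMeans(m)
  index_cor <- apply(m, 2, function(x) {
    if (stats::sd(x) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(x, index)
  })
  res <- .stability_result("bestkeeper", vals, rownames(m))
  attr(res, "index") <- index
  attr(res, "index_cor") <- index_cor
  res
}

#' NormFinder model-based stability
#'
#' Treats Ct as a log2-scale expression measure and decomposes its
#' variation into gene and sample main effects plus a gene-specific
#' residual variance. Without groups, the matrix is double-centred
#' (gene means and sample means removed, grand mean restored) and each
#' gene's residual mean square is corrected for the bias introduced by
#' centring over a finite gene panel:
#'
#' \deqn{\hat\sigma^2_g = \frac{g}{g-2}\Big(z_g - \frac{\sum_h z_h}{(g-1)\,g}\Big),
#'   \quad z_g = \frac{\sum_s r_{gs}^2}{n-1}}
#'
#' Stability is \eqn{\sqrt{\max(\hat\sigma^2_g, 0)}}; at very small n the
#' estimate can go negative and is floored at zero, which may tie the most
#' stable genes exactly. With `groups`, the grouped variance-decomposition
#' model is used: per-group residual variances estimated as above, group
#' differences shrunk towards zero by their estimated signal-to-noise
#' ratio, and stability is the average across groups of the absolute
#' shrunken group difference plus the sampling standard error.
#'
#' @param table A complete `ct_table` with >= 3 genes and >= 2 samples.
#' @param groups Optional per-sample group labels (e.g. condition); each
#'   group needs >= 2 samples and there must be >= 2 groups.
#' @return A `stability_result` (values in model-SD units, cycles scale).
#' @examples
#' normfinder(subset_conditions(asc_ct(), "F"))
#' @export
normfinder <- function(table, groups = NULL) {
  m <- .stab_matrix(table, min_genes = 3, min_samples = 2)
  if (is.null(groups)) {
    vals <- .normfinder_ungrouped(m)
  } else {
    if (length(groups) != nrow(m))
      stop("`groups` must give one label per sample", call. = FALSE)
    tab <- table(groups)
    if (any(tab < 2))
      stop("every group needs >= 2 samples; too small: ",
           paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
    if (length(tab) < 2)
      stop("grouped model needs >= 2 groups", call. = FALSE)
    vals <- .normfinder_grouped(m, as.character(groups))
  }
  .stability_result("normfinder", vals, rownames(m))
}

.normfinder_ungrouped <- function(m) {
  g <- ncol(m); n <- nrow(m)
  if (n < 2) stop("ungrouped model needs >= 2 samples", call. = FALSE)
  r <- sweep(sweep(m, 2, colMeans(m)), 1, rowMeans(m)) + mean(m)
  z <- colSums(r^2) / (n - 1)
  v <- (z - sum(z) / ((g - 1) * g)) * g / (g - 2)
  out <- sqrt(pmax(v, 0))
  names(out) <- colnames(m)
  out
}

.normfinder_grouped <- function(m, groups) {
  g <- ncol(m)
  lev <- unique(groups)
  J <- length(lev)
  n_j <- vapply(lev, function(l) sum(groups == l), numeric(1))
  # per-group residual variances with the finite-panel correction
  sig2 <- sapply(lev, function(l) {
    pmax(0, {
      mj <- m[groups == l, , drop = FALSE]
      z <- colSums((sweep(sweep(mj, 2, colMeans(mj)), 1, rowMeans(mj)) +
                      mean(mj))^2) / (nrow(mj) - 1)
      (z - sum(z) / ((g - 1) * g)) * g / (g - 2)
    })
  })                                            # genes x groups
  # group differences: gene-by-group interaction of the cell means
  cell <- sapply(lev, function(l) colMeans(m[groups == l, , drop = FALSE]))
  d <- sweep(sweep(cell, 1, rowMeans(cell)), 2, colMeans(cell)) + mean(cell)
  samp_var <- sweep(sig2, 2, n_j, `/`)          # Var(d-hat | d)
  gamma2 <- max(0, sum(d^2) / ((g - 1) * (J - 1)) - mean(samp_var))
  shrink <- gamma2 / (gamma2 + samp_var)
  if (gamma2 == 0) shrink[] <- 0
  rho <- rowMeans(abs(d * shrink) + sqrt(samp_var))
  names(rho) <- colnames(m)
  rho
}

#' geNorm M-value with stepwise exclusion
#'
#' The pairwise variation V(i, j) between two genes is the standard
#' deviation of their per-sample Ct difference (the log2 expression
#' ratio at efficiency 2); a gene's M value is the mean of V(i, j) over
#' all other candidates. The least stable gene (largest M) is recorded
#' and removed, M values are recomputed, and the procedure repeats until
#' two genes remain: the final pair, which shares one M value — the SD of
#' its mutual difference series. Each gene's reported value is its M at
#' the step of its exclusion.
#'
#' @param table A complete `ct_table` with >= 2 genes and >= 3 samples
#'   (with exactly 2 genes the final-pair M is returned directly).
#' @param denominator `"sample"` (n - 1, default) or `"population"` (n)
#'   SD denominator.
#' @return A `stability_result`; the attribute `genorm_pair` names the two
#'   surviving genes and the ranks follow the pair rule (both final genes
#'   rank 1, the next gene 3, then 4, ..., g). Exact ties in M during
#'   exclusion are broken by removing the gene occurring later in column
#'   order.
#' @examples
#' genorm(subset_conditions(asc_ct(), "F"))
#' @export
genorm <- function(table, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  m <- .stab_matrix(table, min_genes = 2, min_samples = 3)
  sdfun <- if (denominator == "sample") stats::sd else
    function(x) sqrt(mean((x - mean(x))^2))
  genes <- colnames(m)
  cur <- genes
  vals <- stats::setNames(numeric(length(genes)), genes)
  ranks <- stats::setNames(numeric(length(genes)), genes)
  pos <- length(genes)
  repeat {
    M <- vapply(cur, function(i) {
      mean(vapply(setdiff(cur, i),
                  function(j) sdfun(m[, i] - m[, j]), numeric(1)))
    }, numeric(1))
    if (length(cur) == 2) {
      vals[cur] <- sdfun(m[, cur[1]] - m[, cur[2]])
      ranks[cur] <- 1
      break
    }
    worst <- max(M)
    w <- cur[which(M >= worst - 1e-12)]
    w <- w[length(w)]                 # tie-break: later column excluded
    vals[w] <- M[w]
    ranks[w] <- pos
    pos <- pos - 1
    cur <- setdiff(cur, w)
  }
  .stability_result("genorm", vals, rownames(m),
                    genorm_pair = sort(cur), ranks = ranks)
}

#' Run all four stability algorithms on one sample subset
#'
#' @param table A complete `ct_table`.
#' @param genorm_denominator Passed to [genorm()].
#' @param normfinder_groups Passed to [normfinder()] (default ungrouped).
#' @return Named list of four `stability_result`s
#'   (`delta_ct`, `bestkeeper`, `normfinder`, `genorm`).
#' @examples
#' hkg_stability(subset_conditions(asc_ct(), "S"))
#' @export
hkg_stability <- function(table, genorm_denominator = "sample",
                          normfinder_groups = NULL) {
  list(
    delta_ct = delta_ct_stability(table),
    bestkeeper = bestkeeper(table),
    normfinder = normfinder(table, groups = normfinder_groups),
    genorm = genorm(table, denominator = genorm_denominator)
  )
}
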