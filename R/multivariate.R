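# Multivariate overview of reference-gene expression: PCA across samples
# and two-way hierarchical clustering with correlation distance.

#' Principal component analysis of a Ct table
#'
#' Samples are the observations and genes the variables. Gene columns are
#' mean-centred; by default they are *not* scaled to unit variance, so
#' genes with larger Ct fluctuation carry proportionally more weight
#' (set `scale = TRUE` for correlation-matrix PCA). Computed by SVD via
#' [stats::prcomp()].
#'
#' @param table A complete `ct_table` with >= 2 genes and >= 3 samples.
#' @param scale Scale gene columns to unit variance? Default `FALSE`.
#' @param observations `"samples"` (default) or `"genes"` — which margin
#'   to treat as observations.
#' @return A list of class `ct_pca`: `scores` (observations x PCs),
#'   `loadings` (variables x PCs), `var_explained` (percent of total
#'   variance per PC), `sdev`.
#' @examples
#' p <- ct_pca(asc_ct())
#' round(p$var_explained, 1)
#' @export
ct_pca <- function(table, scale = FALSE,
                   observations = c("samples", "genes")) {
  observations <- match.arg(observations)
  m <- .stab_matrix(table, min_genes = 2, min_samples = 3)
  if (observations == "genes") m <- t(m)
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable(s), cannot scale: ",
           paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = ve, sdev = p$sdev),
            class = "ct_pca")
}

#' @export
print.ct_pca <- function(x, ...) {
  cat("<ct_pca>\n  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_along(x$var_explained),
                    x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Two-way hierarchical clustering of a Ct table
#'
#' Clusters genes (rows) and samples (columns) of the row-centred Ct
#' matrix with correlation distance (1 - Pearson r) and average linkage
#' (UPGMA). Leaf ordering places the tighter subtree — the one merged at
#' the lower height — first at every internal node. The row-centred
#' matrix (each gene's mean Ct subtracted) is returned for heatmap
#' export: positive cells mean higher Ct (lower expression) than that
#' gene's average.
#'
#' @param table A complete `ct_table` with >= 2 genes and >= 2 samples;
#'   no gene or sample may be constant (correlation undefined).
#' @return A list of class `ct_clustering`: `gene_hclust` and
#'   `sample_hclust` ([stats::hclust] trees with tighter-first leaf
#'   order) and `matrix` (genes x samples, row-centred).
#' @examples
#' cl <- ct_hclust(asc_ct())
#' stats::cutree(cl$sample_hclust, k = 2)
#' @export
ct_hclust <- function(table) {
  m <- t(.stab_matrix(table, min_genes = 2, min_samples = 2))  # genes x samples
  const_g <- rownames(m)[apply(m, 1, stats::sd) == 0]
  if (length(const_g))
    stop("constant gene(s), correlation undefined: ",
         paste(const_g, collapse = ", "), call. = FALSE)
  centred <- m - rowMeans(m)
  const_s <- colnames(centred)[apply(centred, 2, stats::sd) == 0]
  if (length(const_s))
    stop("constant sample column(s) after row centring: ",
         paste(const_s, collapse = ", "), call. = FALSE)

  gene_hc <- .tighter_first(stats::hclust(
    stats::as.dist(1 - stats::cor(t(centred))), method = "average"))
  sample_hc <- .tighter_first(stats::hclust(
    stats::as.dist(1 - stats::cor(centred)), method = "average"))

  structure(list(gene_hclust = gene_hc, sample_hclust = sample_hc,
                 matrix = centred),
            class = "ct_clustering")
}

# Reorder an hclust tree so that at every merge the subtree with the
# lower merge height (the tighter cluster) is placed first; leaves count
# as height 0 and ties keep the original orientation.
.tighter_first <- function(hc) {
  height_of <- function(k) if (k < 0) 0 else hc$height[k]
  walk <- function(k) {
    if (k < 0) return(-k)
    ch <- hc$merge[k, ]
    if (height_of(ch[2]) < height_of(ch[1])) ch <- ch[c(2, 1)]
    c(walk(ch[1]), walk(ch[2]))
  }
  hc$order <- walk(nrow(hc$merge))
  hc
}

#' @export
print.ct_clustering <- function(x, ...) {
  cat(sprintf("<ct_clustering> %d genes x %d samples, correlation distance, average linkage\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  sample leaf order:",
      paste(x$sample_hclust$labels[x$sample_hclust$order], collapse = ", "), "\n")
  invisible(x)
}
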