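asc <- asc_ct()

test_that("PCA variance-explained shares are conserved and orientation flags work", {
  p <- ct_pca(asc)
  expect_equal(sum(p$var_explained), 100, tolerance = 1e-9)
  expect_true(all(p$var_explained >= 0))
  expect_equal(dim(p$scores), c(15, 5))
  # scores are uncorrelated across components
  cv <- crossprod(scale(p$scores, scale = FALSE)) / (nrow(p$scores) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)

  pt <- ct_pca(asc, observations = "genes")
  expect_equal(nrow(pt$scores), 5)
  expect_equal(nrow(pt$loadings), 15)

  # a rank-one expression pattern loads entirely on PC1
  pat <- c(1, 2, 3, 2.5, 1.5, 2)
  m <- outer(pat, c(1, 2, 0.5, 3)) + matrix(20, 6, 4)
  rownames(m) <- paste0("s", 1:6); colnames(m) <- paste0("G", 1:4)
  p1 <- ct_pca(make_table(m, rep("F", 6)))
  expect_equal(p1$var_explained[1], 100, tolerance = 1e-9)

  const <- make_table(cbind(G1 = rep(20, 4), G2 = c(21, 22, 23, 21.5)),
                      rep("F", 4))
  expect_error(ct_pca(const, scale = TRUE), "zero-variance")
})

test_that("UPGMA with correlation distance matches a brute-force oracle", {
  set.seed(19)
  m <- matrix(rnorm(16, 21, 1), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("G", 1:4)))
  cl <- ct_hclust(make_table(m, rep("F", 4)))

  centred <- t(m) - rowMeans(t(m))
  d_genes <- 1 - stats::cor(t(centred))
  coph <- stats::cophenetic(cl$gene_hclust)
  expect_equal(as.matrix(coph)[rownames(d_genes), colnames(d_genes)],
               oracle_upgma_cophenetic(d_genes), tolerance = 1e-12)

  d_samp <- 1 - stats::cor(centred)
  coph_s <- stats::cophenetic(cl$sample_hclust)
  expect_equal(as.matrix(coph_s)[rownames(d_samp), colnames(d_samp)],
               oracle_upgma_cophenetic(d_samp), tolerance = 1e-12)
})

test_that("identical samples merge first at height zero, tighter subtree leads", {
  m <- cbind(G1 = c(20, 20, 21, 24), G2 = c(22, 22, 23.1, 26.2),
             G3 = c(19, 19, 20.2, 23.5))
  rownames(m) <- c("twin1", "twin2", "near", "far")
  cl <- ct_hclust(make_table(m, rep("F", 4)))
  hc <- cl$sample_hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first_pair, c("twin1", "twin2"))
  # twins merged at height 0 must sit next to each other in the leaf order
  twin_idx <- match(c("twin1", "twin2"), hc$labels)
  expect_equal(abs(diff(match(twin_idx, hc$order))), 1)
  # leaf order starts inside the tighter (lower-height) top-level subtree
  h_of <- function(k) if (k < 0) 0 else hc$height[k]
  leaves_of <- function(k) {
    if (k < 0) return(-k)
    c(leaves_of(hc$merge[k, 1]), leaves_of(hc$merge[k, 2]))
  }
  top <- hc$merge[nrow(hc$merge), ]
  tighter <- if (h_of(top[2]) < h_of(top[1])) top[2] else top[1]
  expect_true(hc$order[1] %in% leaves_of(tighter))
})

test_that("clustering is invariant to positive affine rescaling of genes", {
  sim <- generate_ct(synthetic_spec(), seed = 4)
  cl1 <- ct_hclust(sim$table)
  rescaled <- sweep(sweep(sim$table$ct, 2, c(1.2, 0.5, 1.3, 0.8, 1.1), `*`),
                    2, c(1, -4, 2, 0.5, 3), `+`)
  cl2 <- ct_hclust(ct_table(rescaled, sim$table$meta))
  expect_equal(cl2$gene_hclust$merge, cl1$gene_hclust$merge)
  expect_equal(cl2$gene_hclust$height, cl1$gene_hclust$height,
               tolerance = 1e-10)
})

test_that("constant genes are rejected by name", {
  m <- cbind(FLAT = rep(20, 4), G2 = c(21, 22, 23, 21.5),
             G3 = c(25, 26, 27, 25.5))
  rownames(m) <- paste0("s", 1:4)
  expect_error(ct_hclust(make_table(m, rep("F", 4))), "FLAT")
})
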