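asc <- asc_ct()
asc_F <- subset_conditions(asc, "F")
asc_S <- subset_conditions(asc, "S")

test_that("descriptive statistics use the population SD and reproduce the study values", {
  d <- ct_descriptives(asc)
  rownames(d) <- d$gene
  expect_equal(round(d["RPLP0", "mean"], 2), 19.20)
  expect_equal(round(d["RPLP0", "sd"], 2), 0.53)
  expect_equal(round(d["HPRT1", "mean"], 2), 27.11)
  expect_equal(round(d["HPRT1", "sd"], 2), 0.71)
  expect_equal(d["ACTB", "range"], 3.54)
  expect_equal(d["B2M", "range"], 1.53)
  expect_true(all(d$min <= d$mean & d$mean <= d$max))
  expect_equal(d$range, d$max - d$min)

  const <- make_table(matrix(c(20, 20, 20, 19, 21, 23), 3, 2), rep("F", 3))
  dc <- ct_descriptives(const)
  expect_equal(dc$sd[1], 0)
  expect_equal(dc$range[1], 0)
})

test_that("comparative delta-Ct matches the printed per-condition cells", {
  f <- delta_ct_stability(asc_F)
  s <- delta_ct_stability(asc_S)
  vf <- setNames(f$value, f$gene)
  vs <- setNames(s$value, s$gene)
  expect_equal(round(vf[["HPRT1"]], 2), 0.14)
  expect_equal(round(vf[["ACTB"]], 2), 0.16)
  expect_equal(round(vs[["B2M"]], 2), 0.16)
  expect_error(delta_ct_stability(make_table(matrix(1:4 + 20, 2, 2),
                                             c("F", "F"))), "3 samples")
})

test_that("genes differing by a constant have a zero mutual delta-Ct term", {
  set.seed(1)
  m <- cbind(G1 = c(20, 21, 22, 20.5),
             G2 = c(22, 23, 24, 22.5),          # G1 + 2
             G3 = 25 + rnorm(4, 0, 0.5))
  rownames(m) <- paste0("s", 1:4)
  tab <- make_table(m, rep("F", 4))
  res <- delta_ct_stability(tab)
  v <- setNames(res$value, res$gene)
  # each of G1, G2 averages {0, sd(vs G3)}; they share the same value
  expect_equal(v[["G1"]], v[["G2"]])
  expect_equal(v[["G1"]], mean(c(0, sd(m[, 1] - m[, 3]))))
})

test_that("BestKeeper MAD reproduces printed cells and reports the index", {
  f <- bestkeeper(asc_F)
  s <- bestkeeper(asc_S)
  vf <- setNames(f$value, f$gene)
  expect_equal(round(vf[["RPLP0"]], 2), 0.16)
  expect_equal(round(setNames(s$value, s$gene)[["RPLP0"]], 2), 0.14)
  expect_equal(unname(attr(f, "index")),
               unname(rowMeans(asc_F$ct)))
  expect_true(all(abs(attr(f, "index_cor")) <= 1))

  # constant gene: MAD 0, correlation with the index undefined
  m <- cbind(G1 = rep(20, 4), G2 = c(25, 26, 24, 25.5), G3 = c(19, 20, 18, 19.5))
  rownames(m) <- paste0("s", 1:4)
  res <- bestkeeper(make_table(m, rep("F", 4)))
  v <- setNames(res$value, res$gene)
  expect_equal(v[["G1"]], 0)
  expect_true(is.na(attr(res, "index_cor")[["G1"]]))

  # geometric variant differs only marginally at these Ct magnitudes
  g <- bestkeeper(asc_F, variant = "geometric")
  expect_equal(setNames(g$value, g$gene)[f$gene], setNames(f$value, f$gene),
               tolerance = 0.05)
})

test_that("NormFinder matches a literal step-by-step transcription of the model", {
  set.seed(42)
  m <- matrix(rnorm(24, 22, 1), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("G", 1:4)))
  tab <- make_table(m, rep("F", 6))
  res <- normfinder(tab)
  expect_equal(setNames(res$value, res$gene)[colnames(m)],
               oracle_normfinder(m), tolerance = 1e-12)

  # the two most stable genes in condition F, tied at this sample size
  f <- normfinder(asc_F)
  expect_equal(sort(f$gene[f$rank <= 2]), c("B2M", "HPRT1"))
  expect_equal(f$value[1], f$value[2])

  # a gene with exactly zero centred residuals scores exactly 0:
  # G1 tracks the per-sample mean of the panel up to a constant
  others <- matrix(rnorm(18, 22, 1), 6, 3)
  G1 <- rowSums(others) / 3 + 2
  m0 <- cbind(G1 = G1, G2 = others[, 1], G3 = others[, 2], G4 = others[, 3])
  rownames(m0) <- paste0("s", 1:6)
  r0 <- normfinder(make_table(m0, rep("F", 6)))
  expect_equal(setNames(r0$value, r0$gene)[["G1"]], 0)
})

test_that("grouped NormFinder penalises between-group movers and rejects singleton groups", {
  set.seed(9)
  base <- rnorm(8, 0, 0.2)
  m <- cbind(G1 = 20 + base + rnorm(8, 0, 0.05),
             G2 = 22 + base + c(rep(0, 4), rep(1.5, 4)) + rnorm(8, 0, 0.05),
             G3 = 24 + base + rnorm(8, 0, 0.05),
             G4 = 26 + base + rnorm(8, 0, 0.05))
  rownames(m) <- paste0("s", 1:8)
  tab <- make_table(m, rep(c("F", "S"), each = 4))
  res <- normfinder(tab, groups = tab$meta$condition)
  expect_equal(res$gene[res$rank == max(res$rank)], "G2")
  expect_true(all(res$value >= 0))
  expect_error(normfinder(tab, groups = c(rep("a", 7), "b")), ">= 2 samples")
})

test_that("geNorm stepwise exclusion reproduces the printed final pairs", {
  f <- genorm(asc_F)
  expect_equal(attr(f, "genorm_pair"), c("B2M", "HPRT1"))
  vf <- setNames(f$value, f$gene)
  expect_equal(round(vf[["B2M"]], 2), 0.07)
  expect_equal(vf[["B2M"]], vf[["HPRT1"]])
  expect_equal(sort(f$rank), c(1, 1, 3, 4, 5))

  s <- genorm(asc_S)
  expect_equal(attr(s, "genorm_pair"), c("GAPDH", "RPLP0"))
  expect_equal(round(setNames(s$value, s$gene)[["GAPDH"]], 2), 0.07)

  # two identical expression profiles survive to the final pair with M = 0
  set.seed(5)
  prof <- c(20, 21, 20.5, 21.5)
  m <- cbind(G1 = prof, G2 = prof + 3, G3 = 22 + rnorm(4, 0, 0.8),
             G4 = 25 + rnorm(4, 0, 0.8))
  rownames(m) <- paste0("s", 1:4)
  res <- genorm(make_table(m, rep("F", 4)))
  expect_equal(attr(res, "genorm_pair"), c("G1", "G2"))
  expect_equal(setNames(res$value, res$gene)[["G1"]], 0)
})

test_that("pairwise-SD methods equal a brute-force loop oracle on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    g <- sample(2:4, 1); n <- sample(3:4, 1)
    m <- matrix(rnorm(g * n, 22, 1.5), n, g,
                dimnames = list(paste0("s", 1:n), paste0("G", 1:g)))
    tab <- make_table(m, rep("F", n))
    d <- delta_ct_stability(tab)
    expect_equal(setNames(d$value, d$gene)[colnames(m)],
                 oracle_pairwise_mean_sd(m), tolerance = 1e-12)
    if (g >= 3) {
      gn <- genorm(tab)
      # first-excluded gene's M equals the oracle's full-panel value
      worst <- gn$gene[gn$rank == g]
      expect_equal(setNames(gn$value, gn$gene)[[worst]],
                   max(oracle_pairwise_mean_sd(m)), tolerance = 1e-12)
    }
  }
})

test_that("stability values obey the shift and ordering invariances", {
  set.seed(77)
  sim <- generate_ct(synthetic_spec(), seed = 77)
  tab <- sim$table
  n <- nrow(tab$ct); g <- ncol(tab$ct)
  row_shift <- rnorm(n, 0, 1)
  col_shift <- rnorm(g, 0, 2)
  tab_rows <- ct_table(tab$ct + row_shift, tab$meta)
  tab_cols <- ct_table(sweep(tab$ct, 2, col_shift, `+`), tab$meta)

  vals <- function(r) setNames(r$value, r$gene)[sort(colnames(tab$ct))]
  for (fn in list(delta_ct_stability, normfinder, genorm)) {
    expect_equal(vals(fn(tab_rows)), vals(fn(tab)), tolerance = 1e-10)
    expect_equal(vals(fn(tab_cols)), vals(fn(tab)), tolerance = 1e-10)
  }
  # BestKeeper is not sample-shift invariant, but is gene-shift invariant
  expect_false(isTRUE(all.equal(vals(bestkeeper(tab_rows)),
                                vals(bestkeeper(tab)))))
  expect_equal(vals(bestkeeper(tab_cols)), vals(bestkeeper(tab)),
               tolerance = 1e-10)

  # permuting samples and genes changes nothing
  perm <- ct_table(tab$ct[sample(n), sample(g)],
                   tab$meta[sample(n), ])
  for (fn in list(delta_ct_stability, bestkeeper, normfinder, genorm))
    expect_equal(vals(fn(perm)), vals(fn(tab)), tolerance = 1e-10)
})

test_that("on two genes, delta-Ct stability equals the geNorm final-pair M", {
  set.seed(13)
  m <- matrix(rnorm(10, 21, 0.7), 5, 2,
              dimnames = list(paste0("s", 1:5), c("G1", "G2")))
  tab <- make_table(m, rep("F", 5))
  d <- delta_ct_stability(tab)
  gn <- genorm(tab)
  expect_equal(d$value, rep(sd(m[, 1] - m[, 2]), 2))
  expect_equal(gn$value, d$value)
  expect_equal(attr(gn, "genorm_pair"), c("G1", "G2"))
})

test_that("incomplete matrices are rejected by all stability operations", {
  m <- asc_F$ct
  m[1, 2] <- NA
  tab <- ct_table(m, asc_F$meta)
  for (fn in list(ct_descriptives, delta_ct_stability, bestkeeper,
                  normfinder, genorm))
    expect_error(fn(tab), "missing")
})
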