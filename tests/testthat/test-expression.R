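# Fold-change quantification and significance conventions, exercised on
# small constructed tables: three donors per condition, as in the study.

fc_table <- function(target_f, target_s, hkg_f = NULL, hkg_s = NULL,
                     noise = 0.05, seed = 1) {
  set.seed(seed)
  if (is.null(hkg_f)) hkg_f <- rep(20, 3)
  if (is.null(hkg_s)) hkg_s <- rep(20, 3)
  m <- cbind(TGT = c(target_f, target_s) + rnorm(6, 0, noise),
             HKG = c(hkg_f, hkg_s) + rnorm(6, 0, noise))
  rownames(m) <- paste0("D", 1:3, c(" F", " F", " F", " S", " S", " S"))
  make_table(m, rep(c("F", "S"), each = 3), donors = rep(paste0("D", 1:3), 2))
}

test_that("unchanged target gives fold 1 and identical groups p = 1", {
  tab <- fc_table(rep(25, 3), rep(25, 3), noise = 0)
  fc <- ddct_fold_change(tab, "TGT", "HKG", "S", "F")
  expect_equal(fc$mean_fold, 1)
  expect_equal(fc$p, 1)
  expect_equal(fc$call, "unchanged")
})

test_that("a uniform ddCt of -1 gives fold 2 exactly, per donor", {
  tab <- fc_table(rep(25, 3), rep(24, 3), noise = 0)
  # distinct constants: p = 0 side of the degenerate-variance convention
  fc <- ddct_fold_change(tab, "TGT", "HKG", "S", "F")
  expect_equal(fc$per_donor$fold, rep(2, 3))
  expect_equal(fc$mean_fold, 2)
  expect_equal(fc$call, "up")
})

test_that("fold changes are HKG-shift invariant and reciprocal under condition swap", {
  tab <- fc_table(c(25.0, 25.3, 24.8), c(27.1, 27.4, 26.9))
  fc <- ddct_fold_change(tab, "TGT", "HKG", "S", "F")

  shifted <- tab
  shifted$ct[, "HKG"] <- shifted$ct[, "HKG"] + 3.7
  tab2 <- ct_table(shifted$ct, shifted$meta)
  fc2 <- ddct_fold_change(tab2, "TGT", "HKG", "S", "F")
  expect_equal(fc2$per_donor$fold, fc$per_donor$fold)
  expect_equal(fc2$p, fc$p)

  rev <- ddct_fold_change(tab, "TGT", "HKG", "F", "S")
  expect_equal(fc$per_donor$fold * rev$per_donor$fold, rep(1, 3))
})

test_that("a stable HKG recovers an injected shift; an equally drifting HKG masks it", {
  # target +2 Ct under S (4-fold down); bad HKG drifts +2 Ct as well
  set.seed(3)
  m <- cbind(TGT = c(25, 25.2, 24.9, 27, 27.2, 26.9) + rnorm(6, 0, 0.05),
             GOOD = c(20, 20.1, 19.9, 20, 20.1, 20.0) + rnorm(6, 0, 0.05),
             BAD = c(18, 18.1, 17.9, 20, 20.2, 19.9) + rnorm(6, 0, 0.05))
  rownames(m) <- paste0("s", 1:6)
  tab <- make_table(m, rep(c("F", "S"), each = 3),
                    donors = rep(paste0("D", 1:3), 2))
  good <- ddct_fold_change(tab, "TGT", "GOOD", "S", "F")
  bad <- ddct_fold_change(tab, "TGT", "BAD", "S", "F")
  expect_equal(good$call, "down")
  expect_equal(good$mean_fold, 0.25, tolerance = 0.1)
  expect_equal(bad$call, "unchanged")          # the drift cancels the shift
  expect_gt(bad$mean_fold, 0.5)
})

test_that("donor mismatch and missing genes are rejected", {
  tab <- fc_table(rep(25, 3), rep(24, 3))
  meta <- tab$meta
  meta$donor[6] <- "D9"
  tab2 <- ct_table(tab$ct, meta)
  expect_error(ddct_fold_change(tab2, "TGT", "HKG", "S", "F"), "donor")
  expect_error(ddct_fold_change(tab, "TGT", "NOPE", "S", "F"), "NOPE")
})

test_that("significance follows the t-test / ANOVA+Tukey conventions", {
  res <- significance(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_lt(res$p, 0.001)
  expect_equal(res$call, "significant")
  expect_match(res$test, "t-test")

  set.seed(8)
  g <- list(F = rnorm(3, 0), S = rnorm(3, 0), X = rnorm(3, 5))
  res3 <- significance(g, design = "all_conditions")
  expect_match(res3$test, "ANOVA")
  expect_equal(nrow(res3$pairwise), 3)
  pw <- setNames(res3$pairwise$p, res3$pairwise$comparison)
  expect_lt(pw[["X-F"]], 0.05)
  expect_gt(pw[["S-F"]], 0.1)

  # the normality gate refuses clearly non-normal groups
  skewed <- c(rep(0.001, 9), 1000)
  expect_error(significance(list(a = skewed, b = rnorm(10))),
               "Shapiro-Wilk rejects")
})
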