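# Relative quantification of target genes against a chosen reference
# gene, with the study's significance conventions.

#' Per-sample relative expression, 2^-dCt
#'
#' Expression of a target gene relative to a housekeeping gene within the
#' same sample, \eqn{2^{-(Ct_{target} - Ct_{hkg})}} (amplification
#' efficiency assumed 2). Positive, and monotone decreasing in the
#' target's Ct.
#'
#' @param table A `ct_table` containing both genes.
#' @param target Target gene symbol.
#' @param hkg Reference gene symbol.
#' @return data.frame `sample`, `donor`, `condition`, `rel_expr`.
#' @export
relative_expression <- function(table, target, hkg) {
  stopifnot(is.ct_table(table))
  for (g in c(target, hkg))
    if (!g %in% colnames(table$ct))
      stop("gene not in table: ", g, call. = FALSE)
  data.frame(table$meta[, c("sample", "donor", "condition")],
             rel_expr = 2^(-(table$ct[, target] - table$ct[, hkg])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Significance testing with the study's conventions
#'
#' Normality is screened per group by Shapiro-Wilk at alpha = 0.01; if any
#' group rejects, an error instructs the user (no non-parametric fallback
#' is defined). For two groups an unpaired Student's t-test (equal
#' variances) is run; for more, a one-way ANOVA with Tukey HSD post hoc.
#' Significance is called at p <= 0.05, with a tendency band at
#' 0.05 < p <= 0.1.
#'
#' Degenerate inputs: a constant group cannot be normality-tested and is
#' let through; two groups that are constant and identical give p = 1.
#'
#' @param groups Named list of numeric vectors (>= 3 values each).
#' @param design `"two_conditions"` (t-test) or `"all_conditions"`
#'   (ANOVA + Tukey).
#' @param normality `"gate"` (default, Shapiro-Wilk screen) or `"skip"`.
#' @return A list: `test`, `p` (overall p-value), `pairwise` (data.frame
#'   of pairwise comparisons with p-values and calls; for the t-test the
#'   single comparison), and `call` for the overall p.
#' @export
significance <- function(groups, design = c("two_conditions", "all_conditions"),
                         normality = c("gate", "skip")) {
  design <- match.arg(design)
  normality <- match.arg(normality)
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 3))
    stop("every group needs >= 3 values", call. = FALSE)

  if (normality == "gate") {
    for (nm in names(groups)) {
      v <- groups[[nm]]
      if (stats::sd(v) == 0) next   # constant: not testable, let through
      p_sw <- stats::shapiro.test(v)$p.value
      if (p_sw < 0.01)
        stop("Shapiro-Wilk rejects normality for group '", nm,
             "' (p = ", signif(p_sw, 3), " < 0.01); the parametric tests ",
             "used here are not applicable -- inspect or transform the data",
             call. = FALSE)
    }
  }

  if (design == "two_conditions") {
    if (length(groups) != 2)
      stop("two_conditions design needs exactly 2 groups", call. = FALSE)
    a <- groups[[1]]; b <- groups[[2]]
    p <- if (stats::sd(c(a, b)) == 0) {
      1                             # identical constants: no evidence
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      0                             # two distinct constants
    } else {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }
    pw <- data.frame(comparison = paste(names(groups), collapse = " vs "),
                     p = p, call = .sig_call(p), stringsAsFactors = FALSE)
    list(test = "unpaired Student t-test", p = p, pairwise = pw,
         call = .sig_call(p))
  } else {
    y <- unlist(groups, use.names = FALSE)
    f <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    fit <- stats::aov(y ~ f)
    p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$f
    pw <- data.frame(comparison = rownames(tk), p = tk[, "p adj"],
                     call = vapply(tk[, "p adj"], .sig_call, character(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
    list(test = "one-way ANOVA + Tukey HSD", p = p_overall, pairwise = pw,
         call = .sig_call(p_overall))
  }
}

.sig_call <- function(p) {
  if (is.na(p)) "unchanged"
  else if (p <= 0.05) "significant"
  else if (p <= 0.1) "tendency"
  else "unchanged"
}

#' Fold change between two conditions by 2^-ddCt
#'
#' Computes, per donor, the target gene's expression change in `cond_a`
#' relative to `cond_b`, normalized to a housekeeping gene:
#' \eqn{\Delta Ct = Ct_{target} - Ct_{hkg}} within each sample,
#' \eqn{\Delta\Delta Ct_d = \Delta Ct_{a,d} - \Delta Ct_{b,d}} matching
#' samples by donor (the biological replicate unit), and fold change
#' \eqn{2^{-\Delta\Delta Ct_d}}. The summary reports the mean and SD of
#' the per-donor folds on the linear scale. Significance follows
#' [significance()] on the unpaired per-sample delta-Ct values (default)
#' or on the linear 2^-dCt values (`test_scale = "linear"`).
#'
#' Call conventions: `up` requires mean fold >= 2 and p <= 0.05; `down`
#' requires mean fold <= 0.5 and p <= 0.05; `tendency` flags a >= 2-fold
#' (or <= 0.5) mean with 0.05 < p <= 0.1; anything else is `unchanged`.
#'
#' @param table A `ct_table` containing the target and reference genes.
#' @param target Target gene symbol.
#' @param hkg Housekeeping gene used as normalizer.
#' @param cond_a Condition of interest.
#' @param cond_b Reference condition.
#' @param pairing Replicate matching rule; `"by_donor"` (the only one
#'   implemented) averages each donor's delta-Ct within a condition and
#'   requires the same donors in both conditions.
#' @param test_scale `"dct"` (default) or `"linear"` scale for the t-test.
#' @param normality Passed to [significance()].
#' @return A list of class `fold_change_result`: `target`, `hkg`,
#'   `cond_a`, `cond_b`, `per_donor` (data.frame of donor, ddct, fold),
#'   `mean_fold`, `sd_fold`, `p`, `test`, `call`.
#' @export
ddct_fold_change <- function(table, target, hkg, cond_a, cond_b,
                             pairing = "by_donor",
                             test_scale = c("dct", "linear"),
                             normality = "gate") {
  stopifnot(is.ct_table(table))
  pairing <- match.arg(pairing, "by_donor")
  test_scale <- match.arg(test_scale)
  for (g in c(target, hkg))
    if (!g %in% colnames(table$ct))
      stop("gene not in table: ", g, call. = FALSE)
  for (cc in c(cond_a, cond_b))
    if (!cc %in% table$meta$condition)
      stop("no samples in condition: ", cc, call. = FALSE)

  dct <- table$ct[, target] - table$ct[, hkg]
  meta <- table$meta
  in_a <- meta$condition == cond_a
  in_b <- meta$condition == cond_b
  donors_a <- unique(meta$donor[in_a])
  donors_b <- unique(meta$donor[in_b])
  odd <- c(setdiff(donors_a, donors_b), setdiff(donors_b, donors_a))
  if (length(odd))
    stop("donor(s) present in only one condition: ",
         paste(odd, collapse = ", "), call. = FALSE)

  donor_mean <- function(keep) {
    tapply(dct[keep], meta$donor[keep], mean)
  }
  da <- donor_mean(in_a)
  db <- donor_mean(in_b)[names(da)]
  ddct <- da - db
  fold <- 2^(-ddct)

  groups <- if (test_scale == "dct") {
    list(a = dct[in_a], b = dct[in_b])
  } else {
    list(a = 2^(-dct[in_a]), b = 2^(-dct[in_b]))
  }
  names(groups) <- c(cond_a, cond_b)
  sig <- significance(groups, design = "two_conditions",
                      normality = normality)

  mean_fold <- mean(fold)
  call <- if (mean_fold >= 2 && sig$p <= 0.05) "up"
          else if (mean_fold <= 0.5 && sig$p <= 0.05) "down"
          else if ((mean_fold >= 2 || mean_fold <= 0.5) &&
                   sig$p > 0.05 && sig$p <= 0.1) "tendency"
          else "unchanged"

  structure(list(
    target = target, hkg = hkg, cond_a = cond_a, cond_b = cond_b,
    per_donor = data.frame(donor = names(ddct), ddct = unname(ddct),
                           fold = unname(fold), stringsAsFactors = FALSE),
    mean_fold = mean_fold, sd_fold = stats::sd(fold),
    p = sig$p, test = sig$test, call = call
  ), class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> %s (%s vs %s, normalized to %s)\n",
              x$target, x$cond_a, x$cond_b, x$hkg))
  cat(sprintf("  fold change %.2f +/- %.2f (n = %d donors), p = %.3g [%s] -> %s\n",
              x$mean_fold, x$sd_fold, nrow(x$per_donor), x$p, x$test, x$call))
  invisible(x)
}
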