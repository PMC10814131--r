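#' Define a condition-combinatorial analysis plan
#'
#' A plan is a named list of condition sets; each entry is analysed
#' independently with all four stability methods plus the consensus
#' ranking. [default_plan()] returns the study design used throughout
#' this package's worked analyses: each of the five conditions alone, six
#' coupled condition sets chosen to contrast serum, starvation and
#' inflammatory priming, and all samples together (`ALL`) — 12 analyses.
#'
#' @param subsets Named list; each element a character vector of condition
#'   labels.
#' @return An object of class `analysis_plan`.
#' @examples
#' default_plan()
#' analysis_plan(list(serum_only = "F", starvation = c("S", "S+IL1")))
#' @export
analysis_plan <- function(subsets) {
  if (!is.list(subsets) || is.null(names(subsets)) ||
      any(!nzchar(names(subsets))))
    stop("`subsets` must be a named list of condition-label vectors",
         call. = FALSE)
  for (nm in names(subsets)) {
    unknown <- setdiff(subsets[[nm]], .condition_levels())
    if (length(unknown))
      stop("subset '", nm, "' names unknown condition(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(subsets, class = "analysis_plan")
}

#' @rdname analysis_plan
#' @export
default_plan <- function() {
  analysis_plan(list(
    "F" = "F",
    "F+IL1" = "F+IL1",
    "S" = "S",
    "S+IL1" = "S+IL1",
    "F+IL1/S" = "F+IL1/S",
    "F and F+IL1" = c("F", "F+IL1"),
    "S and S+IL1" = c("S", "S+IL1"),
    "S and F+IL1/S" = c("S", "F+IL1/S"),
    "F+IL1 and S+IL1" = c("F+IL1", "S+IL1"),
    "F and S" = c("F", "S"),
    "F+IL1 and F+IL1/S" = c("F+IL1", "F+IL1/S"),
    "ALL" = .condition_levels()
  ))
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat("<analysis_plan>", length(x), "subsets\n")
  for (nm in names(x)) cat(" ", nm, "=", paste(x[[nm]], collapse = " + "), "\n")
  invisible(x)
}

#' Run an analysis plan over a Ct table
#'
#' Iterates deterministically over the plan's subsets; for each, restricts
#' the table to the matching samples, runs the four stability algorithms
#' and the geometric-mean consensus, and collects the results. Each subset
#' is analysed independently: rows outside the subset never influence its
#' result.
#'
#' @param table A complete `ct_table`.
#' @param plan An `analysis_plan`; defaults to [default_plan()].
#' @param ... Passed to [hkg_stability()].
#' @return An object of class `plan_results`: a named list with, per
#'   subset, `label`, `conditions`, `stability` (list of 4
#'   `stability_result`s) and `consensus` (a `consensus_ranking`).
#'   `as.data.frame()` flattens it to one tidy table.
#' @examples
#' res <- run_plan(asc_ct())
#' res[["ALL"]]$consensus
#' @export
run_plan <- function(table, plan = default_plan(), ...) {
  stopifnot(is.ct_table(table), inherits(plan, "analysis_plan"))
  out <- lapply(names(plan), function(nm) {
    sub <- subset_conditions(table, plan[[nm]])
    if (nrow(sub$ct) < 3)
      stop("subset '", nm, "' resolves to fewer than 3 samples", call. = FALSE)
    stab <- hkg_stability(sub, ...)
    list(label = nm, conditions = plan[[nm]], stability = stab,
         consensus = consensus_rank(stab))
  })
  names(out) <- names(plan)
  structure(out, class = "plan_results")
}

#' @export
print.plan_results <- function(x, ...) {
  cat("<plan_results>", length(x), "subsets\n")
  for (e in x) {
    cons <- e$consensus
    cat(sprintf("  %-20s best %-6s (%.2f)  worst %-6s (%.2f)\n", e$label,
                cons$gene[1], cons$geomean[1],
                cons$gene[nrow(cons)], cons$geomean[nrow(cons)]))
  }
  invisible(x)
}

#' @export
as.data.frame.plan_results <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) {
    long <- do.call(rbind, lapply(e$stability, function(r) {
      data.frame(subset = e$label, method = attr(r, "method"),
                 gene = r$gene, value = r$value, rank = r$rank,
                 stringsAsFactors = FALSE)
    }))
    cons <- data.frame(subset = e$label, method = "consensus",
                       gene = e$consensus$gene, value = e$consensus$geomean,
                       rank = seq_len(nrow(e$consensus)),
                       stringsAsFactors = FALSE)
    rbind(long, cons)
  }))
}
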