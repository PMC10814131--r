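#' Geometric-mean consensus ranking across the four stability methods
#'
#' Aggregates the rankings of the comparative delta-Ct, BestKeeper,
#' NormFinder and geNorm methods into one comprehensive score per gene:
#' the geometric mean of its four ranks,
#' \eqn{(r_{\Delta Ct}\, r_{BK}\, r_{NF}\, r_{gN})^{1/4}}. Ranks are taken
#' at full numeric precision (average ranks on exact ties); geNorm
#' contributes its pair-rule ranks, with both final-pair genes at rank 1
#' and the next gene at rank 3. Lower geomean = more stable; output is
#' sorted ascending with alphabetical tie-break.
#'
#' @param results A list of four `stability_result`s (one per method, any
#'   order) computed on identical gene sets and sample subsets, e.g. from
#'   [hkg_stability()].
#' @return A data.frame of class `consensus_ranking` with columns `gene`,
#'   `rank_delta_ct`, `rank_bestkeeper`, `rank_normfinder`, `rank_genorm`,
#'   `geomean`.
#' @examples
#' consensus_rank(hkg_stability(subset_conditions(asc_ct(), "F")))
#' @export
consensus_rank <- function(results) {
  methods <- c("delta_ct", "bestkeeper", "normfinder", "genorm")
  if (!is.list(results) || length(results) != 4 ||
      !all(vapply(results, inherits, logical(1), "stability_result")))
    stop("`results` must be a list of four stability_result objects",
         call. = FALSE)
  got <- vapply(results, attr, character(1), "method")
  if (!setequal(got, methods))
    stop("need one result per method (", paste(methods, collapse = ", "),
         "); got: ", paste(got, collapse = ", "), call. = FALSE)
  results <- results[match(methods, got)]

  genes <- sort(results[[1]]$gene)
  for (r in results[-1]) {
    if (!setequal(r$gene, genes))
      stop("gene sets differ between methods: ",
           paste(union(setdiff(r$gene, genes), setdiff(genes, r$gene)),
                 collapse = ", "), call. = FALSE)
  }
  subsets <- lapply(results, attr, "samples")
  for (s in subsets[-1]) {
    if (!setequal(s, subsets[[1]]))
      stop("sample subsets differ between methods", call. = FALSE)
  }

  ranks <- vapply(results,
                  function(r) r$rank[match(genes, r$gene)], numeric(length(genes)))
  colnames(ranks) <- methods
  geomean <- apply(ranks, 1, function(x) prod(x)^(1 / 4))
  out <- data.frame(gene = genes,
                    rank_delta_ct = ranks[, "delta_ct"],
                    rank_bestkeeper = ranks[, "bestkeeper"],
                    rank_normfinder = ranks[, "normfinder"],
                    rank_genorm = ranks[, "genorm"],
                    geomean = geomean,
                    stringsAsFactors = FALSE)
  out <- out[order(out$geomean, out$gene), ]
  rownames(out) <- NULL
  structure(out, samples = subsets[[1]],
            class = c("consensus_ranking", "data.frame"))
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("<consensus_ranking> %d genes, %d samples (best first)\n",
              nrow(x), length(attr(x, "samples"))))
  print.data.frame(cbind(x[1], round(x[-1], 2)))
  invisible(x)
}
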