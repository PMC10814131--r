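#' Experimental conditions of the culture design
#'
#' The five culture conditions and the binary design flags they imply:
#' whether serum (FBS) was present during the assayed 48 h window
#' (`serum`), whether IL-1 beta was present during that window (`il1b`),
#' and whether the cells were primed with IL-1 beta during a preceding
#' serum phase before starvation (`primed`).
#'
#' @return A data.frame with columns `condition`, `serum`, `il1b`, `primed`.
#' @examples
#' condition_design()
#' @export
condition_design <- function() {
  data.frame(
    condition = c("F", "F+IL1", "S", "S+IL1", "F+IL1/S"),
    serum     = c(TRUE,  TRUE,  FALSE, FALSE, FALSE),
    il1b      = c(FALSE, TRUE,  FALSE, TRUE,  FALSE),
    primed    = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

.condition_levels <- function() condition_design()$condition

#' Construct a Ct table
#'
#' The central data container of the package: a samples-by-genes matrix of
#' cycle-threshold (Ct) values together with per-sample metadata (donor and
#' culture condition). Ct is a log2-scale quantity: one cycle corresponds to
#' a two-fold difference in template amount.
#'
#' @param ct Numeric matrix, samples in rows, genes in columns; dimnames
#'   required. Present values must lie strictly between 0 and 45 cycles;
#'   `NA` marks an explicitly missing cell.
#' @param meta data.frame with columns `sample`, `donor`, `condition`, one
#'   row per sample, in any order (matched to `rownames(ct)` by `sample`).
#'   `condition` must be one of the five labels in [condition_design()].
#' @return An object of class `ct_table`: a list with elements `ct` (the
#'   validated matrix) and `meta` (metadata with derived `serum`, `il1b`,
#'   `primed` flags, in matrix row order).
#' @seealso [read_ct_table()], [subset_conditions()]
#' @export
ct_table <- function(ct, meta) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x genes)", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have sample rownames and gene colnames", call. = FALSE)
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(ct)))
    stop("duplicate gene symbols: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.finite(ct) & (ct <= 0 | ct >= 45))
  if (length(bad))
    stop("Ct values must lie in (0, 45) cycles; offending cells: ",
         paste(utils::head(ct[bad], 5), collapse = ", "), call. = FALSE)
  if (any(is.nan(ct) | is.infinite(ct)))
    stop("non-finite Ct values present; use NA for missing cells", call. = FALSE)

  if (!is.data.frame(meta) || !all(c("sample", "donor", "condition") %in% names(meta)))
    stop("`meta` must be a data.frame with columns sample, donor, condition",
         call. = FALSE)
  if (!setequal(meta$sample, rownames(ct)) || nrow(meta) != nrow(ct))
    stop("`meta$sample` must match the rownames of `ct` exactly", call. = FALSE)
  unknown <- setdiff(meta$condition, .condition_levels())
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         "; expected one of ", paste(.condition_levels(), collapse = ", "),
         call. = FALSE)

  meta <- meta[match(rownames(ct), meta$sample),
               c("sample", "donor", "condition"), drop = FALSE]
  des <- condition_design()
  i <- match(meta$condition, des$condition)
  meta$serum  <- des$serum[i]
  meta$il1b   <- des$il1b[i]
  meta$primed <- des$primed[i]
  rownames(meta) <- NULL

  structure(list(ct = ct, meta = meta), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d samples x %d genes\n", nrow(x$ct), ncol(x$ct)))
  cat("genes:", paste(colnames(x$ct), collapse = ", "), "\n")
  tb <- table(x$meta$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  if (anyNA(x$ct)) cat("missing cells:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' @rdname ct_table
#' @param x A `ct_table`.
#' @export
is.ct_table <- function(x) inherits(x, "ct_table")

#' Extract the Ct matrix of a table
#' @param x A `ct_table`.
#' @return The numeric samples-by-genes matrix.
#' @export
ct_matrix <- function(x) {
  stopifnot(is.ct_table(x))
  x$ct
}

#' Subset a Ct table
#'
#' `subset_samples()` keeps the named samples (in table order);
#' `subset_conditions()` keeps all samples belonging to the given
#' condition labels.
#'
#' @param x A `ct_table`.
#' @param samples Character vector of sample identifiers.
#' @param conditions Character vector of condition labels.
#' @return A `ct_table` restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(is.ct_table(x))
  missing <- setdiff(samples, rownames(x$ct))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- rownames(x$ct) %in% samples
  ct_table(x$ct[keep, , drop = FALSE], x$meta[keep, , drop = FALSE])
}

#' @rdname subset_samples
#' @export
subset_conditions <- function(x, conditions) {
  stopifnot(is.ct_table(x))
  unknown <- setdiff(conditions, .condition_levels())
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- x$meta$condition %in% conditions
  if (!any(keep))
    stop("no samples in condition(s): ", paste(conditions, collapse = ", "),
         call. = FALSE)
  ct_table(x$ct[keep, , drop = FALSE], x$meta[keep, , drop = FALSE])
}

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a Ct table from a delimited file
#'
#' Wide format: one row per sample with columns
#' `sample,donor,condition,<gene1>,<gene2>,...`. Long format: one row per
#' measurement with columns `sample,donor,condition,gene,ct`. The delimiter
#' is inferred from the extension (`.csv` comma, `.tsv`/`.txt` tab) and can
#' be overridden.
#'
#' Long files may carry technical replicates (repeated `(sample, gene)`
#' records); pass `collapse = "mean"` or `"median"` to average them on
#' read, otherwise repeated records are an error (see
#' [collapse_duplicates()]).
#'
#' @param path Path to the file.
#' @param format `"wide"` or `"long"`.
#' @param sep Field delimiter; default inferred from the extension.
#' @param collapse Optional duplicate-collapsing rule for long files.
#' @return A validated `ct_table`.
#' @examples
#' path <- system.file("extdata", "asc_hkg_ct.csv", package = "refstab")
#' tab <- read_ct_table(path)
#' tab$ct["ASC1 F", "ACTB"]
#' @export
read_ct_table <- function(path, format = c("wide", "long"), sep = NULL,
                          collapse = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .infer_sep(path, sep)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 4)
    stop("cannot parse ", path, ": no data rows or too few columns",
         call. = FALSE)

  if (format == "wide") {
    need <- c("sample", "donor", "condition")
    if (!all(need %in% names(df)))
      stop("wide file must have columns sample, donor, condition; got: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$sample))
      stop("duplicate sample row(s) in wide file: ",
           paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
           call. = FALSE)
    genes <- setdiff(names(df), need)
    ct <- as.matrix(df[, genes, drop = FALSE])
    if (!is.numeric(ct))
      stop("cannot parse ", path, ": non-numeric Ct values", call. = FALSE)
    rownames(ct) <- df$sample
    ct_table(ct, df[, need, drop = FALSE])
  } else {
    need <- c("sample", "donor", "condition", "gene", "ct")
    if (!all(need %in% names(df)))
      stop("long file must have columns sample, donor, condition, gene, ct",
           call. = FALSE)
    if (anyDuplicated(df[, c("sample", "gene")])) {
      if (is.null(collapse))
        stop("repeated (sample, gene) records; pass collapse = \"mean\" or ",
             "\"median\", or use collapse_duplicates()", call. = FALSE)
      return(collapse_duplicates(df, rule = collapse))
    }
    .long_to_table(df)
  }
}

.long_to_table <- function(df) {
  samples <- unique(df$sample)
  genes <- unique(df$gene)
  ct <- matrix(NA_real_, length(samples), length(genes),
               dimnames = list(samples, genes))
  ct[cbind(match(df$sample, samples), match(df$gene, genes))] <- df$ct
  meta <- unique(df[, c("sample", "donor", "condition"), drop = FALSE])
  if (anyDuplicated(meta$sample))
    stop("inconsistent metadata for sample(s): ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "),
         call. = FALSE)
  ct_table(ct, meta)
}

#' Collapse technical replicates into one Ct per cell
#'
#' Takes long-format measurement records (columns
#' `sample,donor,condition,gene,ct`) in which a `(sample, gene)` pair may
#' appear several times — e.g. qPCR technical duplicates — and collapses
#' each cell to a single value. Replicates disagreeing by more than 1 cycle
#' are collapsed anyway but flagged with a warning, since such spread
#' usually indicates a pipetting or amplification problem.
#'
#' @param records data.frame of long-format records.
#' @param rule `"mean"` (default) or `"median"`.
#' @return A `ct_table` with one value per cell; the rule used is recorded
#'   in the `"collapse_rule"` attribute.
#' @export
collapse_duplicates <- function(records, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  need <- c("sample", "donor", "condition", "gene", "ct")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("`records` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  f <- interaction(records$sample, records$gene, drop = TRUE)
  spread <- tapply(records$ct, f, function(v) diff(range(v)))
  wide_cells <- names(spread)[spread > 1.0]
  if (length(wide_cells))
    warning("technical replicates differ by > 1 cycle in cell(s): ",
            paste(wide_cells, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(
    ct ~ sample + donor + condition + gene, data = records,
    FUN = if (rule == "mean") mean else stats::median)
  out <- .long_to_table(agg[order(match(agg$sample, unique(records$sample)),
                                  match(agg$gene, unique(records$gene))), ])
  attr(out, "collapse_rule") <- rule
  out
}

#' Write a Ct table to a delimited file
#'
#' @param x A `ct_table`.
#' @param path Output path; delimiter inferred from the extension.
#' @param format `"wide"` or `"long"`.
#' @param sep Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, format = c("wide", "long"), sep = NULL) {
  stopifnot(is.ct_table(x))
  format <- match.arg(format)
  sep <- .infer_sep(path, sep)
  if (format == "wide") {
    df <- cbind(x$meta[, c("sample", "donor", "condition")],
                as.data.frame(x$ct, check.names = FALSE))
  } else {
    df <- data.frame(
      sample = rep(rownames(x$ct), times = ncol(x$ct)),
      donor = rep(x$meta$donor, times = ncol(x$ct)),
      condition = rep(x$meta$condition, times = ncol(x$ct)),
      gene = rep(colnames(x$ct), each = nrow(x$ct)),
      ct = as.vector(x$ct),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample control readings
#'
#' Controls file format: `sample,ppc,rtc` where `ppc` is the Ct of the
#' positive PCR control and `rtc` the Ct of the reverse-transcription
#' control for that sample.
#'
#' @param path Path to the CSV/TSV file.
#' @param sep Optional delimiter override.
#' @return A data.frame of class `control_readings`.
#' @export
read_controls <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .infer_sep(path, sep),
                          stringsAsFactors = FALSE)
  control_readings(df$sample, df$ppc, df$rtc)
}

#' Construct control readings
#'
#' @param sample Sample identifiers.
#' @param ppc Positive-PCR-control Ct per sample (cycles).
#' @param rtc Reverse-transcription-control Ct per sample (cycles).
#' @return A data.frame of class `control_readings`.
#' @export
control_readings <- function(sample, ppc, rtc) {
  if (!all(is.finite(ppc)) || !all(is.finite(rtc)))
    stop("control readings must all be finite", call. = FALSE)
  if (anyDuplicated(sample))
    stop("duplicate sample identifiers in controls", call. = FALSE)
  structure(data.frame(sample = sample, ppc = ppc, rtc = rtc,
                       stringsAsFactors = FALSE),
            class = c("control_readings", "data.frame"))
}

#' Amplification call for a Ct value
#'
#' A measurement is called amplified when its Ct is strictly below 35
#' cycles; missing values are called not amplified. Vectorised.
#'
#' @param ct Numeric vector of Ct values (may contain `NA`).
#' @return Logical vector.
#' @examples
#' call_amplification(c(27.11, 35, 34.99, NA))
#' @export
call_amplification <- function(ct) {
  !is.na(ct) & ct < 35
}

#' The packaged adipose-MSC housekeeping-gene Ct dataset
#'
#' Final (technically normalized) Ct values of five candidate reference
#' genes (*ACTB*, *B2M*, *GAPDH*, *HPRT1*, *RPLP0*) measured in
#' adipose-derived mesenchymal stromal cells from three donors under five
#' culture conditions: serum (F), serum + IL-1 beta (F+IL1), starvation
#' (S), starvation + IL-1 beta (S+IL1), and starvation after IL-1 beta
#' priming (F+IL1/S). 15 samples x 5 genes, complete.
#'
#' @return A `ct_table`.
#' @examples
#' asc_ct()
#' @export
asc_ct <- function() {
  read_ct_table(system.file("extdata", "asc_hkg_ct.csv", package = "refstab"))
}
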