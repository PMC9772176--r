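#' Expression matrix with a sample design
#'
#' Container for a genes-by-samples matrix of non-negative expression
#' values (raw counts or RPKM) together with the sample-to-condition
#' design. Every downstream testing operation requires at least two
#' replicates per condition.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene
#'   ids), samples in columns (unique colnames = sample ids). All values
#'   must be finite and non-negative.
#' @param design Data frame with columns `sample` and `condition` mapping
#'   every column of `values` to a condition; optional `replicate` and
#'   `total_mapped` (per-sample mapped-read totals for RPKM, e.g. the
#'   sequencing depth) columns are carried along.
#' @param unit Either `"counts"` or `"rpkm"`.
#' @param gene_lengths Optional named numeric vector of effective gene
#'   lengths in bp (for RPKM); defaults to 1000 bp for every gene.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `design`, `unit`, `gene_lengths`.
#' @export
ExpressionMatrix <- function(values, design, unit = c("counts", "rpkm"),
                             gene_lengths = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (gene ids); duplicated: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames (sample ids)")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  design <- as.data.frame(design)
  if (!all(c("sample", "condition") %in% names(design)))
    stop("`design` needs columns `sample` and `condition`")
  missing_smp <- setdiff(colnames(values), design$sample)
  if (length(missing_smp) > 0)
    stop("sample(s) absent from design: ", paste(missing_smp, collapse = ", "))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (is.null(gene_lengths)) {
    gene_lengths <- setNames(rep(1000, nrow(values)), rownames(values))
  } else {
    if (is.null(names(gene_lengths)) ||
        !all(rownames(values) %in% names(gene_lengths)))
      stop("`gene_lengths` must be named and cover every gene")
    gene_lengths <- gene_lengths[rownames(values)]
    if (any(!is.finite(gene_lengths) | gene_lengths <= 0))
      stop("gene lengths must be positive")
  }
  total_mapped <- NULL
  if ("total_mapped" %in% names(design)) {
    total_mapped <- setNames(as.numeric(design$total_mapped), design$sample)
    if (any(!is.finite(total_mapped) | total_mapped <= 0))
      stop("total_mapped must be positive for every sample")
  }
  structure(list(values = values, design = design, unit = unit,
                 gene_lengths = gene_lengths, total_mapped = total_mapped),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$design$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

# samples belonging to one condition, with a replicate-count check
condition_samples <- function(x, condition, min_replicates = 2L) {
  smp <- x$design$sample[x$design$condition == condition]
  if (length(smp) < min_replicates)
    stop(sprintf("condition '%s' has %d replicate(s); need >= %d",
                 condition, length(smp), min_replicates))
  smp
}
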