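#' Normalize condition means to the average over expressed genes
#'
#' Each gene's condition-mean RPKM is divided by the arithmetic mean of
#' the condition-mean RPKM over the expressed genes of that condition,
#' so the normalized expression averages to exactly 1 over expressed
#' genes. This tempers the extreme fold changes that arise at low
#' expression before classifying DEGs by level.
#'
#' @param mean_rpkm Numeric vector of condition-mean RPKM, one per gene.
#' @param expressed Logical mask of "expressed" genes used for the
#'   denominator (default: mean RPKM strictly above 0).
#' @return Numeric vector of normalized expression.
#' @export
normalize_to_average <- function(mean_rpkm, expressed = mean_rpkm > 0) {
  if (length(mean_rpkm) == 0 || !any(expressed))
    stop("no expressed genes in this condition; cannot normalize")
  mean_rpkm / mean(mean_rpkm[expressed])
}

#' Classify DEGs into the six expression-level clusters
#'
#' DEGs are classified by direction and by whether their
#' average-normalized expression sits below or above 1 in each condition
#' (a = control, b = mutant):
#'
#' | label | direction | control | mutant |
#' |-------|-----------|---------|--------|
#' | C1    | down      | < 1     | < 1    |
#' | C2    | up        | < 1     | < 1    |
#' | C3    | down      | > 1     | < 1    |
#' | C4    | up        | < 1     | > 1    |
#' | C5    | down      | > 1     | > 1    |
#' | C6    | up        | > 1     | > 1    |
#'
#' The two logically possible but undescribed combinations (down with
#' control < 1 and mutant > 1; up with control > 1 and mutant < 1) and
#' exact ties at 1 are reported as `unclassified` rather than forced
#' into a cluster.
#'
#' @param status Character vector, each `"up"` or `"down"` (other values
#'   are rejected: only DEGs are classified).
#' @param norm_a,norm_b Non-negative normalized expression in control
#'   and mutant (see [normalize_to_average()]); zero (a gene silent in
#'   one condition) is simply below average.
#' @return Character vector of labels in
#'   `{C1,...,C6, unclassified}`.
#' @export
classify_cluster <- function(status, norm_a, norm_b) {
  if (!all(status %in% c("up", "down")))
    stop("only DEGs (status 'up' or 'down') are classified; got: ",
         paste(unique(setdiff(status, c("up", "down"))), collapse = ", "))
  if (any(!is.finite(norm_a) | norm_a < 0) ||
      any(!is.finite(norm_b) | norm_b < 0))
    stop("normalized expression must be non-negative and finite")
  lab <- rep("unclassified", length(status))
  down <- status == "down"; up <- status == "up"
  lab[down & norm_a < 1 & norm_b < 1] <- "C1"
  lab[up   & norm_a < 1 & norm_b < 1] <- "C2"
  lab[down & norm_a > 1 & norm_b < 1] <- "C3"
  lab[up   & norm_a < 1 & norm_b > 1] <- "C4"
  lab[down & norm_a > 1 & norm_b > 1] <- "C5"
  lab[up   & norm_a > 1 & norm_b > 1] <- "C6"
  lab
}

#' Classify every DEG of a contrast
#'
#' Convenience wrapper: normalizes each condition's mean RPKM to the
#' average over expressed genes of that condition (over the full result
#' table, not just DEGs), then labels the DEG subset.
#'
#' @param result A `contrast_result` from [call_degs()].
#' @param expressed_min Expression threshold defining "expressed" for the
#'   normalization denominator (default 0, strict `>`).
#' @return Data frame with `gene_id`, `status`, `norm_expr_a`,
#'   `norm_expr_b`, `cluster` for the DEGs.
#' @export
assign_clusters <- function(result, expressed_min = 0) {
  stopifnot(is.data.frame(result))
  na <- normalize_to_average(result$mean_rpkm_a,
                             result$mean_rpkm_a > expressed_min)
  nb <- normalize_to_average(result$mean_rpkm_b,
                             result$mean_rpkm_b > expressed_min)
  deg <- result$status %in% c("up", "down")
  data.frame(gene_id = result$gene_id[deg],
             status = result$status[deg],
             norm_expr_a = na[deg], norm_expr_b = nb[deg],
             cluster = classify_cluster(result$status[deg], na[deg], nb[deg]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster composition table with partition checks
#'
#' Tabulates cluster sizes and verifies that they partition the DEGs:
#' the sizes sum to the number of DEGs, and (when no DEG is
#' unclassified) the odd clusters C1/C3/C5 sum to the downregulated
#' count and C2/C4/C6 to the upregulated count.
#'
#' @param assignments Data frame from [assign_clusters()] (needs
#'   `cluster` and `status` columns), or a character vector of labels
#'   with a parallel `status` argument.
#' @param status Optional status vector when `assignments` is a vector.
#' @return List with `sizes` (named integer vector over C1..C6 and
#'   unclassified), `n_deg`, `n_down`, `n_up`, `down_cluster_sum`,
#'   `up_cluster_sum`.
#' @export
cluster_counts <- function(assignments, status = NULL) {
  if (is.data.frame(assignments)) {
    labels <- assignments$cluster
    status <- assignments$status
  } else {
    labels <- assignments
    if (is.null(status)) stop("need DEG statuses alongside the labels")
  }
  levels <- c("C1", "C2", "C3", "C4", "C5", "C6", "unclassified")
  sizes <- table(factor(labels, levels = levels))
  sizes <- setNames(as.integer(sizes), levels)
  n_deg <- length(labels)
  stopifnot(sum(sizes) == n_deg)
  list(sizes = sizes,
       n_deg = n_deg,
       n_down = sum(status == "down"),
       n_up = sum(status == "up"),
       down_cluster_sum = sum(sizes[c("C1", "C3", "C5")]),
       up_cluster_sum = sum(sizes[c("C2", "C4", "C6")]))
}
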