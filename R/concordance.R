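# round half away from zero to one decimal, the convention used for
# printed percentages (base round() is banker's rounding)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pearson correlation with t-distribution p-value
#'
#' Sample Pearson coefficient with the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` under a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_with_pvalue <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 paired finite values")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Direction concordance percentage between two contrasts
#'
#' `100 * n_concordant / n_total`, rounded half away from zero to one
#' decimal — the arithmetic behind printed summaries such as
#' "646 of 707 (91.4%)".
#'
#' @param n_concordant,n_total Non-negative counts, `n_total > 0`.
#' @return Percentage to one decimal.
#' @export
concordance_percentage <- function(n_concordant, n_total) {
  if (any(n_total <= 0)) stop("denominator must be positive")
  round_half_away(100 * n_concordant / n_total, 1)
}

#' Sign-quadrant summary of paired log2 fold changes
#'
#' Counts genes per sign quadrant of the `(x, y)` log2FC plane (exact
#' zeros sit on an axis and are excluded from quadrants, reported via
#' `n_axis`), the Pearson correlation with its t-distribution p-value,
#' and per-direction concordance percentages: of the genes with the
#' stated `x` direction (and off-axis `y`), the percentage with each `y`
#' direction, rounded half away from zero to one decimal.
#'
#' @param log2fc_x,log2fc_y Paired finite log2 fold changes.
#' @return A `concordance_summary` list: `n`, `n_axis`, `r`, `p_value`,
#'   `quadrant_counts` (named `up_up`, `up_down`, `down_up`,
#'   `down_down`), `concordance_pct` (same names; `NA` when the
#'   denominator is empty).
#' @export
quadrant_summary <- function(log2fc_x, log2fc_y) {
  if (length(log2fc_x) == 0) stop("empty input")
  if (length(log2fc_x) != length(log2fc_y)) stop("x and y must be paired")
  if (any(!is.finite(log2fc_x)) || any(!is.finite(log2fc_y)))
    stop("log2 fold changes must be finite")
  n <- length(log2fc_x)
  on_axis <- log2fc_x == 0 | log2fc_y == 0
  x <- log2fc_x[!on_axis]; y <- log2fc_y[!on_axis]
  counts <- c(up_up = sum(x > 0 & y > 0),
              up_down = sum(x > 0 & y < 0),
              down_up = sum(x < 0 & y > 0),
              down_down = sum(x < 0 & y < 0))
  n_up <- sum(x > 0); n_down <- sum(x < 0)
  pct <- c(up_up = if (n_up > 0) concordance_percentage(counts[["up_up"]], n_up) else NA_real_,
           up_down = if (n_up > 0) concordance_percentage(counts[["up_down"]], n_up) else NA_real_,
           down_up = if (n_down > 0) concordance_percentage(counts[["down_up"]], n_down) else NA_real_,
           down_down = if (n_down > 0) concordance_percentage(counts[["down_down"]], n_down) else NA_real_)
  cor_res <- if (n >= 3 && var(log2fc_x) > 0 && var(log2fc_y) > 0)
    pearson_with_pvalue(log2fc_x, log2fc_y)
  else list(r = NA_real_, p_value = NA_real_, n = n)
  structure(list(n = n, n_axis = sum(on_axis), r = cor_res$r,
                 p_value = cor_res$p_value, quadrant_counts = counts,
                 concordance_pct = pct),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance over %d genes (%d on an axis): r = %.3f, p = %.3g\n",
              x$n, x$n_axis, x$r, x$p_value))
  cat("quadrants:",
      paste(sprintf("%s=%d", names(x$quadrant_counts), x$quadrant_counts),
            collapse = ", "), "\n")
  cat("percent by x-direction:",
      paste(sprintf("%s=%.1f", names(x$concordance_pct), x$concordance_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare two contrasts over a named gene selection
#'
#' Joins two contrast result tables by `gene_id` (genes present in both
#' form the comparison universe) and summarizes the selected subset's
#' log2 fold changes with [quadrant_summary()]. Selections: `all` genes
#' of the universe, `degs_x` / `degs_y` (DEGs of one contrast), or
#' `common_degs` (DEG in both).
#'
#' @param results_x,results_y Data frames with `gene_id`, `log2_fc` and
#'   `status` columns ([call_degs()] output or an external contrast
#'   table).
#' @param selection One of `"all"`, `"degs_x"`, `"degs_y"`,
#'   `"common_degs"`.
#' @return A `concordance_summary` with an added `selection` element and
#'   `scatter` data frame (`gene_id`, `log2fc_x`, `log2fc_y`).
#' @export
subset_compare <- function(results_x, results_y,
                           selection = c("all", "degs_x", "degs_y",
                                         "common_degs")) {
  selection <- match.arg(selection)
  merged <- merge(results_x[, c("gene_id", "log2_fc", "status")],
                  results_y[, c("gene_id", "log2_fc", "status")],
                  by = "gene_id", suffixes = c("_x", "_y"))
  deg_x <- merged$status_x %in% c("up", "down")
  deg_y <- merged$status_y %in% c("up", "down")
  keep <- switch(selection,
                 all = rep(TRUE, nrow(merged)),
                 degs_x = deg_x,
                 degs_y = deg_y,
                 common_degs = deg_x & deg_y)
  keep <- keep & is.finite(merged$log2_fc_x) & is.finite(merged$log2_fc_y)
  if (!any(keep))
    stop(sprintf("empty selection '%s': no genes to compare", selection))
  sub <- merged[keep, , drop = FALSE]
  out <- quadrant_summary(sub$log2_fc_x, sub$log2_fc_y)
  out$selection <- selection
  out$scatter <- data.frame(gene_id = sub$gene_id,
                            log2fc_x = sub$log2_fc_x,
                            log2fc_y = sub$log2_fc_y,
                            stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Relative quantification from a qPCR CT table
#'
#' Delta-Ct normalization against the reference gene:
#' `dCT_cond = mean(CT_target - CT_reference)` per condition,
#' `ddCT = dCT_b - dCT_a`, `fold_change = 2^(-ddCT)`. The signed fold
#' change follows the same negative-reciprocal convention as the RNA-seq
#' side.
#'
#' @param table qPCR table (see [read_qpcr()]).
#' @param target Target gene name.
#' @param cond_b,cond_a Condition labels (b vs a, e.g. mutant vs
#'   control).
#' @return List with `target_gene`, `delta_delta_ct`, `fold_change`,
#'   `log2_fc`, `signed_fc`.
#' @export
qpcr_fold_change <- function(table, target, cond_b, cond_a) {
  rows <- table[table$target_gene == target, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for target gene ", target)
  dct <- function(cond) {
    sub <- rows[rows$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("no qPCR rows for target '%s' in condition '%s'",
                   target, cond))
    mean(sub$ct_target - sub$ct_reference)
  }
  ddct <- dct(cond_b) - dct(cond_a)
  fc <- 2^(-ddct)
  list(target_gene = target, delta_delta_ct = ddct, fold_change = fc,
       log2_fc = -ddct, signed_fc = if (fc >= 1) fc else -1 / fc)
}

#' Correlate qPCR and RNA-seq fold changes
#'
#' Pearson correlation (with t-distribution p-value) of the log2 fold
#' changes of the genes shared between a qPCR panel and an RNA-seq
#' contrast. Computed on the log2 scale, which avoids the discontinuity
#' of the signed-fold-change convention.
#'
#' @param qpcr_log2fc Named numeric vector of qPCR log2 fold changes.
#' @param rnaseq_log2fc Named numeric vector of RNA-seq log2 fold
#'   changes.
#' @return List with `r`, `p_value`, `n`.
#' @export
validate_qpcr <- function(qpcr_log2fc, rnaseq_log2fc) {
  shared <- intersect(names(qpcr_log2fc), names(rnaseq_log2fc))
  if (length(shared) < 3)
    stop("need >= 3 shared genes between qPCR and RNA-seq")
  pearson_with_pvalue(qpcr_log2fc[shared], rnaseq_log2fc[shared])
}
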