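#' Reads per kilobase per million mapped reads
#'
#' `rpkm = counts * 1e9 / (gene_length_bp * total_mapped)`, applied
#' column-wise.
#'
#' @param counts Numeric vector (one gene across samples) or matrix
#'   (genes x samples) of raw counts.
#' @param gene_length_bp Positive gene length(s) in bp; recycled across
#'   genes for a matrix.
#' @param total_mapped Positive per-sample totals of mapped reads.
#' @return Same shape as `counts`, in RPKM units.
#' @export
compute_rpkm <- function(counts, gene_length_bp, total_mapped) {
  if (any(!is.finite(gene_length_bp) | gene_length_bp <= 0))
    stop("gene lengths must be positive")
  if (any(!is.finite(total_mapped) | total_mapped <= 0))
    stop("total mapped reads must be positive")
  if (is.matrix(counts)) {
    if (length(total_mapped) != ncol(counts))
      stop("need one total per sample column")
    sweep(counts / gene_length_bp, 2, total_mapped, "/") * 1e9
  } else {
    counts * 1e9 / (gene_length_bp * total_mapped)
  }
}

#' Signed fold change under the negative-reciprocal convention
#'
#' With pseudocount-stabilized means `m_a`, `m_b`, the expression ratio
#' is `m_b / m_a`; a ratio below 1 is reported as its negative
#' reciprocal, so a 40-fold drop appears as -40 and `|signed_fc| >= 1`
#' always. `log2_fc = log2(ratio)` shares the same sign. When both means
#' and the pseudocount are zero the fold change is undefined and `NA` is
#' returned (never an error).
#'
#' @param mean_b,mean_a Non-negative condition means (b = numerator,
#'   conventionally the mutant; a = denominator, the control).
#' @param pseudocount Non-negative value added to both means (default
#'   0.01) to tame division by near-zero expression.
#' @return Data frame with columns `signed_fc`, `log2_fc`.
#' @export
signed_fold_change <- function(mean_b, mean_a, pseudocount = 0.01) {
  if (length(pseudocount) != 1 || !is.finite(pseudocount) || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE))
    stop("condition means must be non-negative")
  ma <- mean_a + pseudocount
  mb <- mean_b + pseudocount
  ratio <- mb / ma
  undef <- ma == 0 & mb == 0
  signed <- ifelse(ratio >= 1, ratio, -1 / ratio)
  l2 <- log2(ratio)
  signed[undef] <- NA_real_
  l2[undef] <- NA_real_
  data.frame(signed_fc = signed, log2_fc = l2)
}

# vectorized two-sample t over matrix rows; returns p, t, df, zero-variance flag
row_t_test <- function(a, b, mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 replicates")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (mode == "pooled") {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  zero_var <- se == 0
  tstat <- (mb - ma) / se
  p <- 2 * pt(-abs(tstat), df)
  # zero variance: equal means -> p = 1; unequal -> smallest positive double
  p[zero_var & mb == ma] <- 1
  p[zero_var & mb != ma] <- .Machine$double.xmin
  list(p_value = p, statistic = tstat, df = df, zero_variance = zero_var,
       mean_a = ma, mean_b = mb)
}

#' Two-tailed two-sample t-test
#'
#' Student's pooled-variance t (df `n_a + n_b - 2`) or Welch's t with
#' Satterthwaite df. Degenerate inputs follow an explicit policy: zero
#' variance in both groups with equal means gives `p = 1`; zero variance
#' with unequal means gives the smallest representable positive p,
#' flagged via `zero_variance`.
#'
#' @param group_a,group_b Numeric vectors of at least 2 finite values.
#' @param mode `"pooled"` (default) or `"welch"`.
#' @return List with `p_value`, `statistic`, `df`, `zero_variance`.
#' @export
t_test_two_tailed <- function(group_a, group_b, mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 finite values")
  res <- row_t_test(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1),
                    mode = mode)
  list(p_value = res$p_value[1], statistic = res$statistic[1],
       df = res$df[1], zero_variance = res$zero_variance[1])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment. Inputs outside `(0, 1]` are rejected.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes for one contrast
#'
#' Per gene: condition-mean RPKM in both conditions, signed fold change
#' (negative-reciprocal convention) on the raw mean RPKM, a two-tailed
#' t-test on `log2(RPKM + 1)` (default; raw RPKM by flag), BH q-values,
#' and a status under the three-part DEG rule: `up` if
#' `signed_fc >= fc_min` and `q < q_max`; `down` if
#' `signed_fc <= -fc_min` and `q < q_max`; `filtered` if the mean RPKM is
#' `<= rpkm_min` in both conditions (regardless of p); otherwise `ns`.
#'
#' @param x An [ExpressionMatrix()] (counts or RPKM).
#' @param condition_a,condition_b Condition labels in the design
#'   (a = control/reference, b = mutant/test).
#' @param fc_min Minimum `|signed_fc|` (default 2).
#' @param q_max Maximum q-value (default 0.05).
#' @param rpkm_min Expression filter: mean RPKM must exceed this in at
#'   least one condition (default 1, strict `>`).
#' @param test `"pooled"` (default) or `"welch"`.
#' @param on Test on `"log2"`-transformed (`log2(RPKM+1)`, default) or
#'   `"raw"` RPKM.
#' @param pseudocount Pseudocount for [signed_fold_change()].
#' @param total_mapped Optional per-sample mapped-read totals for RPKM.
#'   Defaults to the design's `total_mapped` column when present (the
#'   preferred source: genome-wide mapped totals, not just the genes in
#'   the table), else to the column sums of the count matrix.
#' @return A `contrast_result` data frame: `gene_id`, `mean_rpkm_a`,
#'   `mean_rpkm_b`, `signed_fc`, `log2_fc`, `p_value`, `q_value`,
#'   `status`, `zero_variance`.
#' @export
call_degs <- function(x, condition_a, condition_b, fc_min = 2, q_max = 0.05,
                      rpkm_min = 1, test = c("pooled", "welch"),
                      on = c("log2", "raw"), pseudocount = 0.01,
                      total_mapped = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  test <- match.arg(test); on <- match.arg(on)
  if (fc_min < 1) stop("fc_min must be >= 1")
  smp_a <- condition_samples(x, condition_a)
  smp_b <- condition_samples(x, condition_b)
  if (x$unit == "counts") {
    if (is.null(total_mapped)) total_mapped <- x$total_mapped
    if (is.null(total_mapped)) total_mapped <- colSums(x$values)
    total_mapped <- total_mapped[colnames(x$values)]
    rpkm <- compute_rpkm(x$values, x$gene_lengths, total_mapped)
  } else {
    rpkm <- x$values
  }
  ra <- rpkm[, smp_a, drop = FALSE]
  rb <- rpkm[, smp_b, drop = FALSE]
  mean_a <- rowMeans(ra)
  mean_b <- rowMeans(rb)
  if (on == "log2") {
    tt <- row_t_test(log2(ra + 1), log2(rb + 1), mode = test)
  } else {
    tt <- row_t_test(ra, rb, mode = test)
  }
  fc <- signed_fold_change(mean_b, mean_a, pseudocount = pseudocount)
  q <- bh_adjust(tt$p_value)
  filtered <- !(pmax(mean_a, mean_b) > rpkm_min)
  status <- rep("ns", nrow(rpkm))
  status[!filtered & !is.na(fc$signed_fc) &
           fc$signed_fc >= fc_min & q < q_max] <- "up"
  status[!filtered & !is.na(fc$signed_fc) &
           fc$signed_fc <= -fc_min & q < q_max] <- "down"
  status[filtered] <- "filtered"
  out <- data.frame(gene_id = rownames(rpkm),
                    mean_rpkm_a = mean_a, mean_rpkm_b = mean_b,
                    signed_fc = fc$signed_fc, log2_fc = fc$log2_fc,
                    p_value = tt$p_value, q_value = q, status = status,
                    zero_variance = tt$zero_variance,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Threshold-only developmental DEG labels
#'
#' Stage-to-stage calls made on the signed fold change alone, with no
#' significance test: `dev_up` when `fc > fc_min`, `dev_down` when
#' `fc < -fc_min`, else `dev_ns`.
#'
#' @param signed_fc Vector of signed fold changes (negative-reciprocal
#'   convention).
#' @param fc_min Threshold (default 2), strict inequality.
#' @return Character vector of labels.
#' @export
call_developmental_degs <- function(signed_fc, fc_min = 2) {
  out <- rep("dev_ns", length(signed_fc))
  out[!is.na(signed_fc) & signed_fc > fc_min] <- "dev_up"
  out[!is.na(signed_fc) & signed_fc < -fc_min] <- "dev_down"
  out
}
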