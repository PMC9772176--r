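# Independent oracles used to check the analytical routines. These stay
# deliberately naive: direct definitions, enumeration, or numerical
# integration, never the code paths they verify.

# two-tailed t-tail probability by numerical integration of the t density
t_pvalue_by_integration <- function(tstat, df) {
  dens <- function(u) (1 + u^2 / df)^(-(df + 1) / 2)
  norm <- integrate(dens, -Inf, Inf, rel.tol = 1e-12)$value
  2 * integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value / norm
}

# Benjamini-Hochberg by the step-up definition: q_(i) = min_{j>=i} p_(j)*n/j
bh_by_definition <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(ps * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- q
  out
}

# upper-tail hypergeometric by explicit summation over the overlap count
hyper_tail_by_enumeration <- function(overlap, term_size, bg_size, query_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) * choose(bg_size - term_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# permutation p-value for a Pearson correlation (shuffle y), vectorized
pearson_permutation_p <- function(x, y, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  n <- length(x)
  r_obs <- cor(x, y)
  xs <- (x - mean(x)) / sd(x)
  perm <- replicate(n_perm, sample(y))
  perm <- (perm - mean(y)) / sd(y)
  r_null <- as.numeric(crossprod(xs, perm)) / (n - 1)
  (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
}

# small two-condition expression matrix built directly from values
tiny_matrix <- function(values, unit = "rpkm", k = ncol(values) / 2,
                        total_mapped = NULL) {
  colnames(values) <- c(sprintf("a%d", seq_len(k)), sprintf("b%d", seq_len(k)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  design <- data.frame(sample = colnames(values),
                       condition = rep(c("ctrl", "mut"), each = k))
  if (!is.null(total_mapped)) design$total_mapped <- total_mapped
  ExpressionMatrix(values, design, unit = unit)
}
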