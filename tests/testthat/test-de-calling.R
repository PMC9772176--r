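test_that("RPKM follows counts * 1e9 / (length * total)", {
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_rpkm(10, 2000, 2e7), 0.25)
  m <- matrix(c(1000, 10, 2000, 20), nrow = 2)
  rpkm <- compute_rpkm(m, c(1000, 2000), c(1e6, 1e7))
  expect_equal(rpkm[1, 1], 1000)
  expect_equal(rpkm[2, 2], 1)
  expect_error(compute_rpkm(5, 1000, 0), "positive")
  expect_error(compute_rpkm(5, 0, 1e6), "positive")
})

test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fold_change(5, 5, 0),
               data.frame(signed_fc = 1, log2_fc = 0))
  # a 40-fold drop is reported as -40
  expect_equal(signed_fold_change(1, 40, 0)$signed_fc, -40)
  expect_equal(signed_fold_change(8, 2, 0),
               data.frame(signed_fc = 4, log2_fc = 2))
  # undefined at 0/0 with no pseudocount: NA sentinel, not an error
  both0 <- signed_fold_change(0, 0, 0)
  expect_true(is.na(both0$signed_fc) && is.na(both0$log2_fc))
  expect_error(signed_fold_change(-1, 2), "non-negative")
})

test_that("signed fold change is antisymmetric and bounded away from 0", {
  set.seed(42)
  a <- rlnorm(300, 3, 2); b <- rlnorm(300, 3, 2)
  fwd <- signed_fold_change(b, a, 0.01)
  rev <- signed_fold_change(a, b, 0.01)
  expect_equal(fwd$signed_fc, -rev$signed_fc, tolerance = 1e-12)
  expect_equal(fwd$log2_fc, -rev$log2_fc, tolerance = 1e-12)
  expect_true(all(abs(fwd$signed_fc) >= 1))
  expect_true(all(sign(fwd$log2_fc) == sign(fwd$signed_fc) |
                    fwd$log2_fc == 0))
})

test_that("t-test handles equal-mean and zero-variance inputs by policy", {
  res <- t_test_two_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$p_value, 1)
  expect_true(res$zero_variance)
  # equal means with spread: t = 0 so p = 1
  expect_equal(t_test_two_tailed(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  res <- t_test_two_tailed(c(2, 2, 2), c(5, 5, 5))
  expect_equal(res$p_value, .Machine$double.xmin)
  expect_true(res$zero_variance)
  expect_error(t_test_two_tailed(1, c(1, 2)), ">= 2")
})

test_that("pooled t-test p matches the integrated t density to 6 digits", {
  res <- t_test_two_tailed(c(1, 2, 3), c(10, 11, 12), "pooled")
  # frozen from the numerical-integration oracle (t = 11.0227038425, df 4)
  expect_equal(res$p_value, 0.0003850677114, tolerance = 1e-6)
  expect_equal(res$p_value,
               t_pvalue_by_integration(res$statistic, res$df),
               tolerance = 1e-9)
})

test_that("both t modes agree with stats::t.test on random draws", {
  set.seed(7)
  for (i in 1:30) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    expect_equal(t_test_two_tailed(a, b, "pooled")$p_value,
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(t_test_two_tailed(a, b, "welch")$p_value,
                 t.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_by_definition(p), tolerance = 1e-12)
  }
})

test_that("the expression filter trumps significance", {
  # one flat low gene, one strongly changed low gene, one expressed DEG
  vals <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                   0.9, 0.8, 0.85, 0.1, 0.12, 0.11,
                   10, 11, 9, 55, 52, 57),
                 nrow = 3, byrow = TRUE)
  x <- tiny_matrix(vals, unit = "rpkm", k = 3)
  res <- call_degs(x, "ctrl", "mut")
  expect_equal(res$status, c("filtered", "filtered", "up"))
  expect_gt(res$signed_fc[3], 2)
})

test_that("DEG calls are invariant to gene order and replicate order", {
  cfg <- sim_config(n_genes = 150, seed = 31)
  dat <- simulate_counts(cfg)
  base <- call_degs(dat$matrix, "control", "mutant")

  perm <- sample(nrow(dat$matrix$values))
  xg <- dat$matrix
  xg$values <- xg$values[perm, ]
  xg$gene_lengths <- xg$gene_lengths[perm]
  g <- call_degs(xg, "control", "mutant")
  g <- g[match(base$gene_id, g$gene_id), ]
  rownames(g) <- NULL
  expect_equal(g, base)

  xs <- dat$matrix
  xs$values <- xs$values[, c(3, 1, 2, 5, 6, 4)]
  xs$design <- xs$design[c(3, 1, 2, 5, 6, 4), ]
  s <- call_degs(xs, "control", "mutant")
  expect_equal(s, base)
})

test_that("a strong planted effect at high expression is called up", {
  vals <- matrix(rpois(6 * 20, 100), ncol = 6)
  set.seed(1)
  vals[3, 4:6] <- rpois(3, 100 * 2^5)
  x <- tiny_matrix(vals, unit = "counts", k = 3, total_mapped = 1e6)
  res <- call_degs(x, "ctrl", "mut")
  expect_equal(res$status[3], "up")
  expect_equal(res$log2_fc[3], 5, tolerance = 0.2)
})

test_that("developmental calls use the threshold-only rule", {
  expect_equal(call_developmental_degs(c(2.5, -2.5, 1.5, -1.5, 2, -2, NA)),
               c("dev_up", "dev_down", "dev_ns", "dev_ns", "dev_ns",
                 "dev_ns", "dev_ns"))
})
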