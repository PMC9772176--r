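test_that("a null configuration plants no effects", {
  cfg <- sim_config(n_genes = 100, frac_deg = 0, seed = 11)
  dat <- simulate_counts(cfg)
  expect_true(all(dat$truth$log2fc_planted == 0))
  expect_true(all(!dat$truth$is_deg))
  expect_true(all(dat$truth$direction == "none"))
  expect_equal(nrow(dat$truth), 100)
  expect_false(anyDuplicated(dat$truth$gene_id) > 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 120, seed = 5)
  d1 <- simulate_counts(cfg)
  d2 <- simulate_counts(cfg)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$truth, d2$truth)

  p1 <- simulate_positions(d1$truth$gene_id, d1$truth$is_deg,
                           c(chrA = 2e5, chrB = 2e5), 0.5, seed = 9)
  p2 <- simulate_positions(d1$truth$gene_id, d1$truth$is_deg,
                           c(chrA = 2e5, chrB = 2e5), 0.5, seed = 9)
  expect_identical(p1$loci, p2$loci)

  ids <- d1$truth$gene_id[1:10]
  pr1 <- simulate_promoters(ids, "GATAAG", setNames(c(1L, 2L), ids[1:2]),
                            seed = 3)
  pr2 <- simulate_promoters(ids, "GATAAG", setNames(c(1L, 2L), ids[1:2]),
                            seed = 3)
  expect_identical(as.character(pr1$promoters), as.character(pr2$promoters))
})

test_that("planted condition means follow baseline * 2^effect", {
  cfg <- sim_config(n_genes = 4000, baseline_mean = 200, baseline_sdlog = 0,
                    frac_deg = 0.5, nb_dispersion = 0.01,
                    log2fc = list(min_abs = 3, max_abs = 3, frac_extreme = 0,
                                  extreme_min_abs = 6, extreme_max_abs = 10,
                                  prob_up = 1),
                    seed = 21)
  dat <- simulate_counts(cfg)
  mut <- dat$matrix$values[, dat$matrix$design$condition == "mutant"]
  deg <- dat$truth$is_deg
  # all planted effects are +3, so mutant means should sit near 200*8
  expect_equal(mean(rowMeans(mut[deg, ])), 200 * 8, tolerance = 0.02)
  expect_equal(mean(rowMeans(mut[!deg, ])), 200, tolerance = 0.02)
})

test_that("vanishing dispersion approaches Poisson variance", {
  cfg <- sim_config(n_genes = 5000, baseline_mean = 50, baseline_sdlog = 0,
                    nb_dispersion = 1e-8, frac_deg = 0, seed = 13)
  dat <- simulate_counts(cfg)
  ctrl <- dat$matrix$values[, dat$matrix$design$condition == "control"]
  ratio <- apply(ctrl, 1, var) / rowMeans(ctrl)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("rejected configurations name the broken constraint", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(baseline_mean = -1), "baseline_mean")
  expect_error(sim_config(frac_deg = 1.2), "fractions")
  expect_error(sim_config(n_replicates = 1))
  expect_error(sim_config(motif = "GATN"), "ACGT|A,C,G,T")
})

test_that("companion generator achieves its target correlation", {
  base <- rnorm(5000)
  # perfect correlation: an exact affine transform
  expect_equal(cor(base, simulate_companion_log2fc(base, 1, seed = 1)), 1)
  expect_equal(cor(base, simulate_companion_log2fc(base, -1, seed = 1)), -1)
  # independence target
  y0 <- simulate_companion_log2fc(base, 0, seed = 2)
  expect_lt(abs(cor(base, y0)), 0.05)
  # the developmental-style anti-correlation
  y <- simulate_companion_log2fc(base, -0.67, seed = 3)
  expect_gt(cor(base, y), -0.72)
  expect_lt(cor(base, y), -0.62)
  expect_error(simulate_companion_log2fc(base, -1.2), "target_r")
  expect_error(simulate_companion_log2fc(c(1, 2), 0.5), "length")
})

test_that("full clustering lays DEGs down in adjacent runs", {
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  is_deg <- seq_len(n) <= 40
  pos <- simulate_positions(ids, is_deg, c(chrA = 5e5, chrB = 5e5),
                            cluster_fraction = 1, run_length = c(4L, 4L),
                            seed = 17)
  loci <- pos$loci
  ord <- order(loci$chrom, loci$start)
  deg_mask <- loci$gene_id[ord] %in% ids[is_deg]
  # every DEG slot is adjacent to another DEG slot on the same chromosome
  chrom_ord <- loci$chrom[ord]
  for (i in which(deg_mask)) {
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= n & chrom_ord[nb] == chrom_ord[i]]
    expect_true(any(deg_mask[nb]))
  }
  # runs recorded in the truth table have the requested length
  runs <- table(pos$truth$cluster_id)
  expect_true(all(runs == 4))
  # loci are non-overlapping and ordered within chromosomes
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(diff(sub$start) > sub$length_bp[-nrow(sub)]))
  }
})

test_that("an overfull genome is rejected", {
  expect_error(
    simulate_positions(sprintf("g%d", 1:100), rep(FALSE, 100),
                       c(chrA = 1e4), 0, seed = 1),
    "cannot fit")
})

test_that("promoter copy plans are honored exactly", {
  ids <- sprintf("g%d", 1:12)
  plan <- setNames(c(0L, 1L, 2L, 3L), ids[1:4])
  pro <- simulate_promoters(ids, "GATAAG", plan, seed = 8)
  expect_true(all(Biostrings::width(pro$promoters) == 600))
  counts <- vapply(as.character(pro$promoters),
                   function(s) count_motif(s, "GATAAG")$copy_count,
                   integer(1))
  expect_identical(unname(counts), pro$truth$planted_copies)
  expect_identical(pro$truth$planted_copies, c(0L, 1L, 2L, 3L, rep(0L, 8)))
  expect_error(simulate_promoters(ids, strrep("A", 700), NULL), "longer")
  expect_error(simulate_promoters(ids, "GATAAG", setNames(-1L, ids[1])),
               ">= 0")
})
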