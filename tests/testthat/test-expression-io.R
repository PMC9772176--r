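test_that("expression/design TSVs round-trip through read and write", {
  vals <- matrix(c(0, 1.5, 2, 3.25, 4, 5, 10, 20, 30, 40, 50, 60),
                 nrow = 2, byrow = TRUE)
  rownames(vals) <- c("gA", "gB")
  x <- tiny_matrix(vals, unit = "counts", k = 3, total_mapped = 1e6)
  ef <- tempfile(fileext = ".tsv"); df <- tempfile(fileext = ".tsv")
  write_expression(x, ef, df)
  y <- read_expression(ef, df, unit = "counts")
  expect_equal(y$values, x$values)
  expect_equal(y$design$condition, x$design$condition)
  expect_equal(y$total_mapped, x$total_mapped)
  expect_equal(dim(y$values), c(2L, 6L))
})

test_that("invalid expression input is rejected with its location", {
  ef <- tempfile(fileext = ".tsv"); df <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4",
               "g2\t5\t-1\t6\t7"), ef)
  writeLines(c("sample\tcondition",
               "s1\tctrl", "s2\tctrl", "s3\tmut", "s4\tmut"), df)
  expect_error(read_expression(ef, df), "g2.*s2")

  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4",
               "g1\t5\t1\t6\t7"), ef)
  expect_error(read_expression(ef, df), "duplicate.*g1")

  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4"), ef)
  writeLines(c("sample\tcondition",
               "s1\tctrl", "s2\tctrl", "s3\tmut"), df)
  expect_error(read_expression(ef, df), "s4")
})

test_that("BED input converts to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr2L\t999\t2000\tg1\t0\t+", bed)
  rec <- read_gene_loci(bed, "bed")
  expect_equal(rec$start, 1000L)
  expect_equal(rec$end, 2000L)
  expect_equal(rec$strand, "+")
  expect_equal(rec$tss, 1000L)
})

test_that("GFF3 coordinates are taken as-is and round-trip with BED", {
  loci <- gene_records(c("g1", "g2"), c("chr2L", "chr3R"),
                       c(1000L, 500L), c(2000L, 1499L), c("+", "-"))
  for (fmt in c("bed", "gff3")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_gene_loci(loci, f, fmt)
    back <- read_gene_loci(f, fmt)
    back <- back[match(loci$gene_id, back$gene_id), ]
    rownames(back) <- NULL
    expect_equal(back$start, loci$start, info = fmt)
    expect_equal(back$end, loci$end, info = fmt)
    expect_equal(back$strand, loci$strand, info = fmt)
    expect_equal(back$tss, loci$tss, info = fmt)
  }
})

test_that("records without a proper strand are rejected", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr2L\t999\t2000\tg1\t0\t.", bed)
  expect_error(read_gene_loci(bed, "bed"), "strand")
  expect_error(gene_records("g1", "chr2L", 10L, 5L, "+"), "end < start")
  expect_error(gene_records("g1", "chr2L", 0L, 5L, "+"), ">= 1")
  expect_error(gene_records(c("g1", "g1"), "chr2L", c(1L, 9L),
                            c(5L, 20L), c("+", "+")), "duplicate")
})

test_that("result tables round-trip at full precision", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:5),
                    mean_rpkm_a = c(0, 1/3, pi, 1e-7, 47.9),
                    signed_fc = c(-1919.17, -40, 1, 2, 1320.86),
                    p_value = c(1e-12, 0.049999, 0.5, 1, 0.003),
                    status = c("down", "down", "ns", "ns", "up"),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_results(tab, f, params = list(fc_min = 2))
  back <- read_results(f)
  expect_equal(back$mean_rpkm_a, tab$mean_rpkm_a, tolerance = 1e-12)
  expect_equal(back$signed_fc, tab$signed_fc, tolerance = 1e-12)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-12)
  expect_identical(back$status, tab$status)
})

test_that("an empty result table writes a header-only file", {
  tab <- data.frame(gene_id = character(0), signed_fc = numeric(0))
  f <- tempfile(fileext = ".tsv")
  write_results(tab, f)
  back <- read_results(f)
  expect_equal(nrow(back), 0)
  expect_identical(names(back), names(tab))
})

test_that("qPCR tables are validated on read", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("target_gene\tcondition\treplicate\tct_target\tct_reference",
               "g1\tctrl\t1\t22.5\t16.1"), f)
  tab <- read_qpcr(f)
  expect_equal(tab$ct_target, 22.5)
  writeLines(c("target_gene\tcondition\treplicate\tct_target",
               "g1\tctrl\t1\t22.5"), f)
  expect_error(read_qpcr(f), "ct_reference")
  writeLines(c("target_gene\tcondition\treplicate\tct_target\tct_reference",
               "g1\tctrl\t1\tNA\t16.1"), f)
  expect_error(read_qpcr(f), "finite")
})
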