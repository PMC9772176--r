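test_that("hypergeometric p at the combinatorial corner cases", {
  bg <- sprintf("g%d", 1:10)
  # query of 5 hitting all 5 members of a term: p = 1/C(10,5)
  res <- hypergeometric_enrichment(bg[1:5], bg, list(T1 = bg[1:5]))
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$expected, 2.5)
  # a term equal to the background is hit with certainty
  res <- hypergeometric_enrichment(bg[1:3], bg, list(T1 = bg))
  expect_equal(res$p_value, 1)
  # zero overlap with a small term: p near 1, q capped at 1
  res <- hypergeometric_enrichment(bg[1:5], bg, list(T1 = bg[6:10]))
  expect_gt(res$p_value, 0.9)
  expect_lte(res$q_value, 1)
  expect_error(hypergeometric_enrichment(c(bg[1], "gX"), bg,
                                         list(T1 = bg[1:3])), "gX")
  expect_error(hypergeometric_enrichment(bg[1:2], bg, list(T1 = bg[1])),
               "size")
})

test_that("hypergeometric tail equals brute-force enumeration (bg <= 30)", {
  for (N in c(8, 15, 22, 30)) {
    bg <- sprintf("g%d", seq_len(N))
    for (K in unique(c(3, 5, floor(N / 2), N - 2))) {
      for (k in unique(c(3, floor(N / 3), floor(N / 2)))) {
        query <- bg[seq_len(k)]
        term <- bg[seq(1, 2 * K, by = 2)[seq_len(K)] %% N + 1]
        term <- unique(term)[seq_len(min(K, length(unique(term))))]
        if (length(term) < 3) next
        res <- hypergeometric_enrichment(query, bg, list(T1 = term),
                                         min_term_size = 3)
        expect_equal(res$p_value,
                     hyper_tail_by_enumeration(res$overlap, res$term_size,
                                               N, k),
                     tolerance = 1e-12,
                     info = sprintf("N=%d K=%d k=%d", N, K, k))
      }
    }
  }
})

test_that("a planted enriched term is flagged at q < 0.05", {
  set.seed(18)
  universe <- sprintf("g%d", 1:2000)
  favored <- sample(universe, 120)
  tm <- simulate_term_map(universe, favored, n_terms = 20, n_enriched = 2,
                          seed = 19)
  query <- sample(favored, 80)
  res <- hypergeometric_enrichment(query, universe, tm$term_map)
  enriched <- tm$truth$term_id[tm$truth$enriched]
  expect_true(all(res$q_value[res$term_id %in% enriched] < 0.05))
  expect_true(all(res$q_value[!res$term_id %in% enriched] > 0.05))
})

test_that("promoter extraction honors strand, boundary and truncation", {
  chr <- paste(rep(c("A", "C", "G", "T"), 175), collapse = "")  # 700 bp
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  # + strand TSS at 501: window starts at base 1 of the chromosome
  g <- gene_records("g1", "chr1", 501L, 650L, "+")
  res <- extract_promoter(g, genome)
  expect_false(res$truncated)
  expect_equal(nchar(res$sequence), 600)
  expect_equal(res$sequence, substr(chr, 1, 600))

  # - strand on a 20 bp toy, upstream 3 / downstream 2, TSS = end = 15:
  # forward window [14, 18], promoter = its reverse complement
  toy <- Biostrings::DNAStringSet(c(c1 = "AACCGGTTACGTAGCTAGGT"))
  gm <- gene_records("gm", "c1", 10L, 15L, "-")
  res <- extract_promoter(gm, toy, upstream = 3, downstream = 2)
  win <- substr("AACCGGTTACGTAGCTAGGT", 14, 18)
  expect_equal(res$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(win))))

  # window spilling over the chromosome start is truncated and flagged
  g2 <- gene_records("g2", "chr1", 100L, 300L, "+")
  res <- extract_promoter(g2, genome)
  expect_true(res$truncated)
  expect_equal(nchar(res$sequence), 100 + 100 - 1)

  expect_error(extract_promoter(gene_records("g3", "chrZ", 50L, 60L, "+"),
                                genome), "chrZ")
})

test_that("motif counting: exact matches, overlap semantics, offsets", {
  expect_equal(count_motif("CCGATAAGCC", "GATAAG")$copy_count, 1)
  expect_equal(count_motif("CCCCCCCCCC", "GATAAG")$copy_count, 0)
  expect_equal(count_motif("AAAA", "AAA", allow_overlap = TRUE)$copy_count, 2)
  expect_equal(count_motif("AAAA", "AAA", allow_overlap = FALSE)$copy_count, 1)
  expect_error(count_motif("ACGT", "GATNN"), "A,C,G,T|ACGT")
  expect_error(count_motif("ACG", "ACGT"), "longer")
  # offset arithmetic: match at string position 1 of a 600 bp window
  # is 500 bp upstream of the TSS
  seq <- paste0("GATAAG", strrep("C", 594))
  expect_equal(count_motif(seq, "GATAAG")$offsets, -500L)
  # a match opening at the TSS itself has offset 0
  seq2 <- paste0(strrep("C", 500), "GATAAG", strrep("C", 94))
  expect_equal(count_motif(seq2, "GATAAG")$offsets, 0L)
})

test_that("copy-number distributions report exact fractions", {
  expect_equal(copy_number_distribution(rep(1L, 20))$percent[["1"]], 100.0)
  dist <- copy_number_distribution(c(0, 0, 1, 1, 1, 2, 2, 3, 4, 5))
  expect_equal(sum(dist$fraction), 1)
  expect_equal(dist$percent[["3+"]], 30.0)
  expect_error(copy_number_distribution(integer(0)), "profiles")
})

test_that("extracting generated promoters recovers the planted plan", {
  n <- 30
  ids <- sprintf("g%d", seq_len(n))
  is_deg <- seq_len(n) <= 10
  pos <- simulate_positions(ids, is_deg, c(chrA = 1e5, chrB = 1e5), 0.5,
                            seed = 20)
  plan <- setNames(rep(c(0L, 1L, 2L), 10), ids)
  pro <- simulate_promoters(ids, "GATAAG", plan, seed = 21)
  genome <- build_promoter_genome(pos$loci, pro$promoters,
                                  c(chrA = 1e5, chrB = 1e5), seed = 22)
  ext <- extract_promoters(pos$loci, genome)
  expect_false(any(ext$truncated))
  # extraction returns the planted promoter byte-for-byte
  expect_identical(as.character(ext$sequences[ids]),
                   setNames(as.character(pro$promoters[ids]), ids))
  counts <- count_motifs(ext$sequences, "GATAAG")
  expect_identical(setNames(counts$copy_count, counts$gene_id)[ids],
                   setNames(plan, ids))
})
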