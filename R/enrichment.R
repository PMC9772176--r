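#' Hypergeometric term overrepresentation
#'
#' One-sided upper-tail hypergeometric test per term: the probability of
#' drawing at least the observed overlap between the query and the term
#' when `|query|` genes are drawn from the background without
#' replacement. Terms are intersected with the background; terms smaller
#' than `min_term_size` are skipped. q-values are BH-adjusted across the
#' tested terms.
#'
#' @param query Character vector of gene ids, a subset of `background`.
#' @param background Character vector of gene ids (the gene universe,
#'   e.g. all expressed genes).
#' @param term_map Named list mapping term id to a character vector of
#'   member gene ids, or a two-column data frame `(term_id, gene_id)`.
#' @param min_term_size Minimum in-background term size (default 3).
#' @return Data frame with `term_id`, `term_size`, `overlap`,
#'   `expected`, `p_value`, `q_value`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(query, background, term_map,
                                      min_term_size = 3) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    stop("query gene(s) not in background: ",
         paste(head(stray, 5), collapse = ", "))
  if (is.data.frame(term_map))
    term_map <- split(as.character(term_map[[2]]), term_map[[1]])
  term_map <- lapply(term_map, function(g) intersect(unique(g), background))
  sizes <- lengths(term_map)
  term_map <- term_map[sizes >= min_term_size]
  if (length(term_map) == 0)
    stop("no term of size >= ", min_term_size, " within the background")
  N <- length(background)
  k <- length(query)
  rows <- lapply(names(term_map), function(tid) {
    term <- term_map[[tid]]
    K <- length(term)
    ov <- length(intersect(term, query))
    p <- phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(term_id = tid, term_size = K, overlap = ov,
               expected = k * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Extract a TSS-anchored promoter window
#'
#' The promoter covers `upstream` bases before and `downstream` bases
#' from the TSS (600 bp by default), in transcription orientation. For a
#' `+` strand gene this is the forward-strand window
#' `[TSS - upstream, TSS + downstream - 1]`; for a `-` strand gene the
#' reverse complement of `[TSS - downstream + 1, TSS + upstream]` (TSS =
#' the `end` coordinate). Windows running off a chromosome edge are
#' truncated and flagged.
#'
#' @param gene One row of a `gene_records` data frame (or a one-row
#'   data frame with `gene_id`, `chrom`, `strand`, `tss`).
#' @param genome A named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @param upstream,downstream Window extents in bp (defaults 500 / 100).
#' @return List with `gene_id`, `sequence` (character), `truncated`
#'   (logical).
#' @export
extract_promoter <- function(gene, genome, upstream = 500, downstream = 100) {
  gene <- as.data.frame(gene)
  if (nrow(gene) != 1) stop("extract_promoter takes a single gene record")
  if (!gene$chrom %in% names(genome))
    stop("chromosome '", gene$chrom, "' absent from genome")
  chr <- genome[[gene$chrom]]
  len <- length(chr)
  tss <- gene$tss
  if (gene$strand == "+") {
    from <- tss - upstream
    to <- tss + downstream - 1
  } else {
    from <- tss - downstream + 1
    to <- tss + upstream
  }
  truncated <- from < 1 || to > len
  from <- max(from, 1); to <- min(to, len)
  if (from > to) stop("promoter window falls entirely off chromosome '",
                      gene$chrom, "'")
  seq <- Biostrings::subseq(chr, start = from, end = to)
  if (gene$strand == "-") seq <- Biostrings::reverseComplement(seq)
  list(gene_id = gene$gene_id, sequence = as.character(seq),
       truncated = truncated)
}

#' Extract promoters for a set of genes
#'
#' Vectorized [extract_promoter()].
#'
#' @inheritParams extract_promoter
#' @param loci A `gene_records` data frame.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truncated` (named logical vector).
#' @export
extract_promoters <- function(loci, genome, upstream = 500, downstream = 100) {
  res <- lapply(seq_len(nrow(loci)), function(i)
    extract_promoter(loci[i, , drop = FALSE], genome,
                     upstream = upstream, downstream = downstream))
  seqs <- Biostrings::DNAStringSet(vapply(res, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(res, `[[`, character(1), "gene_id")
  list(sequences = seqs,
       truncated = setNames(vapply(res, `[[`, logical(1), "truncated"),
                            names(seqs)))
}

#' Count exact motif copies in a promoter sequence
#'
#' Exact matches of the motif on the given (sense) sequence.
#' Overlapping occurrences are counted when `allow_overlap = TRUE`
#' (default); otherwise a greedy left-to-right non-overlapping scan is
#' used. Offsets are reported relative to the TSS, i.e. position 1 of a
#' standard promoter window maps to `-upstream` and the TSS itself is
#' offset 0.
#'
#' @param sequence A character string or [Biostrings::DNAString] over
#'   `{A,C,G,T}`.
#' @param motif Non-empty motif over `{A,C,G,T}` (IUPAC ambiguity codes
#'   are rejected), no longer than the sequence.
#' @param allow_overlap Count overlapping matches (default `TRUE`).
#' @param upstream Upstream extent of the window, used only to express
#'   offsets relative to the TSS (default 500).
#' @return List with `copy_count` and `offsets` (integer vector,
#'   TSS-relative).
#' @export
count_motif <- function(sequence, motif, allow_overlap = TRUE,
                        upstream = 500) {
  motif <- toupper(as.character(motif))
  sequence <- toupper(as.character(sequence))
  if (nchar(motif) == 0 || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over {A,C,G,T}")
  if (nchar(motif) > nchar(sequence))
    stop("motif longer than the sequence")
  if (allow_overlap) {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
    starts <- Biostrings::start(m)
  } else {
    hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
    starts <- if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  list(copy_count = length(starts),
       offsets = as.integer(starts) - as.integer(upstream) - 1L)
}

#' Motif copy counts across a promoter set
#'
#' @param promoters Named character vector or
#'   [Biostrings::DNAStringSet] of promoter sequences.
#' @inheritParams count_motif
#' @return Data frame with `gene_id`, `copy_count`; TSS-relative offsets
#'   are attached as the `offsets` attribute (named list).
#' @export
count_motifs <- function(promoters, motif, allow_overlap = TRUE,
                         upstream = 500) {
  seqs <- as.character(promoters)
  if (is.null(names(seqs))) stop("promoters must be named by gene id")
  prof <- lapply(seqs, count_motif, motif = motif,
                 allow_overlap = allow_overlap, upstream = upstream)
  out <- data.frame(gene_id = names(seqs),
                    copy_count = vapply(prof, `[[`, integer(1), "copy_count"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "offsets") <- lapply(prof, `[[`, "offsets")
  out
}

#' Copy-number distribution of a motif over genes
#'
#' Fractions of genes carrying 0, 1, 2, or 3+ motif copies, as one-decimal
#' percentages (rounded half away from zero) plus exact fractions.
#'
#' @param copy_counts Integer vector of per-gene copy counts (or a data
#'   frame from [count_motifs()]).
#' @return List with `percent` (named numeric over `0`,`1`,`2`,`3+`) and
#'   `fraction` (exact, sums to 1) and `n`.
#' @export
copy_number_distribution <- function(copy_counts) {
  if (is.data.frame(copy_counts)) copy_counts <- copy_counts$copy_count
  if (length(copy_counts) == 0) stop("no motif profiles given")
  cls <- ifelse(copy_counts >= 3, "3+", as.character(copy_counts))
  levels <- c("0", "1", "2", "3+")
  frac <- as.numeric(table(factor(cls, levels = levels))) / length(cls)
  names(frac) <- levels
  list(percent = round_half_away(100 * frac, 1), fraction = frac,
       n = length(copy_counts))
}
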