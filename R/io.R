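#' Read an expression table and its design
#'
#' The expression file is a TSV with gene ids in the first column and one
#' column per sample; the design file is a TSV with columns `sample`,
#' `condition` and optionally `replicate`. Lines starting with `#` are
#' ignored. Negative values, duplicate gene ids and samples missing from
#' the design are rejected with the offending location named.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @param unit `"counts"` or `"rpkm"`.
#' @param gene_lengths Optional named vector of gene lengths (see
#'   [ExpressionMatrix()]).
#' @return An [ExpressionMatrix()].
#' @export
read_expression <- function(path, design_path, unit = c("counts", "rpkm"),
                            gene_lengths = NULL) {
  unit <- match.arg(unit)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       comment.char = "#", stringsAsFactors = FALSE)
  ExpressionMatrix(vals, design, unit = unit, gene_lengths = gene_lengths)
}

#' Write an expression matrix and design to TSV
#'
#' @param x An [ExpressionMatrix()].
#' @param path Expression TSV path.
#' @param design_path Design TSV path.
#' @return Invisibly, `c(path, design_path)`.
#' @export
write_expression <- function(x, path, design_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results(df, path)
  write_results(x$design, design_path)
  invisible(c(path, design_path))
}

#' Construct a validated set of gene records
#'
#' Coordinates are 1-based inclusive (the GFF3 convention). The TSS is
#' the `start` for `+` strand genes and the `end` for `-` strand genes.
#'
#' @param gene_id Character, unique ids.
#' @param chrom Character chromosome names.
#' @param start,end Integer 1-based inclusive coordinates, `end >= start >= 1`.
#' @param strand `"+"` or `"-"`.
#' @param length_bp Effective length for RPKM; defaults to the genomic span.
#' @return A data frame of class `gene_records` with one row per gene and
#'   a computed `tss` column.
#' @export
gene_records <- function(gene_id, chrom, start, end, strand,
                         length_bp = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1)) stop("start coordinates must be >= 1")
  if (any(end < start)) stop("end < start for gene(s): ",
                             paste(gene_id[end < start], collapse = ", "))
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("invalid strand (must be '+' or '-') for gene(s): ",
         paste(gene_id[!strand %in% c("+", "-")], collapse = ", "))
  if (is.null(length_bp)) length_bp <- end - start + 1L
  length_bp <- as.integer(length_bp)
  if (any(length_bp <= 0)) stop("gene lengths must be positive")
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    length_bp = length_bp,
                    tss = ifelse(strand == "+", start, end),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_records", "data.frame")
  out
}

#' Read gene loci from BED6 or GFF3
#'
#' BED input (0-based half-open) is converted to the internal 1-based
#' inclusive convention; GFF3 is taken as-is. Records without a `+`/`-`
#' strand are rejected.
#'
#' @param path File path.
#' @param format `"bed"` or `"gff3"`.
#' @return A `gene_records` data frame (see [gene_records()]).
#' @export
read_gene_loci <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- if (format == "bed") mc$name else {
    if (!is.null(mc$ID)) as.character(mc$ID) else as.character(mc$Name)
  }
  if (is.null(ids) || any(is.na(ids)))
    stop("every record needs a gene id (BED name / GFF3 ID attribute)")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("record(s) without a '+'/'-' strand: ",
         paste(ids[strand == "*"], collapse = ", "))
  gene_records(ids, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr), strand)
}

#' Write gene loci to BED6 or GFF3
#'
#' The inverse of [read_gene_loci()]; round-trips are exact on valid
#' records.
#'
#' @param loci A `gene_records` data frame.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_gene_loci <- function(loci, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand)
  if (format == "bed") {
    S4Vectors::mcols(gr)$name <- loci$gene_id
    S4Vectors::mcols(gr)$score <- 0
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- loci$gene_id
    S4Vectors::mcols(gr)$source <- "coopdeg"
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read a qPCR CT table
#'
#' Expects a TSV with columns `target_gene`, `condition`, `replicate`,
#' `ct_target`, `ct_reference`; all CT values must be finite.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_qpcr <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("target_gene", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tab$ct_target)) || any(!is.finite(tab$ct_reference)))
    stop("non-finite CT value(s) in qPCR table")
  tab
}

#' Write a result table as TSV with a provenance header
#'
#' All tabular outputs are tab-delimited UTF-8 with `.` as the decimal
#' mark and a `#` comment header carrying the tool version (no
#' timestamps, so identical inputs give byte-identical files). Values
#' survive a read/write round-trip at full double precision.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param params Optional named list echoed into the header.
#' @return Invisibly, `path`.
#' @export
write_results <- function(df, path, params = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# coopdeg %s", as.character(packageVersion("coopdeg"))), con)
  if (!is.null(params))
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","),
                              character(1))), con)
  out <- df
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
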