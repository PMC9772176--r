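#' Configuration for the synthetic dataset generator
#'
#' Defines the statistical structure of a simulated two-condition,
#' replicated RNA-seq study with companion contrasts: negative-binomial
#' counts with a fraction of genes carrying planted signed effects
#' (including a small extreme-effect tail reaching `|log2FC|` ~ 10,
#' which reproduces the pattern that the most extreme fold changes come
#' from lowly expressed genes), a companion contrast whose log2 fold
#' changes correlate positively with the planted effects, a
#' developmental contrast anti-correlated with them among DEGs, optional
#' tandem genomic clustering of DEG loci, annotation terms enriched
#' among up-DEGs, and promoters with planted motif copies.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (>= 2, default 3).
#' @param baseline_mean Expected counts for a typical gene (median of
#'   the log-normal baseline distribution).
#' @param baseline_sdlog sdlog of the per-gene log-normal baseline.
#' @param nb_dispersion Negative-binomial dispersion (1/size); variance
#'   is `mu + dispersion * mu^2`. Must be positive.
#' @param frac_deg Fraction of genes with planted effects, in `[0, 1]`.
#' @param log2fc Mixture describing planted effect sizes: a list with
#'   `min_abs`/`max_abs` (uniform magnitude of ordinary effects),
#'   `frac_extreme` plus `extreme_min_abs`/`extreme_max_abs` (the
#'   extreme tail), and `prob_up` (probability an effect is positive;
#'   default 0.8, emulating a predominantly upregulated DEG set).
#' @param companion_r Target Pearson correlation of the companion
#'   contrast's log2FCs with the planted effects, in `[-1, 1]`.
#' @param dev_r Target correlation (typically negative) of the
#'   developmental contrast's log2FCs with the planted effects,
#'   restricted to the DEGs.
#' @param cluster_fraction Fraction of planted DEG loci placed in
#'   tandem genomic runs, in `[0, 1]`.
#' @param run_length Length-2 integer range of tandem run sizes
#'   (default 3 to 8 adjacent genes).
#' @param gene_length Gene length in bp (default 1000, so counts and
#'   RPKM are proportional).
#' @param motif Short DNA motif planted in promoters (default
#'   `"GATAAG"`).
#' @param motif_plan Promoter motif plan: `frac_with_motif_up` = the
#'   fraction of up-DEG promoters carrying the motif, and `copy_probs` =
#'   probabilities of 1, 2 and 3 copies among carriers (default
#'   0.65/0.20/0.15).
#' @param chrom_sizes Named integer vector of chromosome sizes; `NULL`
#'   (default) sizes four chromosomes generously for `n_genes`.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 3, baseline_mean = 50,
                       baseline_sdlog = 1.2, nb_dispersion = 0.05,
                       frac_deg = 0.1,
                       log2fc = list(min_abs = 1.5, max_abs = 6,
                                     frac_extreme = 0.05,
                                     extreme_min_abs = 6,
                                     extreme_max_abs = 10,
                                     prob_up = 0.8),
                       companion_r = 0.65, dev_r = -0.7,
                       cluster_fraction = 0.5, run_length = c(3L, 8L),
                       gene_length = 1000L, motif = "GATAAG",
                       motif_plan = list(frac_with_motif_up = 0.666,
                                         copy_probs = c(0.65, 0.20, 0.15)),
                       chrom_sizes = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 2)
  if (!is.finite(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be positive")
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be positive")
  for (f in c(frac_deg, cluster_fraction, log2fc$frac_extreme,
              log2fc$prob_up, motif_plan$frac_with_motif_up))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (abs(companion_r) > 1 || abs(dev_r) > 1)
    stop("target correlations must lie in [-1, 1]")
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (is.null(chrom_sizes)) {
    per <- ceiling(n_genes / 4)
    chrom_sizes <- setNames(rep(as.integer(ceiling(per * 2100 * 1.5 + 2000)), 4),
                            c("chr2L", "chr2R", "chr3L", "chr3R"))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog,
                 nb_dispersion = nb_dispersion, frac_deg = frac_deg,
                 log2fc = log2fc, companion_r = companion_r, dev_r = dev_r,
                 cluster_fraction = cluster_fraction,
                 run_length = as.integer(run_length),
                 gene_length = as.integer(gene_length), motif = motif,
                 motif_plan = motif_plan, chrom_sizes = chrom_sizes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a replicated two-condition count matrix with planted effects
#'
#' Negative-binomial counts for `control` and `mutant` conditions. A
#' gene with planted effect `e` has mutant mean `baseline * 2^e`;
#' baselines are log-normal across genes. The planted truth (effect,
#' DEG flag, direction) is returned alongside.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [ExpressionMatrix()] of counts) and
#'   `truth` (data frame: `gene_id`, `is_deg`, `log2fc_planted`,
#'   `direction`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  base_mu <- rlnorm(n, meanlog = log(config$baseline_mean),
                    sdlog = config$baseline_sdlog)
  lfc <- numeric(n)
  n_deg <- round(config$frac_deg * n)
  if (n_deg > 0) {
    deg_idx <- sample.int(n, n_deg)
    lf <- config$log2fc
    sgn <- ifelse(runif(n_deg) < lf$prob_up, 1, -1)
    extreme <- runif(n_deg) < lf$frac_extreme
    mag <- ifelse(extreme,
                  runif(n_deg, lf$extreme_min_abs, lf$extreme_max_abs),
                  runif(n_deg, lf$min_abs, lf$max_abs))
    lfc[deg_idx] <- sgn * mag
  }
  mu_a <- base_mu
  mu_b <- base_mu * 2^lfc
  k <- config$n_replicates
  size <- 1 / config$nb_dispersion
  counts_a <- matrix(rnbinom(n * k, mu = rep(mu_a, k), size = size),
                     nrow = n, ncol = k)
  counts_b <- matrix(rnbinom(n * k, mu = rep(mu_b, k), size = size),
                     nrow = n, ncol = k)
  values <- cbind(counts_a, counts_b)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  colnames(values) <- c(sprintf("control_%d", seq_len(k)),
                        sprintf("mutant_%d", seq_len(k)))
  # libraries sequenced to a fixed nominal depth: with 1e6 mapped reads
  # and 1 kb genes, RPKM is numerically equal to the raw count, and the
  # simulated gene panel (a sample of a transcriptome) cannot distort
  # the depth the way per-panel column sums would
  design <- data.frame(sample = colnames(values),
                       condition = rep(c("control", "mutant"), each = k),
                       replicate = rep(seq_len(k), 2),
                       total_mapped = 1e6,
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, is_deg = lfc != 0,
                      log2fc_planted = lfc,
                      direction = ifelse(lfc > 0, "up",
                                         ifelse(lfc < 0, "down", "none")),
                      stringsAsFactors = FALSE)
  list(matrix = ExpressionMatrix(values, design, unit = "counts",
                                 gene_lengths = setNames(
                                   rep(config$gene_length, n), ids)),
       truth = truth)
}

#' Generate a companion log2FC vector with a target correlation
#'
#' Shared-signal-plus-independent-noise construction: the input is
#' standardized, mixed with independent Gaussian noise as
#' `y = r * x_std + sqrt(1 - r^2) * noise`, and rescaled to the input's
#' spread, so the expected Pearson correlation with the input is
#' exactly `target_r`. At `|target_r| = 1` the output is an exact
#' (sign-flipped) scaled copy of the input.
#'
#' @param base_log2fc Numeric vector, length >= 3, non-zero variance.
#' @param target_r Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Numeric vector, same length.
#' @export
simulate_companion_log2fc <- function(base_log2fc, target_r, seed = 1L) {
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  x <- as.numeric(base_log2fc)
  if (length(x) < 3) stop("need a vector of length >= 3")
  s <- sd(x)
  if (s == 0) stop("base vector has zero variance")
  xs <- (x - mean(x)) / s
  if (abs(target_r) == 1) return(target_r * x)
  set.seed(seed)
  noise <- rnorm(length(x))
  (target_r * xs + sqrt(1 - target_r^2) * noise) * s
}

#' Place genes on chromosomes with optional tandem DEG clustering
#'
#' Generates non-overlapping, ordered gene loci (fixed gene length,
#' minimum inter-gene spacing, and a margin at each chromosome end so
#' that promoter windows never truncate), then assigns gene labels to
#' the slots: the stated fraction of DEG genes is laid down in adjacent
#' runs of `run_length[1]` to `run_length[2]` genes, the remaining DEGs
#' and all other genes are scattered uniformly.
#'
#' @param gene_ids Character vector of gene ids.
#' @param is_deg Logical vector parallel to `gene_ids`.
#' @param chrom_sizes Named positive integer vector of chromosome sizes.
#' @param cluster_fraction Fraction of DEGs placed in tandem runs.
#' @param run_length Integer range of run sizes (default `c(3, 8)`).
#' @param gene_length Gene length in bp (default 1000).
#' @param spacing Minimum gap between consecutive genes (default 1100).
#' @param margin Unused margin at each chromosome end (default 600).
#' @param seed Integer seed.
#' @return List with `loci` (a `gene_records` data frame, ordered by
#'   position) and `truth` (data frame: `gene_id`, `cluster_id` — run
#'   membership id or `NA`).
#' @export
simulate_positions <- function(gene_ids, is_deg, chrom_sizes,
                               cluster_fraction, run_length = c(3L, 8L),
                               gene_length = 1000L, spacing = 1100L,
                               margin = 600L, seed = 1L) {
  n <- length(gene_ids)
  stopifnot(length(is_deg) == n, all(chrom_sizes > 0))
  if (cluster_fraction < 0 || cluster_fraction > 1)
    stop("cluster_fraction must lie in [0, 1]")
  set.seed(seed)
  slot <- gene_length + spacing
  # genes per chromosome, proportional to size (largest remainder)
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  share <- n * chrom_sizes / sum(chrom_sizes)
  n_per <- floor(share)
  rem <- n - sum(n_per)
  if (rem > 0) {
    ord <- order(share - n_per, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1
  }
  usable <- chrom_sizes - 2 * margin
  if (any(n_per * slot - spacing > usable))
    stop("genes cannot fit in the genome: enlarge chrom_sizes or reduce n")
  starts <- integer(0); chroms <- character(0)
  for (ci in seq_along(chrom_sizes)) {
    nc <- n_per[ci]
    if (nc == 0) next
    extra <- usable[ci] - (nc * slot - spacing)
    offs <- sort(floor(runif(nc, 0, extra + 1)))
    starts <- c(starts, margin + 1L + as.integer(offs) +
                  (seq_len(nc) - 1L) * slot)
    chroms <- c(chroms, rep(names(chrom_sizes)[ci], nc))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # assign gene labels to the position slots
  deg_ids <- sample(gene_ids[is_deg])
  other_ids <- sample(gene_ids[!is_deg])
  n_deg <- length(deg_ids)
  n_clustered <- round(cluster_fraction * n_deg)
  assigned <- rep(NA_character_, n)
  cluster_id <- rep(NA_integer_, n)
  free <- rep(TRUE, n)
  run_id <- 0L
  placed <- 0L
  run_lens <- seq(run_length[1], run_length[2])
  while (placed < n_clustered) {
    L <- run_lens[sample.int(length(run_lens), 1)]
    L <- min(L, n_clustered - placed)
    if (L < 2) L <- min(2L, n_clustered - placed)
    cand <- which(vapply(seq_len(n - L + 1), function(i) {
      all(free[i:(i + L - 1)]) && chroms[i] == chroms[i + L - 1]
    }, logical(1)))
    if (length(cand) == 0) {
      if (L == 2) stop("cannot place DEG runs: genome too crowded")
      next  # retry with a fresh (possibly shorter) run length
    }
    i <- cand[sample.int(length(cand), 1)]
    run_id <- run_id + 1L
    idx <- i:(i + L - 1)
    assigned[idx] <- deg_ids[(placed + 1):(placed + L)]
    cluster_id[idx] <- run_id
    free[idx] <- FALSE
    placed <- placed + L
  }
  scatter <- deg_ids[seq_len(n_deg) > n_clustered]
  free_idx <- which(free)
  if (length(scatter) > 0) {
    pick <- free_idx[sample.int(length(free_idx), length(scatter))]
    assigned[pick] <- scatter
    free[pick] <- FALSE
  }
  assigned[which(free)] <- other_ids
  loci <- gene_records(assigned, chroms, starts,
                       starts + gene_length - 1L, strand,
                       length_bp = gene_length)
  list(loci = loci,
       truth = data.frame(gene_id = assigned, cluster_id = cluster_id,
                          stringsAsFactors = FALSE)[
                            match(gene_ids, assigned), , drop = FALSE] |>
         (\(d) { rownames(d) <- NULL; d })())
}

# random DNA of length n as a single string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random DNA guaranteed to contain no copy of any banned motif
random_dna_free <- function(n, banned, max_iter = 200L) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  for (iter in seq_len(max_iter)) {
    s <- paste(chars, collapse = "")
    hit <- FALSE
    for (b in banned) {
      m <- gregexpr(b, s, fixed = TRUE)[[1]]
      if (m[1] != -1) {
        hit <- TRUE
        for (st in as.integer(m))
          chars[st:(st + nchar(b) - 1)] <-
            sample(c("A", "C", "G", "T"), nchar(b), replace = TRUE)
      }
    }
    if (!hit) return(s)
  }
  stop("could not generate motif-free background")
}

#' Generate promoter sequences with a planted motif copy plan
#'
#' Each promoter is `upstream + downstream` bases (600 by default).
#' Backgrounds are rejection-sampled to contain no chance copy of the
#' motif; the planned number of copies is then inserted at random
#' non-overlapping offsets, and the result is re-scanned to confirm the
#' exact planted count (insertions that create junction artifacts are
#' redrawn).
#'
#' @param gene_ids Character vector of gene ids.
#' @param motif DNA motif over `{A,C,G,T}`, shorter than the window.
#' @param copy_plan Named integer vector (gene id -> copies >= 0);
#'   unnamed genes default to 0.
#' @param upstream,downstream Window extents (defaults 500 / 100).
#' @param seed Integer seed.
#' @return List with `promoters` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame: `gene_id`, `planted_copies`).
#' @export
simulate_promoters <- function(gene_ids, motif, copy_plan = NULL,
                               upstream = 500, downstream = 100, seed = 1L) {
  width <- upstream + downstream
  motif <- toupper(motif)
  if (nchar(motif) == 0 || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over {A,C,G,T}")
  if (nchar(motif) > width) stop("motif longer than the promoter window")
  plan <- setNames(rep(0L, length(gene_ids)), gene_ids)
  if (!is.null(copy_plan)) {
    if (any(copy_plan < 0)) stop("copy counts must be >= 0")
    plan[names(copy_plan)] <- as.integer(copy_plan)
  }
  L <- nchar(motif)
  if (any(plan * L > width)) stop("copy plan does not fit in the window")
  set.seed(seed)
  seqs <- vapply(gene_ids, function(g) {
    k <- plan[[g]]
    for (attempt in 1:100) {
      s <- random_dna_free(width, motif)
      if (k > 0) {
        # non-overlapping insertion offsets
        for (try2 in 1:200) {
          off <- sort(sample.int(width - L + 1, k))
          if (k == 1 || all(diff(off) >= L)) break
          off <- NULL
        }
        if (is.null(off)) next
        ch <- strsplit(s, "")[[1]]
        for (o in off) ch[o:(o + L - 1)] <- strsplit(motif, "")[[1]]
        s <- paste(ch, collapse = "")
      }
      if (count_motif(s, motif, upstream = upstream)$copy_count == k)
        return(s)
    }
    stop("failed to plant ", k, " copies for gene ", g)
  }, character(1))
  promoters <- Biostrings::DNAStringSet(seqs)
  names(promoters) <- gene_ids
  list(promoters = promoters,
       truth = data.frame(gene_id = gene_ids, planted_copies = unname(plan),
                          stringsAsFactors = FALSE))
}

#' Assemble a synthetic genome embedding the planted promoters
#'
#' Builds random chromosome sequences of the given sizes and stamps each
#' gene's promoter into exactly the window that [extract_promoter()]
#' reads (reverse-complemented for `-` strand genes), so extraction
#' round-trips to the planted promoter byte-for-byte. Requires loci laid
#' out with non-colliding promoter windows (as [simulate_positions()]
#' guarantees).
#'
#' @param loci A `gene_records` data frame.
#' @param promoters Named [Biostrings::DNAStringSet] from
#'   [simulate_promoters()].
#' @param chrom_sizes Named integer vector of chromosome sizes.
#' @param upstream,downstream Window extents (defaults 500 / 100).
#' @param seed Integer seed for the background sequence.
#' @return A named [Biostrings::DNAStringSet] of chromosomes.
#' @export
build_promoter_genome <- function(loci, promoters, chrom_sizes,
                                  upstream = 500, downstream = 100,
                                  seed = 1L) {
  set.seed(seed)
  chroms <- lapply(names(chrom_sizes), function(cn)
    strsplit(random_dna(chrom_sizes[[cn]]), "")[[1]])
  names(chroms) <- names(chrom_sizes)
  for (i in seq_len(nrow(loci))) {
    g <- loci[i, ]
    pro <- as.character(promoters[[g$gene_id]])
    if (g$strand == "+") {
      from <- g$tss - upstream; to <- g$tss + downstream - 1
      ins <- pro
    } else {
      from <- g$tss - downstream + 1; to <- g$tss + upstream
      ins <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pro)))
    }
    if (from < 1 || to > length(chroms[[g$chrom]]))
      stop("promoter window of gene ", g$gene_id, " exceeds its chromosome")
    chroms[[g$chrom]][from:to] <- strsplit(ins, "")[[1]]
  }
  out <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1),
                                         collapse = ""))
  names(out) <- names(chrom_sizes)
  out
}

#' Simulate an annotation term map with planted enrichment
#'
#' Builds `n_terms` gene-set terms over the given universe. Enriched
#' terms draw their members preferentially (with the stated odds ratio)
#' from the favored set; the rest sample uniformly.
#'
#' @param gene_ids Gene universe.
#' @param favored Gene ids to overrepresent in enriched terms (e.g. the
#'   up-DEGs).
#' @param n_terms Number of terms (default 20).
#' @param n_enriched Number of planted enriched terms (default 2).
#' @param term_size Integer range of term sizes (default `c(10, 40)`).
#' @param weight Sampling odds multiplier for favored genes in enriched
#'   terms (default 15).
#' @param seed Integer seed.
#' @return List with `term_map` (named list term -> gene ids) and
#'   `truth` (data frame: `term_id`, `enriched`).
#' @export
simulate_term_map <- function(gene_ids, favored, n_terms = 20,
                              n_enriched = 2, term_size = c(10, 40),
                              weight = 15, seed = 1L) {
  set.seed(seed)
  probs_enr <- ifelse(gene_ids %in% favored, weight, 1)
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  enriched <- seq_len(n_terms) <= n_enriched
  term_sizes <- seq(term_size[1], term_size[2])
  term_map <- lapply(seq_len(n_terms), function(i) {
    sz <- term_sizes[sample.int(length(term_sizes), 1)]
    if (enriched[i])
      sample(gene_ids, sz, prob = probs_enr)
    else
      sample(gene_ids, sz)
  })
  names(term_map) <- term_ids
  list(term_map = term_map,
       truth = data.frame(term_id = term_ids, enriched = enriched,
                          stringsAsFactors = FALSE))
}

#' Simulate a qPCR CT table consistent with given fold changes
#'
#' For each panel gene, target CT values are drawn so that the
#' delta-delta-Ct fold change reproduces the given log2 fold change up
#' to per-well Gaussian CT noise; the reference gene CT is constant
#' across conditions up to the same noise.
#'
#' @param log2fc Named numeric vector of true log2 fold changes
#'   (condition b vs a) for the panel genes.
#' @param conditions Length-2 character vector `(a, b)` (default
#'   control/mutant).
#' @param n_replicates Replicates per condition (default 3).
#' @param ct_noise_sd Per-well CT noise sd in cycles (default 0.1).
#' @param seed Integer seed.
#' @return A qPCR table as in [read_qpcr()].
#' @export
simulate_qpcr <- function(log2fc, conditions = c("control", "mutant"),
                          n_replicates = 3, ct_noise_sd = 0.1, seed = 1L) {
  stopifnot(!is.null(names(log2fc)))
  set.seed(seed)
  rows <- lapply(names(log2fc), function(g) {
    base_ct <- runif(1, 18, 28)
    do.call(rbind, lapply(seq_along(conditions), function(ci) {
      shift <- if (ci == 2) -log2fc[[g]] else 0
      data.frame(target_gene = g, condition = conditions[ci],
                 replicate = seq_len(n_replicates),
                 ct_target = base_ct + shift +
                   rnorm(n_replicates, 0, ct_noise_sd),
                 ct_reference = 16 + rnorm(n_replicates, 0, ct_noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# fixed per-stage seed derivation from the global seed (stays < 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage)
}

#' Simulate a complete study dataset with recorded ground truth
#'
#' Runs every generator under seeds derived from the config's global
#' seed: counts with planted effects, a companion contrast table (log2
#' fold changes correlated with the planted effects at `companion_r`;
#' DEG status thresholded at `|log2FC| >= 1` as for an external result
#' table), a developmental contrast table (anti-correlated among DEGs at
#' `dev_r`, mild noise elsewhere), clustered gene loci, promoters with a
#' motif copy plan concentrated on up-DEGs, an annotation term map with
#' planted enrichment, and a 7-gene qPCR panel. With `outdir` set, all
#' standard files (expression + design TSV, BED6 + GFF3 loci, promoter
#' FASTA, companion/developmental/term/qPCR/truth TSVs) are written.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param genome Also assemble the synthetic genome embedding the
#'   promoters (default `FALSE`; costly for large genomes).
#' @return List with `matrix`, `truth`, `companion`, `development`,
#'   `loci`, `position_truth`, `promoters`, `promoter_truth`,
#'   `term_map`, `term_truth`, `qpcr`, `qpcr_panel`, optionally
#'   `genome`, and `files` when written.
#' @export
simulate_dataset <- function(config, outdir = NULL, genome = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cnt <- simulate_counts(config)
  truth <- cnt$truth
  n <- config$n_genes
  ids <- truth$gene_id

  # companion contrast: correlated log2FCs, threshold DEG status
  comp_lfc <- simulate_companion_log2fc(truth$log2fc_planted,
                                        config$companion_r,
                                        seed = stage_seed(config$seed, 2L))
  companion <- data.frame(
    gene_id = ids, log2_fc = comp_lfc,
    signed_fc = ifelse(comp_lfc >= 0, 2^comp_lfc, -2^(-comp_lfc)),
    status = ifelse(comp_lfc >= 1, "up",
                    ifelse(comp_lfc <= -1, "down", "ns")),
    stringsAsFactors = FALSE)

  # developmental contrast: anti-correlated among DEGs, noise elsewhere
  dev_lfc <- numeric(n)
  deg <- truth$is_deg
  if (sum(deg) >= 3)
    dev_lfc[deg] <- simulate_companion_log2fc(truth$log2fc_planted[deg],
                                              config$dev_r,
                                              seed = stage_seed(config$seed, 3L))
  set.seed(stage_seed(config$seed, 4L))
  dev_lfc[!deg] <- rnorm(sum(!deg), 0, 0.8)
  dev_signed <- ifelse(dev_lfc >= 0, 2^dev_lfc, -2^(-dev_lfc))
  development <- data.frame(
    gene_id = ids, log2_fc = dev_lfc, signed_fc = dev_signed,
    status = c(dev_ns = "ns", dev_up = "up",
               dev_down = "down")[call_developmental_degs(dev_signed)],
    stringsAsFactors = FALSE)

  pos <- simulate_positions(ids, deg, config$chrom_sizes,
                            config$cluster_fraction, config$run_length,
                            gene_length = config$gene_length,
                            seed = stage_seed(config$seed, 5L))

  # motif copy plan concentrated on up-DEGs
  set.seed(stage_seed(config$seed, 6L))
  up_ids <- ids[truth$direction == "up"]
  carriers <- up_ids[runif(length(up_ids)) <
                       config$motif_plan$frac_with_motif_up]
  copies <- if (length(carriers) > 0)
    sample(seq_along(config$motif_plan$copy_probs), length(carriers),
           replace = TRUE, prob = config$motif_plan$copy_probs)
  else integer(0)
  copy_plan <- setNames(as.integer(copies), carriers)
  pro <- simulate_promoters(ids, config$motif, copy_plan,
                            seed = stage_seed(config$seed, 7L))

  tm <- simulate_term_map(ids, up_ids, seed = stage_seed(config$seed, 8L))

  # qPCR panel: 7 genes spanning the fold-change range (incl. non-DEGs)
  set.seed(stage_seed(config$seed, 9L))
  ord <- order(truth$log2fc_planted)
  panel_idx <- unique(round(seq(1, n, length.out = 7)))
  panel <- ids[ord][panel_idx]
  qpcr <- simulate_qpcr(setNames(truth$log2fc_planted[match(panel, ids)],
                                 panel),
                        n_replicates = config$n_replicates,
                        seed = stage_seed(config$seed, 10L))

  out <- list(matrix = cnt$matrix, truth = truth, companion = companion,
              development = development, loci = pos$loci,
              position_truth = pos$truth, promoters = pro$promoters,
              promoter_truth = pro$truth, term_map = tm$term_map,
              term_truth = tm$truth, qpcr = qpcr, qpcr_panel = panel,
              config = config)
  if (genome)
    out$genome <- build_promoter_genome(pos$loci, pro$promoters,
                                        config$chrom_sizes,
                                        seed = stage_seed(config$seed, 11L))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    write_expression(cnt$matrix, fp("expression.tsv"), fp("design.tsv"))
    write_gene_loci(pos$loci, fp("genes.bed"), "bed")
    write_gene_loci(pos$loci, fp("genes.gff3"), "gff3")
    Biostrings::writeXStringSet(pro$promoters, fp("promoters.fa"))
    write_results(truth, fp("truth.tsv"))
    write_results(companion, fp("companion_contrast.tsv"))
    write_results(development, fp("developmental_contrast.tsv"))
    write_results(data.frame(
      term_id = rep(names(tm$term_map), lengths(tm$term_map)),
      gene_id = unlist(tm$term_map, use.names = FALSE),
      stringsAsFactors = FALSE), fp("terms.tsv"))
    write_results(qpcr, fp("qpcr.tsv"))
    out$files <- list.files(outdir, full.names = TRUE)
  }
  out
}
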