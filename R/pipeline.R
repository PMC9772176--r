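#' Run the full analysis pipeline from a config
#'
#' Executes the stages in order — simulate (optional), differential
#' expression, cluster classification, concordance against the
#' companion and developmental contrasts, genomic proximity, term
#' enrichment, promoter motif counting, qPCR validation — writing each
#' stage's tables under `outdir` and a JSON manifest with an MD5
#' checksum per file. Re-running with the same config and seed
#' reproduces identical checksums. Any stage failure halts with the
#' stage name and cause.
#'
#' The config is a YAML file (or an equivalent list) with blocks:
#'
#' * `seed`: global seed, fanned out to per-stage seeds;
#' * `simulate`: arguments for [sim_config()] — or, instead, `inputs`
#'   with paths `expression`, `design`, `loci`, `loci_format`,
#'   `promoters`, `terms`, `companion`, `development`, `qpcr`
#'   (companion/development tables need `gene_id`, `log2_fc`, `status`);
#' * `thresholds`: `fc_min`, `q_max`, `rpkm_min`, `dev_fc_min`;
#' * `conditions`: `a` (control) and `b` (mutant) labels;
#' * `proximity`: `n_permutations`, `statistic`;
#' * `enrichment`: `min_term_size`;
#' * `motif`: the motif string to count in promoters.
#'
#' @param config Path to a YAML config or a config list.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly: a list with `stages` (files and
#'   checksums per stage) and `params`. Also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  thr <- modifyList(list(fc_min = 2, q_max = 0.05, rpkm_min = 1,
                         dev_fc_min = 2), config$thresholds %||% list())
  cond <- modifyList(list(a = "control", b = "mutant"),
                     config$conditions %||% list())
  prox <- modifyList(list(n_permutations = 1000,
                          statistic = "median_nn_distance"),
                     config$proximity %||% list())
  enr <- modifyList(list(min_term_size = 3), config$enrichment %||% list())
  manifest <- list(params = list(seed = seed, thresholds = thr,
                                 conditions = cond, proximity = prox,
                                 enrichment = enr),
                   stages = list())
  fp <- function(f) file.path(outdir, f)
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  need_input <- function(inputs, what) {
    path <- inputs[[what]]
    if (is.null(path) || !file.exists(path %||% ""))
      stop(sprintf("missing input '%s'", what))
    path
  }

  # ---- inputs: simulate or load -------------------------------------
  if (!is.null(config$simulate)) {
    dat <- run_stage("simulate", {
      cfg <- do.call(sim_config, modifyList(config$simulate,
                                            list(seed = seed)))
      simulate_dataset(cfg, outdir = fp("inputs"))
    })
    record("simulate", dat$files)
    motif <- config$motif %||% dat$config$motif
  } else {
    inputs <- config$inputs %||% list()
    dat <- run_stage("load_inputs", {
      x <- read_expression(need_input(inputs, "expression"),
                           need_input(inputs, "design"),
                           unit = inputs$unit %||% "counts")
      loci <- read_gene_loci(need_input(inputs, "loci"),
                             format = inputs$loci_format %||% "gff3")
      promoters <- if (!is.null(inputs$promoters))
        Biostrings::readDNAStringSet(need_input(inputs, "promoters"))
      read_table <- function(what) {
        if (is.null(inputs[[what]])) return(NULL)
        read_results(need_input(inputs, what))
      }
      list(matrix = x, loci = loci, promoters = promoters,
           companion = read_table("companion"),
           development = read_table("development"),
           term_map = read_table("terms"),
           qpcr = if (!is.null(inputs$qpcr))
             read_qpcr(need_input(inputs, "qpcr")))
    })
    motif <- config$motif
  }

  # ---- differential expression --------------------------------------
  de <- run_stage("de", {
    res <- call_degs(dat$matrix, cond$a, cond$b, fc_min = thr$fc_min,
                     q_max = thr$q_max, rpkm_min = thr$rpkm_min)
    write_results(res, fp("contrast_result.tsv"),
                  params = thr[c("fc_min", "q_max", "rpkm_min")])
    res
  })
  record("de", fp("contrast_result.tsv"))

  # ---- cluster classification ---------------------------------------
  clu <- run_stage("cluster", {
    asg <- assign_clusters(de)
    write_results(asg, fp("cluster_assignments.tsv"))
    cc <- cluster_counts(asg)
    write_results(data.frame(cluster = names(cc$sizes),
                             n = unname(cc$sizes)),
                  fp("cluster_sizes.tsv"))
    asg
  })
  record("cluster", c(fp("cluster_assignments.tsv"),
                      fp("cluster_sizes.tsv")))

  # ---- concordance with companion & developmental contrasts ---------
  concord_files <- character(0)
  run_stage("concordance", {
    for (pair in list(c("companion", "companion"),
                      c("development", "development"))) {
      other <- dat[[pair[1]]]
      if (is.null(other)) next
      for (sel in c("all", "degs_x", "degs_y", "common_degs")) {
        cs <- tryCatch(subset_compare(de, other, sel),
                       error = function(e) NULL)
        if (is.null(cs)) next
        f <- fp(sprintf("concordance_%s_%s.tsv", pair[2], sel))
        write_results(data.frame(
          selection = sel, n = cs$n, n_axis = cs$n_axis, r = cs$r,
          p_value = cs$p_value,
          t(cs$quadrant_counts), t(cs$concordance_pct),
          check.names = FALSE), f)
        concord_files <- c(concord_files, f)
      }
    }
  })
  record("concordance", concord_files)

  # ---- genomic proximity --------------------------------------------
  deg_ids <- de$gene_id[de$status %in% c("up", "down")]
  prox_res <- run_stage("proximity", {
    if (is.null(dat$loci)) stop("missing input 'loci'")
    pr <- proximity_permutation_test(dat$loci, deg_ids,
                                     n_permutations = prox$n_permutations,
                                     statistic = prox$statistic,
                                     seed = stage_seed(seed, 21L))
    write_results(data.frame(statistic = pr$statistic_name,
                             observed = pr$observed,
                             empirical_p = pr$empirical_p,
                             n_permutations = pr$n_permutations,
                             n_members = pr$n_members,
                             wilcox_p = pr$wilcox_p), fp("proximity.tsv"))
    write_results(data.frame(null_statistic = pr$null_distribution),
                  fp("proximity_null.tsv"))
    pr
  })
  record("proximity", c(fp("proximity.tsv"), fp("proximity_null.tsv")))

  # ---- term enrichment ----------------------------------------------
  run_stage("enrichment", {
    if (is.null(dat$term_map)) stop("missing input 'terms'")
    tm <- dat$term_map
    if (is.data.frame(tm)) tm <- split(tm$gene_id, tm$term_id)
    background <- de$gene_id[de$status != "filtered"]
    up <- intersect(de$gene_id[de$status == "up"], background)
    res <- hypergeometric_enrichment(up, background, tm,
                                     min_term_size = enr$min_term_size)
    write_results(res, fp("enrichment_up.tsv"))
  })
  record("enrichment", fp("enrichment_up.tsv"))

  # ---- promoter motif counting --------------------------------------
  if (!is.null(dat$promoters) && !is.null(motif)) {
    run_stage("motif", {
      prof <- count_motifs(dat$promoters, motif)
      up_prof <- prof[prof$gene_id %in%
                        de$gene_id[de$status == "up"], , drop = FALSE]
      dist <- copy_number_distribution(
        if (nrow(up_prof) > 0) up_prof else prof)
      write_results(prof, fp("motif_counts.tsv"))
      write_results(data.frame(copies = names(dist$percent),
                               percent = unname(dist$percent),
                               fraction = unname(dist$fraction)),
                    fp("motif_distribution.tsv"))
    })
    record("motif", c(fp("motif_counts.tsv"), fp("motif_distribution.tsv")))
  }

  # ---- qPCR validation ----------------------------------------------
  if (!is.null(dat$qpcr)) {
    run_stage("qpcr", {
      targets <- unique(dat$qpcr$target_gene)
      fcs <- lapply(targets, function(g)
        qpcr_fold_change(dat$qpcr, g, cond$b, cond$a))
      tab <- do.call(rbind, lapply(fcs, as.data.frame))
      val <- validate_qpcr(setNames(tab$log2_fc, tab$target_gene),
                           setNames(de$log2_fc, de$gene_id))
      write_results(tab, fp("qpcr_fold_changes.tsv"))
      write_results(data.frame(r = val$r, p_value = val$p_value,
                               n = val$n), fp("qpcr_validation.tsv"))
    })
    record("qpcr", c(fp("qpcr_fold_changes.tsv"),
                     fp("qpcr_validation.tsv")))
  }

  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
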