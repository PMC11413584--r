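#' Build a pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Either `simulate` (a list of [sim_params()] arguments, optionally with a
#' `transcriptome` sub-list of [simulate_transcriptome()] arguments) or
#' `input` (paths: `vcf`, `samples`, `env`, and optionally `fasta`, `orfs`)
#' must be given. The root `seed` is mandatory; every stochastic stage
#' derives its own child seed from it deterministically.
#'
#' @param simulate,input See description.
#' @param filter List: `type` ("gbs" or "rna") plus threshold overrides.
#' @param association List: `methods` (subset of "rda", "lfmm", "fstscan"),
#'   `n_perm`, `K` (`NULL` = choose by cross-validation), `k_max`, `alpha`,
#'   `sd_cutoff`, `fdr`.
#' @param consensus List: `min_methods`.
#' @param effects List: `min_codons`.
#' @param enrichment List: `ordinations` (subset of "pca", "dapc"), `axes`,
#'   `start`, `stop`, `n_pca` (`NULL` = a-score grid search).
#' @param diversity List: `n_perm`.
#' @param seed Integer root seed.
#' @param out_dir Optional directory for the JSON report and TSV twins.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            filter = list(), association = list(),
                            consensus = list(), effects = list(),
                            enrichment = list(), diversity = list(),
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && is.null(input)) {
    rlang::abort("pipeline_config needs either 'simulate' or 'input'")
  }
  if (!is.null(input)) {
    need <- setdiff(c("vcf", "samples", "env"), names(input))
    if (length(need)) {
      rlang::abort(paste("input paths missing:", paste(need, collapse = ", ")))
    }
    for (p in unlist(input)) {
      if (!file.exists(p)) rlang::abort(paste("input path does not exist:", p))
    }
  }
  defaults <- list(
    filter = list(type = "gbs", maf_min = 0.01, miss_max = 0.20,
                  min_qual = 30, min_dp4 = 10, mac = 4, max_missing = 0.98,
                  maf = 0.01),
    association = list(methods = c("rda", "lfmm", "fstscan"), n_perm = 499,
                       K = NULL, k_max = 8, alpha = 0.01, sd_cutoff = 3,
                       axis_alpha = 0.01, fdr = 0.05),
    consensus = list(min_methods = 2),
    effects = list(min_codons = 100),
    enrichment = list(ordinations = c("pca", "dapc"), axes = 2, start = 10,
                      stop = 200, n_pca = NULL, n_pca_grid = 2:8),
    diversity = list(n_perm = 1000)
  )
  cfg <- list(
    simulate = simulate, input = input,
    filter = utils::modifyList(defaults$filter, filter),
    association = utils::modifyList(defaults$association,
                                    association, keep.null = TRUE),
    consensus = utils::modifyList(defaults$consensus, consensus),
    effects = utils::modifyList(defaults$effects, effects),
    enrichment = utils::modifyList(defaults$enrichment,
                                   enrichment, keep.null = TRUE),
    diversity = utils::modifyList(defaults$diversity, diversity),
    seed = as.integer(seed), out_dir = out_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# deterministic child seeds per stage from the root seed (kept < 2^31)
child_seed <- function(seed, stage) {
  (seed * 1000L + stage) %% .Machine$integer.max
}

#' Run the full seascape-genomics pipeline
#'
#' Executes filter, diversity, the association channels, consensus, effect
#' annotation with the kN/kS comparison, and the ordination + iterative
#' Wilcoxon enrichment, on either a simulated dataset or user files.
#' Every stage's counts, thresholds and child seeds land in the report so
#' the run is auditable end to end; rerunning with the same config and seed
#' reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with sections `data`, `filter`,
#'   `diversity`, `association`, `consensus`, `effects`, `enrichment`,
#'   `seeds`. Written as JSON (plus TSV twins of the main tables) to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(seeds = list(root = seed))

  ## -- data ---------------------------------------------------------------
  stage <- "load"
  res <- with_stage(stage, {
    if (!is.null(config$simulate)) assemble_simulated(config) else
      assemble_input(config)
  })
  gm <- res$gm; samples <- res$samples; env <- res$env
  transcripts <- res$transcripts; orfs <- res$orfs
  report$data <- list(
    source = if (!is.null(config$simulate)) "simulated" else "files",
    n_samples = n_samples(gm), n_loci = n_loci(gm),
    n_localities = length(unique(samples$locality)),
    n_transcripts = length(transcripts %||% character())
  )

  ## -- filter -------------------------------------------------------------
  filt <- with_stage("filter", {
    if (config$filter$type == "rna") {
      filter_rna_variants(gm, min_qual = config$filter$min_qual,
                          min_dp4 = config$filter$min_dp4,
                          mac = config$filter$mac,
                          max_missing = config$filter$max_missing,
                          maf = config$filter$maf)
    } else {
      filter_maf_missing(gm, maf_min = config$filter$maf_min,
                         miss_max = config$filter$miss_max)
    }
  })
  gm <- filt$gm
  report$filter <- list(
    type = config$filter$type,
    n_input = attr(filt$report, "n_input"),
    n_output = attr(filt$report, "n_output"),
    removed_by_rule = stats::setNames(as.list(filt$report$n_removed),
                                      filt$report$rule)
  )

  ## -- diversity ----------------------------------------------------------
  pops <- samples$locality[match(sample_ids(gm), samples$sample_id)]
  regions <- samples$region[match(sample_ids(gm), samples$sample_id)]
  div <- with_stage("diversity", {
    div_tbl <- diversity_report(gm, pops, n_perm = config$diversity$n_perm,
                                seed = child_seed(seed, 2L))
    am <- amova(gm, pops, regions, n_perm = config$diversity$n_perm,
                seed = child_seed(seed, 3L))
    fst <- wc_theta(gm, pops, n_perm = config$diversity$n_perm,
                    seed = child_seed(seed, 4L))
    hh <- compare_ho_he(gm, pops)
    list(table = div_tbl, amova = am, fst = fst, ho_he = hh)
  })
  report$diversity <- list(
    per_pop = div$table,
    global_theta = div$fst$theta, global_theta_p = div$fst$p_value,
    amova = div$amova$components, amova_phi = div$amova$phi,
    ho_he = div$ho_he
  )

  ## -- association --------------------------------------------------------
  assoc_cfg <- config$association
  flagged <- list()
  assoc_out <- list()
  env_pruned <- with_stage("prune", prune_collinear(env))
  assoc_out$predictors_retained <- setdiff(names(env_pruned), "locality")
  if ("rda" %in% assoc_cfg$methods) {
    rda <- with_stage("rda", {
      rda_scan(gm, pops, env_pruned, n_perm = assoc_cfg$n_perm,
               sd_cutoff = assoc_cfg$sd_cutoff,
               axis_alpha = assoc_cfg$axis_alpha,
               seed = child_seed(seed, 5L))
    })
    flagged$rda <- rda$flagged
    assoc_out$rda <- glance(rda)
  }
  if ("lfmm" %in% assoc_cfg$methods) {
    lfmm <- with_stage("lfmm", {
      K <- assoc_cfg$K %||%
        as.integer(choose_k(gm, k_max = min(assoc_cfg$k_max,
                                            min(dim(gm$genotypes)) - 1L),
                            seed = child_seed(seed, 6L)))
      lfmm_scan(gm, pops, env_pruned, K = K, alpha = assoc_cfg$alpha,
                seed = child_seed(seed, 7L))
    })
    flagged$lfmm <- lfmm$flagged
    assoc_out$lfmm <- glance(lfmm)
  }
  if ("fstscan" %in% assoc_cfg$methods) {
    fsc <- with_stage("fstscan", {
      fst_outlier_scan(gm, pops, n_perm = assoc_cfg$n_perm,
                       fdr = assoc_cfg$fdr, seed = child_seed(seed, 8L))
    })
    flagged$fstscan <- fsc$flagged
    assoc_out$fstscan <- list(n_flagged = length(fsc$flagged))
  }
  report$association <- assoc_out

  ## -- consensus ----------------------------------------------------------
  part <- with_stage("consensus", {
    consensus(flagged, locus_ids(gm),
              min_methods = config$consensus$min_methods)
  })
  report$consensus <- list(
    n_total = n_loci(gm),
    n_union = length(part$union),          # under selection by >= 1 method
    n_consensus = length(part$consensus),  # putative adaptive
    n_neutral = length(part$neutral),
    venn = part$venn
  )

  ## -- effects ------------------------------------------------------------
  if (!is.null(transcripts)) {
    eff <- with_stage("effects", {
      if (is.null(orfs)) {
        orfs <- predict_orfs(transcripts,
                             min_codons = config$effects$min_codons)
      }
      single <- filter_single_orf(transcripts, orfs)
      lt <- gm$loci
      snp_tbl <- lt[!is.na(lt$transcript_id) &
                      lt$transcript_id %in% names(single$transcripts),
                    c("locus_id", "transcript_id", "pos", "ref", "alt")]
      classified <- classify_snps(snp_tbl, single$transcripts, single$orfs)
      adaptive_ids <- intersect(classified$locus_id, part$union)
      neutral_ids <- intersect(classified$locus_id, part$neutral)
      counts_adaptive <- count_effects(
        classified[classified$locus_id %in% adaptive_ids, ])
      counts_neutral <- count_effects(
        classified[classified$locus_id %in% neutral_ids, ])
      chi <- tryCatch(compare_knks(counts_adaptive, counts_neutral),
                      error = function(e) {
                        rlang::inform(paste("kN/kS chi-square skipped:",
                                            conditionMessage(e)))
                        NULL
                      })
      list(classified = classified, adaptive = counts_adaptive,
           neutral = counts_neutral, chi = chi,
           n_multi_orf = single$n_multi_orf, n_zero_orf = single$n_zero_orf)
    })
    report$effects <- list(
      n_classified = nrow(eff$classified),
      n_multi_orf_dropped = eff$n_multi_orf,
      adaptive_counts = eff$adaptive,
      neutral_counts = eff$neutral,
      chi_square = eff$chi
    )

    ## -- enrichment -------------------------------------------------------
    enr_cfg <- config$enrichment
    enr <- with_stage("enrichment", {
      cls_gm <- subset_geno(gm, loci = eff$classified$locus_id)
      freqs <- locality_freqs(cls_gm, pops)
      kn_ids <- eff$classified$locus_id[eff$classified$class == "nonsynonymous"]
      series <- list()
      ords <- list()
      stop_m <- min(enr_cfg$stop, n_loci(cls_gm))
      if ("pca" %in% enr_cfg$ordinations) {
        ords$pca <- pca_contributions(freqs)
        series$pca <- enrichment_by_axis(ords$pca, kn_ids,
                                         axes = seq_len(enr_cfg$axes),
                                         start = enr_cfg$start,
                                         stop = stop_m)
      }
      if ("dapc" %in% enr_cfg$ordinations) {
        n_pca <- enr_cfg$n_pca %||%
          as.integer(optimize_a_score(cls_gm, pops,
                                      n_pca_grid = enr_cfg$n_pca_grid,
                                      seed = child_seed(seed, 9L)))
        ords$dapc <- dapc_fit(cls_gm, pops, n_pca = n_pca)
        series$dapc <- enrichment_by_axis(ords$dapc, kn_ids,
                                          axes = seq_len(enr_cfg$axes),
                                          start = enr_cfg$start,
                                          stop = stop_m)
      }
      list(series = series, ords = ords, kn_ids = kn_ids, stop_m = stop_m)
    })
    report$enrichment <- list(
      n_kn = length(enr$kn_ids),
      stop_m = enr$stop_m,
      pca = enr$series$pca,
      dapc = enr$series$dapc,
      pca_var_pct = enr$ords$pca$var_pct[1:2],
      dapc_eigenvalues = enr$ords$dapc$discriminant_eigenvalues
    )
  }

  report$seeds$children <- stats::setNames(
    as.list(child_seed(seed, 2:9)),
    c("diversity", "amova", "fst", "rda", "choose_k", "lfmm", "fstscan",
      "a_score")
  )
  report <- structure(report, class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)))
  })
}

assemble_simulated <- function(config) {
  sim <- config$simulate
  seed <- config$seed
  trans_cfg <- sim$transcriptome
  sim$transcriptome <- NULL
  trans <- NULL
  if (!is.null(trans_cfg)) {
    trans_cfg$seed <- child_seed(seed, 1L)
    if (!is.null(trans_cfg$snp_plan)) {
      trans_cfg$snp_plan <- unlist(trans_cfg$snp_plan)
    }
    trans <- do.call(simulate_transcriptome, trans_cfg)
    sim$n_loci <- nrow(trans$snps)
  }
  sim$seed <- seed
  params <- do.call(sim_params, sim)
  env <- simulate_env(params$n_pops, seed = child_seed(seed, 0L))
  out <- simulate_genotypes(params, env)
  gm <- out$gm
  if (!is.null(trans)) {
    # transcript SNPs become the loci: metadata from the planted table
    lt <- trans$snps[, c("locus_id", "transcript_id", "pos", "ref", "alt")]
    lt$qual <- 40
    lt$dp4 <- 20
    gm <- geno_matrix(gm$genotypes, lt)
  }
  list(gm = gm, samples = out$samples, env = env,
       transcripts = trans$transcripts, orfs = NULL, truth = out$truth,
       planted = trans)
}

assemble_input <- function(config) {
  tabs <- read_tables(config$input$samples, config$input$env,
                      config$input$orfs)
  gm <- read_vcf(config$input$vcf)
  keep <- intersect(sample_ids(gm), tabs$samples$sample_id)
  if (!length(keep)) rlang::abort("no overlap between VCF samples and sample map")
  gm <- subset_geno(gm, samples = keep)
  transcripts <- if (!is.null(config$input$fasta)) {
    read_transcripts(config$input$fasta)
  } else NULL
  list(gm = gm, samples = tabs$samples, env = tabs$env,
       transcripts = transcripts, orfs = tabs$orfs, truth = NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  data: %d samples x %d loci (%s)\n", x$data$n_samples,
              x$data$n_loci, x$data$source))
  cat(sprintf("  filter: %d -> %d loci\n", x$filter$n_input,
              x$filter$n_output))
  cat(sprintf("  consensus: %d total / %d union / %d putative adaptive\n",
              x$consensus$n_total, x$consensus$n_union,
              x$consensus$n_consensus))
  if (!is.null(x$effects)) {
    cat(sprintf("  effects: kN=%d kS=%d oCDS=%d (ratio %s)\n",
                x$effects$adaptive_counts$kN, x$effects$adaptive_counts$kS,
                x$effects$adaptive_counts$oCDS,
                format(x$effects$adaptive_counts$ratio)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$diversity$per_pop)) {
    tsv(report$diversity$per_pop, "diversity.tsv")
  }
  if (!is.null(report$enrichment$pca)) tsv(report$enrichment$pca,
                                           "enrichment_pca.tsv")
  if (!is.null(report$enrichment$dapc)) tsv(report$enrichment$dapc,
                                            "enrichment_dapc.tsv")
  invisible(out_dir)
}
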