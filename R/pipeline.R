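#' Full-pipeline run configuration
#'
#' Bundles the simulation plan with the analysis settings of every stage;
#' the single `seed` is expanded deterministically into per-stage seeds so
#' stages stay independently reproducible.
#'
#' @param plan a [simulation_plan()].
#' @param clump a [clump_config()].
#' @param n_iter permutation iterations for the overlap tests.
#' @param proximity_window proximity window in bp.
#' @param gsea_weight,n_perm GSEA settings.
#' @param eqtl_coding genotype coding for the expression test.
#' @param seed global seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(plan = simulation_plan(), clump = clump_config(),
                       n_iter = 2000, proximity_window = 25000,
                       gsea_weight = 1, n_perm = 2000,
                       eqtl_coding = "additive", seed = 1L) {
  if (n_iter < 1) stop("config error: n_iter must be >= 1", call. = FALSE)
  if (n_perm < 1) stop("config error: n_perm must be >= 1", call. = FALSE)
  if (proximity_window < 0) {
    stop("config error: proximity_window must be >= 0", call. = FALSE)
  }
  validate_plan(plan)
  structure(list(plan = plan, clump = clump, n_iter = n_iter,
                 proximity_window = proximity_window,
                 gsea_weight = gsea_weight, n_perm = n_perm,
                 eqtl_coding = eqtl_coding, seed = as.integer(seed)),
            class = "run_config")
}

derive_seed <- function(seed, k) {
  as.integer(((seed %% 100000L) * 10007L + k * 101L) %% 2147483647L)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: simulate all inputs from the
#' plan (genome, peaks and replicate datasets, enhancers, genotype panel,
#' summary statistics, genes, interactions, counts), define supra- and
#' sub-threshold risk loci by clumping, build consensus peaks, run the
#' bidirectional permutation overlap tests (direct, proximal and
#' peak-shuffled converse), assign candidate genes to supra-threshold
#' loci, rank genes by differential expression, test the assigned gene set
#' by weighted GSEA, and test genotype-stratified expression at the first
#' planted locus with the negative-binomial LRT. Identical configuration
#' and seed give an identical report.
#'
#' @param config a [run_config()].
#' @return an object of class `analysis_report` (nested list of per-stage
#'   results plus a config echo).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  plan <- config$plan
  plan$seed <- derive_seed(config$seed, 1L)

  genome <- make_genome(plan)
  regions <- simulate_regions(plan, genome)
  panel <- simulate_panel(plan, genome, peaks = regions$peaks)
  stats <- simulate_gwas(plan, genome, panel, regions$peaks)
  consensus <- consensus_peaks(regions$peak_sets, min_datasets = 2L)

  supra <- clump(stats, panel, config$clump, tier = "supra")
  sub <- clump(stats, panel, config$clump, tier = "sub")

  tests <- list(
    supra_direct = locus_shuffle_test(
      supra, consensus, genome, window = 0, n_iter = config$n_iter,
      seed = derive_seed(config$seed, 11L)),
    supra_proximal = locus_shuffle_test(
      supra, consensus, genome, window = config$proximity_window,
      n_iter = config$n_iter, seed = derive_seed(config$seed, 12L)),
    supra_converse = peak_shuffle_test(
      supra, consensus, regions$enhancers, n_iter = config$n_iter,
      seed = derive_seed(config$seed, 13L)))
  if (nrow(sub) > 0) {
    tests$sub_direct <- locus_shuffle_test(
      sub, consensus, genome, window = 0, n_iter = config$n_iter,
      seed = derive_seed(config$seed, 14L))
  }

  genes <- simulate_genes(plan, genome, peaks = regions$peaks)
  interactions <- simulate_interactions(
    plan, viewpoints = as.data.frame(supra[, c("chrom", "start", "end")]),
    genes = genes)
  assigned <- sort(unique(unlist(lapply(seq_len(nrow(supra)), function(i)
    assign_genes(supra[i, ], genes, interactions,
                 near_window = config$proximity_window)))))

  # planted biology: genes assigned to risk loci carry the plan's condition
  # effects (pathway targets near loci respond to the condition)
  cond_effects <- rep(0, plan$n_genes)
  if (length(assigned) > 0) {
    idx <- match(assigned, sprintf("gene_%04d", seq_len(plan$n_genes)))
    idx <- idx[!is.na(idx)]
    cond_effects[idx] <- rep_len(plan$condition_log2fc_effects, length(idx))
  }
  condition <- rep(c(0, 1), each = plan$n_rna_per_group)
  sim_rna <- simulate_counts(plan, plan$n_genes, group_labels = condition,
                             condition_effects = cond_effects)
  ranked <- differential_rank_table(sim_rna$counts, condition)

  gsea <- if (length(intersect(assigned, ranked$gene)) > 0) {
    gsea_test(ranked, assigned, weight = config$gsea_weight,
              n_perm = config$n_perm, seed = derive_seed(config$seed, 21L))
  } else NULL

  # genotype-stratified expression at the first planted locus
  eqtl <- NULL
  if (nrow(supra) > 0) {
    maf <- mean(panel_column(panel, supra$index_snp[1])) / 2
    plan_geno <- plan
    plan_geno$seed <- derive_seed(config$seed, 31L)
    set.seed(derive_seed(config$seed, 32L))
    cohort_geno <- stats::rbinom(plan$n_cohort, 2, maf)
    # a broad gene panel keeps median-of-ratios factors insensitive to the
    # few genotype-responsive genes
    n_eqtl_genes <- max(length(plan$genotype_log2fc_effects) * 10L, 60L)
    sim_cohort <- simulate_counts(plan_geno, n_eqtl_genes,
                                genotypes = cohort_geno)
    offsets <- log(size_factors(sim_cohort$counts))
    rows <- lapply(seq_len(nrow(sim_cohort$counts)), function(g) {
      r <- lrt_genotype(sim_cohort$counts[g, ], cohort_geno,
                        offsets = offsets, coding = config$eqtl_coding)
      data.frame(gene = rownames(sim_cohort$counts)[g],
                 beta_genotype = r$full$beta[[2]] / log(2),
                 lrt_stat = r$lrt_stat, df = r$df, p_chi2 = r$p_chi2)
    })
    eqtl <- list(snp = supra$index_snp[1], maf = maf,
                 table = do.call(rbind, rows),
                 truth = sim_cohort$truth)
  }

  structure(list(
    version = as.character(utils::packageVersion("pathtune")),
    config = config,
    loci = list(supra = supra, sub = sub,
                n_supra = nrow(supra), n_sub = nrow(sub)),
    consensus_peaks = consensus,
    overlap_tests = tests,
    assigned_genes = assigned,
    ranked = ranked,
    gsea = gsea,
    eqtl = eqtl), class = "analysis_report")
}

#' Summarise an analysis report
#'
#' Prints a compact text summary (locus counts, observed versus expected
#' overlap with empirical p for each test direction, GSEA and eQTL
#' results) and returns the standard figures: a null-count histogram with
#' the observed value marked for each permutation test, and the GSEA
#' running-sum trace with set members as a rug.
#'
#' @param report an `analysis_report` from [run_full()].
#' @return invisibly, a named list of `ggplot` objects.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  cat("Risk loci: ", report$loci$n_supra, " supra-threshold, ",
      report$loci$n_sub, " sub-threshold; ",
      length(report$consensus_peaks), " consensus peaks\n", sep = "")
  for (nm in names(report$overlap_tests)) {
    t <- report$overlap_tests[[nm]]
    p_txt <- if (t$at_resolution_floor) {
      paste0("p < ", format(1 / t$n_iter, scientific = TRUE))
    } else paste0("p = ", format(t$p_empirical, digits = 3))
    cat(sprintf("  %-15s observed %d, expected %.2f, %s\n", nm,
                t$observed, t$null_mean, p_txt))
  }
  if (!is.null(report$gsea)) {
    g <- report$gsea
    cat(sprintf("  GSEA: %d assigned genes, ES = %.2f, NES = %.2f, p %s\n",
                g$n_set, g$es, g$nes,
                if (g$at_resolution_floor)
                  paste0("< ", format(1 / max(g$n_same_sign, 1),
                                      digits = 2))
                else paste0("= ", format(g$p_perm, digits = 3))))
  }
  if (!is.null(report$eqtl)) {
    sig <- sum(report$eqtl$table$p_chi2 < 0.05)
    cat(sprintf("  eQTL at %s: %d/%d genes with chi-square p < 0.05\n",
                report$eqtl$snp, sig, nrow(report$eqtl$table)))
  }
  figs <- list()
  for (nm in names(report$overlap_tests)) {
    figs[[nm]] <- plot_null_hist(report$overlap_tests[[nm]])
  }
  if (!is.null(report$gsea)) {
    figs$gsea <- plot_running_sum(report$gsea)
  }
  invisible(figs)
}

#' Plot the permutation null histogram
#'
#' Bars give the expected frequency distribution of the overlap count
#' over the shuffles; the vertical line marks the observed count.
#'
#' @param test an `overlap_test`.
#' @return a `ggplot` object.
#' @export
plot_null_hist <- function(test) {
  h <- test$null_hist
  ggplot2::ggplot(h, ggplot2::aes(x = .data$count, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = test$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "overlap count under shuffling", y = "frequency",
                  title = paste0(test$direction, "-shuffle null (observed = ",
                                 test$observed, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the GSEA running sum
#'
#' The running enrichment score over the ranked list; set members appear
#' as a rug along the rank axis.
#'
#' @param gsea a `gsea_result`.
#' @return a `ggplot` object.
#' @export
plot_running_sum <- function(gsea) {
  df <- data.frame(rank = seq_along(gsea$running_sum),
                   running = gsea$running_sum)
  hits <- data.frame(rank = which(gsea$inset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$rank),
                      inherit.aes = FALSE, sides = "b") +
    ggplot2::labs(x = "gene rank", y = "running enrichment score",
                  title = sprintf("ES = %.2f", gsea$es)) +
    ggplot2::theme_minimal()
}

#' Serialise an analysis report to JSON
#'
#' Writes the machine-readable parts of the report (counts, test results
#' with their iteration counts, GSEA and eQTL tables, config echo) as
#' JSON; every p-value travels with its `n_iter`/`n_perm`.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  tests <- lapply(report$overlap_tests, function(t)
    list(observed = t$observed, null_mean = t$null_mean,
         p_empirical = t$p_empirical,
         at_resolution_floor = t$at_resolution_floor,
         n_iter = t$n_iter, mode = t$mode, direction = t$direction,
         null_hist = t$null_hist))
  out <- list(
    version = report$version,
    seed = report$config$seed,
    n_supra_loci = report$loci$n_supra,
    n_sub_loci = report$loci$n_sub,
    n_consensus_peaks = length(report$consensus_peaks),
    overlap_tests = tests,
    assigned_genes = report$assigned_genes,
    gsea = if (!is.null(report$gsea)) list(
      es = report$gsea$es, nes = report$gsea$nes,
      p_perm = report$gsea$p_perm, n_perm = report$gsea$n_perm,
      n_set = report$gsea$n_set) else NULL,
    eqtl = if (!is.null(report$eqtl)) list(
      snp = report$eqtl$snp, table = report$eqtl$table) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
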