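#' Genome layout
#'
#' A minimal description of the coordinate space every other object lives in:
#' an ordered set of chromosome names and their lengths in base pairs. All
#' coordinates in the package are 0-based, half-open (BED convention); a SNP
#' at base pair `k` occupies the interval `[k, k + 1)`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   names are the chromosome identifiers.
#' @return an object of class `genome_layout`: the named length vector.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 1e6))
#' @export
genome_layout <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths)))) {
    stop("chromosome lengths must be named", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  structure(setNames(as.numeric(chrom_lengths), names(chrom_lengths)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Simulation plan
#'
#' Collects every knob of the synthetic-data generator: panel size and LD
#' structure, planted GWAS associations, interval-set geometry, and the
#' negative-binomial count model. Defaults encode the study conditions the
#' pipeline is exercised under: a 20 Mb two-chromosome toy genome, 6 causal
#' loci planted inside binding-site peaks and 6 outside, peaks covering well
#' under 1% of the genome, a 100-sample reference panel (about the size of
#' the 1000 Genomes CEU panel), strong within-block LD (r^2 = 0.9), and
#' moderately overdispersed counts.
#'
#' @param seed integer RNG seed used by the generator functions.
#' @param n_chroms,chrom_len genome geometry (chromosomes x length in bp).
#' @param n_samples reference-panel size (>= 2).
#' @param n_snps total SNPs across the panel.
#' @param snps_per_block SNPs per haplotype block.
#' @param ld_block_len haplotype-block footprint in bp.
#' @param within_block_r2 target pairwise dosage r^2 inside a block.
#' @param maf_range minor-allele-frequency range for block templates.
#' @param n_causal_in_peaks,n_causal_outside planted genome-wide-significant
#'   associations inside / outside peak intervals.
#' @param n_sub_in_peaks,n_sub_outside planted sub-threshold associations
#'   (`5e-8 < p < 1e-4`) inside / outside peaks.
#' @param min_causal_sep minimum separation (bp) between planted index SNPs,
#'   so that LD clumping sees them as independent.
#' @param peak_count,peak_len_range binding-site peaks: count and length
#'   range (bp).
#' @param enhancer_count,enhancer_len_range enhancer background regions.
#' @param frac_peaks_in_enhancers proportion of peaks placed inside
#'   enhancers (the converse shuffle is constrained to that background).
#' @param n_peak_datasets replicate ChIP-seq datasets emitted for consensus
#'   construction.
#' @param peak_jitter per-replicate jitter (bp) on peak edges.
#' @param peak_dropout per-replicate probability a true peak is missed.
#' @param peak_noise_rate per-replicate count of dataset-specific spurious
#'   peaks, as a fraction of `peak_count`.
#' @param n_genes,gene_len_range gene models: count and span length range.
#' @param nb_mean_range baseline negative-binomial mean range (log-uniform).
#' @param nb_dispersion negative-binomial dispersion alpha (> 0);
#'   `Var = mu + alpha * mu^2`.
#' @param condition_log2fc_effects planted condition log2 fold-changes,
#'   assigned to the first genes of a simulated count matrix.
#' @param genotype_log2fc_effects planted per-allele genotype log2
#'   fold-changes, likewise.
#' @param n_rna_per_group RNA-seq samples per condition group (the cell-line
#'   comparison the differential ranking emulates was run in triplicate).
#' @param n_cohort expression-cohort size for the genotype-stratified test.
#' @return an object of class `simulation_plan` (a validated list).
#' @export
simulation_plan <- function(seed = 1L,
                            n_chroms = 2L,
                            chrom_len = 10e6,
                            n_samples = 100L,
                            n_snps = 2000L,
                            snps_per_block = 8L,
                            ld_block_len = 20e3,
                            within_block_r2 = 0.9,
                            maf_range = c(0.1, 0.5),
                            n_causal_in_peaks = 6L,
                            n_causal_outside = 6L,
                            n_sub_in_peaks = 3L,
                            n_sub_outside = 3L,
                            min_causal_sep = 600e3,
                            peak_count = 60L,
                            peak_len_range = c(500, 2000),
                            enhancer_count = 150L,
                            enhancer_len_range = c(1000, 5000),
                            frac_peaks_in_enhancers = 0.8,
                            n_peak_datasets = 3L,
                            peak_jitter = 25,
                            peak_dropout = 0.1,
                            peak_noise_rate = 0.2,
                            n_genes = 300L,
                            gene_len_range = c(2000, 20000),
                            nb_mean_range = c(20, 2000),
                            nb_dispersion = 0.05,
                            condition_log2fc_effects = c(2, 2, -2, 2, 2),
                            genotype_log2fc_effects = c(1, 1, -1),
                            n_rna_per_group = 3L,
                            n_cohort = 450L) {
  plan <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_len = chrom_len, n_samples = as.integer(n_samples),
               n_snps = as.integer(n_snps),
               snps_per_block = as.integer(snps_per_block),
               ld_block_len = ld_block_len,
               within_block_r2 = within_block_r2, maf_range = maf_range,
               n_causal_in_peaks = as.integer(n_causal_in_peaks),
               n_causal_outside = as.integer(n_causal_outside),
               n_sub_in_peaks = as.integer(n_sub_in_peaks),
               n_sub_outside = as.integer(n_sub_outside),
               min_causal_sep = min_causal_sep,
               peak_count = as.integer(peak_count),
               peak_len_range = peak_len_range,
               enhancer_count = as.integer(enhancer_count),
               enhancer_len_range = enhancer_len_range,
               frac_peaks_in_enhancers = frac_peaks_in_enhancers,
               n_peak_datasets = as.integer(n_peak_datasets),
               peak_jitter = peak_jitter, peak_dropout = peak_dropout,
               peak_noise_rate = peak_noise_rate,
               n_genes = as.integer(n_genes),
               gene_len_range = gene_len_range,
               nb_mean_range = nb_mean_range,
               nb_dispersion = nb_dispersion,
               condition_log2fc_effects = condition_log2fc_effects,
               genotype_log2fc_effects = genotype_log2fc_effects,
               n_rna_per_group = as.integer(n_rna_per_group),
               n_cohort = as.integer(n_cohort))
  class(plan) <- "simulation_plan"
  validate_plan(plan)
  plan
}

validate_plan <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  counts <- c("n_chroms", "n_samples", "n_snps", "snps_per_block",
              "n_causal_in_peaks", "n_causal_outside", "n_sub_in_peaks",
              "n_sub_outside", "peak_count", "enhancer_count",
              "n_peak_datasets", "n_genes", "n_rna_per_group", "n_cohort")
  for (f in counts) {
    if (plan[[f]] < 0L) stop("plan field ", f, " must be >= 0", call. = FALSE)
  }
  props <- c("within_block_r2", "frac_peaks_in_enhancers", "peak_dropout")
  for (f in props) {
    if (plan[[f]] < 0 || plan[[f]] > 1) {
      stop("plan field ", f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (plan$nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0", call. = FALSE)
  }
  if (plan$chrom_len <= 0) stop("chrom_len must be positive", call. = FALSE)
  if (any(plan$maf_range <= 0) || any(plan$maf_range > 0.5)) {
    stop("maf_range must lie in (0, 0.5]", call. = FALSE)
  }
  invisible(plan)
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat("<simulation_plan>\n",
      "  genome: ", x$n_chroms, " x ", format(x$chrom_len, big.mark = ","),
      " bp\n",
      "  panel:  ", x$n_samples, " samples, ", x$n_snps, " SNPs (",
      x$snps_per_block, "/block, target r2 ", x$within_block_r2, ")\n",
      "  planted: ", x$n_causal_in_peaks, " causal in peaks, ",
      x$n_causal_outside, " outside; ",
      x$n_sub_in_peaks + x$n_sub_outside, " sub-threshold\n",
      "  peaks:  ", x$peak_count, " in ", x$n_peak_datasets, " datasets; ",
      x$enhancer_count, " enhancers\n", sep = "")
  invisible(x)
}

#' Construct the genome a plan calls for
#'
#' Deterministic for a given plan: chromosome names are `chr1..chrN` with
#' the common length `chrom_len`. Errors if the requested interval features
#' cannot possibly fit.
#'
#' @param plan a [simulation_plan()].
#' @return a [genome_layout()].
#' @export
make_genome <- function(plan) {
  validate_plan(plan)
  lens <- rep(plan$chrom_len, plan$n_chroms)
  names(lens) <- paste0("chr", seq_len(plan$n_chroms))
  total <- sum(lens)
  footprint <- plan$peak_count * max(plan$peak_len_range) +
    plan$enhancer_count * max(plan$enhancer_len_range)
  if (footprint > total) {
    stop("infeasible plan: requested feature footprint (", footprint,
         " bp) exceeds genome length (", total, " bp)", call. = FALSE)
  }
  genome_layout(lens)
}
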