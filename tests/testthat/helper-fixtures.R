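# Shared fixtures, built in code at test time.

# a small, fast plan for end-to-end exercises
small_plan <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2L, chrom_len = 5e6, n_samples = 60L,
         n_snps = 400L, snps_per_block = 5L, n_causal_in_peaks = 3L,
         n_causal_outside = 3L, n_sub_in_peaks = 1L, n_sub_outside = 1L,
         min_causal_sep = 600e3, peak_count = 30L, enhancer_count = 60L,
         n_genes = 80L),
    list(...))
  do.call(simulation_plan, args)
}

# GRanges from 0-based half-open triples
gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1,
                                                 end = end), ...)
}

# a hand-built risk_loci object: one row per locus, each with member SNPs
# at the given positions (list of numeric vectors)
make_loci <- function(chrom, member_pos, ids = NULL) {
  n <- length(member_pos)
  if (is.null(ids)) ids <- paste0("locus", seq_len(n))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  rows <- lapply(seq_len(n), function(i) {
    pos <- sort(member_pos[[i]])
    data.frame(locus_id = ids[i], chrom = chrom[i], start = min(pos),
               end = max(pos) + 1,
               index_snp = paste0(ids[i], "_index"), index_pos = pos[1],
               index_p = 1e-10, tier = "supra", n_members = length(pos),
               members = I(list(data.frame(
                 id = paste0(ids[i], "_m", seq_along(pos)), pos = pos,
                 stringsAsFactors = FALSE))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("risk_loci", "data.frame")
  out
}

# a panel from an explicit dosage matrix (one row per sample)
make_panel <- function(dosage, pos = NULL, chrom = "chr1") {
  ids <- colnames(dosage)
  if (is.null(ids)) {
    ids <- paste0("s", seq_len(ncol(dosage)))
    colnames(dosage) <- ids
  }
  if (is.null(pos)) pos <- seq(0, by = 100, length.out = ncol(dosage))
  if (length(chrom) == 1) chrom <- rep(chrom, ncol(dosage))
  genotype_panel(dosage, data.frame(id = ids, chrom = chrom, pos = pos,
                                    stringsAsFactors = FALSE))
}

# summary stats data.frame shortcut
make_stats <- function(chrom, pos, id, pvalue) {
  data.frame(chrom = chrom, pos = pos, id = id, pvalue = pvalue,
             stringsAsFactors = FALSE)
}
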