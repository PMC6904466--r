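#' Clumping configuration
#'
#' Thresholds for defining independent risk loci and their haplotype
#' blocks. `p_threshold` is the conventional genome-wide significance
#' cutoff; the sub-threshold tier considers SNPs with
#' `p_threshold < p < p_window_low`. During clumping every SNP within
#' `exclude_dist` bp of, or in LD at `r^2 >= exclude_r2` with, a selected
#' index SNP is excluded; blocks collect all SNPs at `r^2 >= block_r2` with
#' the index. The distance default is 500 kb: the source analysis prints
#' "500 Mb", which exceeds every human chromosome and would forbid the
#' multiple same-chromosome loci it reports, so it is treated as a typo for
#' 500 kb and left configurable.
#'
#' @param p_threshold genome-wide significance cutoff (default `5e-8`).
#' @param p_window_low lower bound of the sub-threshold window (default
#'   `1e-4`).
#' @param exclude_dist physical exclusion radius in bp (default `500e3`).
#' @param exclude_r2 LD exclusion threshold (default 0.2).
#' @param block_r2 block membership threshold (default 0.8, inclusive).
#' @return an object of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 5e-8, p_window_low = 1e-4,
                         exclude_dist = 500e3, exclude_r2 = 0.2,
                         block_r2 = 0.8) {
  if (!(p_threshold > 0 && p_threshold < p_window_low && p_window_low <= 1)) {
    stop("need 0 < p_threshold < p_window_low <= 1", call. = FALSE)
  }
  if (!(exclude_r2 >= 0 && exclude_r2 <= block_r2 && block_r2 <= 1)) {
    stop("need 0 <= exclude_r2 <= block_r2 <= 1", call. = FALSE)
  }
  if (exclude_dist < 0) stop("exclude_dist must be >= 0", call. = FALSE)
  structure(list(p_threshold = p_threshold, p_window_low = p_window_low,
                 exclude_dist = exclude_dist, exclude_r2 = exclude_r2,
                 block_r2 = block_r2),
            class = "clump_config")
}

#' Genotype reference panel
#'
#' A sample x SNP dosage matrix (entries 0/1/2 copies of the alternate
#' allele) with a coordinate map aligning SNP ids to summary-statistics
#' positions; the panel supplies every r^2 computation, standing in for a
#' population reference such as 1000 Genomes CEU.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; column
#'   names are SNP ids.
#' @param map data.frame with columns `id`, `chrom`, `pos` (0-based),
#'   one row per dosage column, same order.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  stopifnot(all(c("id", "chrom", "pos") %in% names(map)))
  if (!identical(colnames(dosage), as.character(map$id))) {
    stop("dosage columns and map rows must align on SNP id", call. = FALSE)
  }
  if (!all(dosage %in% 0:2)) {
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(dosage = dosage, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

panel_column <- function(panel, id) {
  j <- match(id, colnames(panel$dosage))
  if (is.na(j)) stop("SNP '", id, "' not found in panel", call. = FALSE)
  panel$dosage[, j]
}

#' Squared dosage correlation between two SNPs
#'
#' LD measured as the squared Pearson correlation of unphased dosage
#' vectors (composite LD, the usual convention for dosage panels).
#'
#' @param panel a [genotype_panel()].
#' @param snp_a,snp_b SNP ids.
#' @return r^2 in `[0, 1]`.
#' @examples
#' panel <- genotype_panel(
#'   matrix(c(0, 1, 1, 2, 0, 1, 2, 2), ncol = 2,
#'          dimnames = list(NULL, c("a", "b"))),
#'   data.frame(id = c("a", "b"), chrom = "chr1", pos = c(0, 10)))
#' compute_r2(panel, "a", "b")  # 8/11
#' @export
compute_r2 <- function(panel, snp_a, snp_b) {
  a <- panel_column(panel, snp_a)
  b <- panel_column(panel, snp_b)
  if (stats::sd(a) == 0) {
    stop("SNP '", snp_a, "' is monomorphic in the panel", call. = FALSE)
  }
  if (stats::sd(b) == 0) {
    stop("SNP '", snp_b, "' is monomorphic in the panel", call. = FALSE)
  }
  stats::cor(a, b)^2
}

# r^2 of one SNP against many, vectorised; monomorphic columns give NA
r2_against <- function(panel, id, ids) {
  x <- panel_column(panel, id)
  j <- match(ids, colnames(panel$dosage))
  if (anyNA(j)) stop("unknown SNP id in panel lookup", call. = FALSE)
  m <- panel$dosage[, j, drop = FALSE]
  keep <- apply(m, 2, stats::sd) > 0
  out <- rep(NA_real_, length(ids))
  if (stats::sd(x) > 0 && any(keep)) {
    out[keep] <- as.vector(stats::cor(x, m[, keep, drop = FALSE]))^2
  }
  setNames(out, ids)
}

new_risk_loci <- function(df) {
  class(df) <- c("risk_loci", "data.frame")
  df
}

empty_risk_loci <- function() {
  new_risk_loci(data.frame(locus_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           index_snp = character(0), index_pos = numeric(0),
                           index_p = numeric(0), tier = character(0),
                           n_members = integer(0),
                           members = I(list())))
}

#' @export
print.risk_loci <- function(x, ...) {
  cat("<risk_loci> ", nrow(x), " locus/loci\n", sep = "")
  if (nrow(x) > 0) {
    print(as.data.frame(x[, c("locus_id", "chrom", "start", "end",
                              "index_snp", "index_p", "tier", "n_members")]))
  }
  invisible(x)
}

#' Haplotype block around an index SNP
#'
#' The block is the index SNP together with every same-chromosome SNP in
#' high LD with it (`r^2 >= block_r2`, inclusive at the threshold); its
#' span is the half-open interval covering all member positions.
#'
#' @param index index SNP id (must be present in `stats` and `panel`).
#' @param stats summary statistics (see [read_summary_stats()]).
#' @param panel a [genotype_panel()].
#' @param cfg a [clump_config()].
#' @param tier significance tier label stored on the locus.
#' @return a one-row `risk_loci` object.
#' @export
define_block <- function(index, stats, panel, cfg = clump_config(),
                         tier = "supra") {
  row <- stats[stats$id == index, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("index SNP '", index, "' not found once in summary stats",
         call. = FALSE)
  }
  same_chrom <- stats[stats$chrom == row$chrom &
                        stats$id %in% colnames(panel$dosage), , drop = FALSE]
  r2 <- r2_against(panel, index, same_chrom$id)
  members <- same_chrom[!is.na(r2) & r2 >= cfg$block_r2, c("id", "pos")]
  if (!index %in% members$id) {
    members <- rbind(members, row[, c("id", "pos")])
  }
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  new_risk_loci(data.frame(
    locus_id = paste0(row$chrom, ":", row$pos),
    chrom = row$chrom,
    start = min(members$pos),
    end = max(members$pos) + 1,
    index_snp = index,
    index_pos = row$pos,
    index_p = row$pvalue,
    tier = tier,
    n_members = nrow(members),
    members = I(list(members)),
    stringsAsFactors = FALSE))
}

#' LD clumping: independent risk loci from summary statistics
#'
#' Iteratively selects the most significant remaining SNP as an index SNP
#' and excludes every candidate on the same chromosome within
#' `exclude_dist` bp of it or in LD with it at `r^2 >= exclude_r2`, until
#' no candidate remains. For `tier = "supra"` candidates are SNPs with
#' `p <= p_threshold`; for `tier = "sub"` candidates have
#' `p_threshold < p < p_window_low` and, to keep the tier independent of
#' genome-wide-significant signals, all SNPs within `exclude_dist` or at
#' `r^2 >= exclude_r2` of any supra-threshold index SNP are removed first.
#' Each returned locus carries its haplotype block via [define_block()].
#'
#' Ties in minimum p are broken by chromosome order then position. SNPs in
#' the summary statistics but absent from the panel cannot serve as index
#' SNPs (their LD is undefined) and are dropped with a warning.
#'
#' @param stats summary statistics data.frame (`chrom`, `pos`, `id`,
#'   `pvalue`).
#' @param panel a [genotype_panel()].
#' @param cfg a [clump_config()].
#' @param tier `"supra"` or `"sub"`.
#' @return a `risk_loci` data.frame, index SNPs in increasing p order.
#' @export
clump <- function(stats, panel, cfg = clump_config(),
                  tier = c("supra", "sub")) {
  tier <- match.arg(tier)
  stopifnot(nrow(stats) > 0)
  if (any(stats$pvalue <= 0 | stats$pvalue > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  in_panel <- stats$id %in% colnames(panel$dosage)
  if (tier == "supra") {
    cand <- stats[stats$pvalue <= cfg$p_threshold, , drop = FALSE]
  } else {
    cand <- stats[stats$pvalue > cfg$p_threshold &
                    stats$pvalue < cfg$p_window_low, , drop = FALSE]
  }
  if (!all(cand$id %in% colnames(panel$dosage))) {
    warning(sum(!cand$id %in% colnames(panel$dosage)),
            " candidate SNP(s) absent from the panel were dropped")
    cand <- cand[cand$id %in% colnames(panel$dosage), , drop = FALSE]
  }
  if (tier == "sub" && nrow(cand) > 0) {
    supra <- clump(stats, panel, cfg, tier = "supra")
    for (i in seq_len(nrow(supra))) {
      cand <- exclude_near(cand, panel, cfg,
                           chrom = supra$chrom[i],
                           pos = supra$index_pos[i],
                           id = supra$index_snp[i])
      if (nrow(cand) == 0) break
    }
  }
  if (nrow(cand) == 0) return(empty_risk_loci())
  chrom_levels <- unique(stats$chrom)
  loci <- list()
  while (nrow(cand) > 0) {
    o <- order(cand$pvalue, match(cand$chrom, chrom_levels), cand$pos)
    cand <- cand[o, , drop = FALSE]
    index <- cand[1, , drop = FALSE]
    loci[[length(loci) + 1]] <-
      define_block(index$id, stats, panel, cfg, tier = tier)
    cand <- exclude_near(cand, panel, cfg, chrom = index$chrom,
                         pos = index$pos, id = index$id)
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  new_risk_loci(out)
}

# drop candidates in physical or genetic proximity to an index SNP
exclude_near <- function(cand, panel, cfg, chrom, pos, id) {
  same <- cand$chrom == chrom
  drop <- same & abs(cand$pos - pos) < cfg$exclude_dist
  ld_check <- same & !drop
  if (any(ld_check)) {
    r2 <- r2_against(panel, id, cand$id[ld_check])
    drop[ld_check] <- !is.na(r2) & r2 >= cfg$exclude_r2
  }
  drop[cand$id == id] <- TRUE
  cand[!drop, , drop = FALSE]
}

#' Convert risk loci spans to GRanges
#'
#' @param loci a `risk_loci` object.
#' @return `GRanges` of the block spans, named by `locus_id`.
#' @export
loci_to_granges <- function(loci) {
  gr <- df_to_regions(data.frame(chrom = loci$chrom, start = loci$start,
                                 end = loci$end, name = loci$locus_id))
  gr
}

#' Read / write SNP-level summary statistics
#'
#' TSV with columns `chrom`, `pos` (0-based bp), `id`, `pvalue`.
#'
#' @param path file path.
#' @param stats summary-statistics data.frame.
#' @return the data.frame (reader) or `path` invisibly (writer).
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "pos", "id", "pvalue") %in% names(df)))
  if (any(df$pvalue <= 0 | df$pvalue > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[, c("chrom", "pos")])) {
    stop("duplicated (chrom, pos) in summary statistics", call. = FALSE)
  }
  df
}

#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats[, c("chrom", "pos", "id", "pvalue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dosage panel
#'
#' TSV with columns `id`, `chrom`, `pos` followed by one column per sample
#' holding 0/1/2 dosages (SNPs in rows).
#'
#' @param path file path.
#' @param panel a [genotype_panel()].
#' @return a `genotype_panel` (reader) or `path` invisibly (writer).
#' @export
read_dosage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"),
                          check.names = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(df)))
  samp <- setdiff(names(df), c("id", "chrom", "pos"))
  dosage <- t(as.matrix(df[, samp, drop = FALSE]))
  colnames(dosage) <- df$id
  rownames(dosage) <- samp
  genotype_panel(dosage, df[, c("id", "chrom", "pos")])
}

#' @rdname read_dosage
#' @export
write_dosage <- function(panel, path) {
  df <- cbind(panel$map[, c("id", "chrom", "pos")],
              as.data.frame(t(panel$dosage)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
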