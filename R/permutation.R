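#' @title Permutation null models for overlap enrichment
#' @description Two bootstrapping null models generate the expected
#'   frequency distribution of overlap counts: risk loci (haplotype blocks)
#'   shuffled uniformly around the genome, or peaks shuffled within an
#'   enhancer background. The empirical p-value is the fraction of
#'   iterations whose null count reaches the observed count.
#' @name permutation
NULL

#' Shuffle haplotype blocks around the genome
#'
#' Each block keeps its span length and internal SNP offsets; the
#' destination chromosome is chosen with probability proportional to the
#' number of valid start positions (`chrom length - block length + 1`) and
#' the start is uniform among them. Blocks are placed independently and
#' may overlap one another. Draws from the current RNG stream; seed
#' outside for reproducibility.
#'
#' @param loci a `risk_loci` object.
#' @param genome a [genome_layout()].
#' @param gap_mask optional `GRanges` of regions a shuffled block may not
#'   intersect (rejection-sampled; off by default).
#' @return a `risk_loci` object with relocated spans and members.
#' @export
shuffle_blocks <- function(loci, genome, gap_mask = NULL) {
  mask_idx <- if (!is.null(gap_mask)) interval_index(gap_mask) else NULL
  out <- loci
  lens <- loci$end - loci$start
  chroms <- names(genome)
  glen <- as.numeric(genome)
  for (i in seq_len(nrow(loci))) {
    slots <- glen - lens[i] + 1
    ok <- slots > 0
    if (!any(ok)) {
      stop("placement error: block of length ", lens[i],
           " fits on no chromosome", call. = FALSE)
    }
    for (try in seq_len(1000)) {
      ch <- if (sum(ok) == 1) chroms[ok] else
        sample(chroms[ok], 1, prob = slots[ok])
      start <- floor(stats::runif(1, 0, genome[[ch]] - lens[i] + 1))
      if (is.null(mask_idx) ||
          !span_in_index(mask_idx, ch, start, start + lens[i])) break
      if (try == 1000) {
        stop("placement error: gap mask leaves no room for a block",
             call. = FALSE)
      }
    }
    shift <- start - loci$start[i]
    out$chrom[i] <- ch
    out$start[i] <- start
    out$end[i] <- start + lens[i]
    out$index_pos[i] <- loci$index_pos[i] + shift
    mem <- loci$members[[i]]
    mem$pos <- mem$pos + shift
    out$members[[i]] <- mem
    out$locus_id[i] <- paste0(ch, ":", out$index_pos[i])
  }
  out
}

#' Shuffle peaks within a background region set
#'
#' Each peak keeps its length and is relocated to lie fully inside a
#' background region (e.g. active enhancers): the destination region is
#' chosen with probability proportional to `region length - peak length +
#' 1` among regions that can contain it, and the start is uniform within
#' the region. Draws from the current RNG stream.
#'
#' @param peaks,background `GRanges`.
#' @return `GRanges` of relocated peaks (metadata preserved).
#' @export
shuffle_peaks_within <- function(peaks, background) {
  pk <- regions_to_df(peaks)
  bg <- regions_to_df(background)
  lens <- pk$end - pk$start
  bw <- bg$end - bg$start
  for (i in seq_len(nrow(pk))) {
    slots <- bw - lens[i] + 1
    ok <- which(slots > 0)
    if (length(ok) == 0) {
      stop("placement error: peak of length ", lens[i],
           " fits in no background region", call. = FALSE)
    }
    j <- if (length(ok) == 1) ok else sample(ok, 1, prob = slots[ok])
    start <- bg$start[j] + floor(stats::runif(1, 0, slots[j]))
    pk$chrom[i] <- bg$chrom[j]
    pk$start[i] <- start
    pk$end[i] <- start + lens[i]
  }
  out <- df_to_regions(pk)
  S4Vectors::mcols(out) <- S4Vectors::mcols(peaks)
  out
}

empirical_result <- function(observed, null_counts, n_iter,
                             variant = c("standard", "plus_one", "mid"),
                             mode = NA_character_,
                             direction = NA_character_) {
  variant <- match.arg(variant)
  n_ge <- sum(null_counts >= observed)
  n_gt <- sum(null_counts > observed)
  p <- switch(variant,
              standard = n_ge / n_iter,
              plus_one = (n_ge + 1) / (n_iter + 1),
              mid = (n_gt + 0.5 * (n_ge - n_gt)) / n_iter)
  tab <- table(null_counts)
  structure(list(observed = observed,
                 null_hist = data.frame(count = as.numeric(names(tab)),
                                        frequency = as.integer(tab)),
                 null_mean = mean(null_counts),
                 p_empirical = p,
                 at_resolution_floor = n_ge == 0,
                 n_ge = n_ge, n_gt = n_gt, n_iter = n_iter,
                 variant = variant, mode = mode, direction = direction),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("<overlap_test> ", x$direction, " shuffle, ", x$mode,
      "-wise counting\n", sep = "")
  cat("  observed overlap: ", x$observed, "  (null mean ",
      signif(x$null_mean, 3), ", ", format(x$n_iter, big.mark = ","),
      " iterations)\n", sep = "")
  if (x$at_resolution_floor) {
    cat("  empirical p < ", format(1 / x$n_iter, scientific = TRUE),
        " (no null count reached the observed value)\n", sep = "")
  } else {
    cat("  empirical p = ", format(x$p_empirical, digits = 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Generic permutation test
#'
#' Runs `counter` on the original `input` and on `n_iter` shuffles of it,
#' and reports the empirical p-value `m / n_iter` where `m` is the number
#' of iterations whose null count is at least the observed count (one
#' sided, enrichment). When `m = 0` the p-value is reported as a bound
#' (`p < 1/n_iter`) and flagged; `variant` selects the add-one or mid-p
#' alternatives to the default convention.
#'
#' @param counter function mapping an input to an integer overlap count.
#' @param shuffler function mapping an input to a shuffled input.
#' @param input the observed object.
#' @param n_iter iterations (>= 1).
#' @param seed optional seed applied before the iteration loop.
#' @param variant `"standard"` (`m/n`), `"plus_one"` (`(m+1)/(n+1)`) or
#'   `"mid"` (counts ties as half).
#' @param mode,direction labels stored on the result.
#' @return an `overlap_test` object.
#' @export
permutation_test <- function(counter, shuffler, input, n_iter = 1e5,
                             seed = NULL,
                             variant = c("standard", "plus_one", "mid"),
                             mode = "locus", direction = "loci") {
  if (n_iter < 1) stop("config error: n_iter must be >= 1", call. = FALSE)
  variant <- match.arg(variant)
  observed <- counter(input)
  if (!is.null(seed)) set.seed(seed)
  null_counts <- vapply(seq_len(n_iter),
                        function(i) as.numeric(counter(shuffler(input))),
                        numeric(1))
  empirical_result(observed, null_counts, n_iter, variant, mode, direction)
}

# light per-locus representation for the fast shuffle loop
block_geometry <- function(loci) {
  list(len = loci$end - loci$start,
       offsets = lapply(seq_len(nrow(loci)), function(i)
         loci$members[[i]]$pos - loci$start[i]),
       n = nrow(loci))
}

#' Enrichment test: risk loci shuffled around the genome
#'
#' The observed statistic is the number of loci overlapping (or, with
#' `window > 0`, lying within `window` bp of) a peak; the null
#' distribution comes from relocating every haplotype block uniformly
#' around the genome `n_iter` times and recounting. Locus-wise, member-SNP
#' counting throughout.
#'
#' @param loci a `risk_loci` object.
#' @param peaks `GRanges`.
#' @param genome a [genome_layout()].
#' @param window proximity window in bp (0 = direct overlap).
#' @param n_iter iterations (the published analyses use 100,000).
#' @param seed RNG seed.
#' @param variant p-value convention, see [permutation_test()].
#' @param gap_mask optional exclusion regions (slower rejection-sampling
#'   path).
#' @return an `overlap_test` object.
#' @export
locus_shuffle_test <- function(loci, peaks, genome, window = 0,
                               n_iter = 1e5, seed = NULL,
                               variant = "standard", gap_mask = NULL) {
  if (n_iter < 1) stop("config error: n_iter must be >= 1", call. = FALSE)
  counter <- function(l) {
    if (window > 0) count_proximal(l, peaks, window)
    else count_locus_overlaps(l, peaks, mode = "snp")
  }
  if (!is.null(gap_mask)) {
    return(permutation_test(counter, function(l)
      shuffle_blocks(l, genome, gap_mask), loci, n_iter, seed, variant,
      mode = "locus", direction = "loci"))
  }
  observed <- counter(loci)
  idx <- interval_index(peaks, window = window)
  geo <- block_geometry(loci)
  chroms <- names(genome)
  glen <- as.numeric(genome)
  n_mem <- lengths(geo$offsets)
  block_of <- rep(seq_len(geo$n), n_mem)
  offsets <- unlist(geo$offsets, use.names = FALSE)
  # per-block chromosome sampling probabilities
  slot_mat <- outer(glen, geo$len, function(L, w) pmax(L - w + 1, 0))
  if (any(colSums(slot_mat) == 0)) {
    stop("placement error: a block fits on no chromosome", call. = FALSE)
  }
  prob_mat <- sweep(slot_mat, 2, colSums(slot_mat), "/")
  if (!is.null(seed)) set.seed(seed)
  null_counts <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    ch_i <- vapply(seq_len(geo$n), function(b)
      sample.int(length(chroms), 1, prob = prob_mat[, b]), integer(1))
    starts <- floor(stats::runif(geo$n) * slot_mat[cbind(ch_i, seq_len(geo$n))])
    pos <- starts[block_of] + offsets
    hit <- points_in_index(idx, chroms[ch_i][block_of], pos)
    null_counts[it] <- length(unique(block_of[hit]))
  }
  empirical_result(observed, null_counts, n_iter, variant,
                   mode = if (window > 0) "proximal" else "locus",
                   direction = "loci")
}

#' Converse enrichment test: peaks shuffled within a background
#'
#' The observed statistic is the number of distinct peaks containing at
#' least one locus member SNP (peak-wise counting, so one locus inside two
#' peaks contributes two); the null relocates every peak uniformly within
#' the background region set `n_iter` times.
#'
#' @param loci a `risk_loci` object.
#' @param peaks,background `GRanges` (peaks are constrained to lie inside
#'   background regions, e.g. active enhancers).
#' @inheritParams locus_shuffle_test
#' @return an `overlap_test` object.
#' @export
peak_shuffle_test <- function(loci, peaks, background, n_iter = 1e5,
                              seed = NULL, variant = "standard") {
  if (n_iter < 1) stop("config error: n_iter must be >= 1", call. = FALSE)
  observed <- count_peak_overlaps(loci, peaks, mode = "snp")
  pk <- regions_to_df(peaks)
  bg <- regions_to_df(background)
  lens <- pk$end - pk$start
  bw <- bg$end - bg$start
  pts <- locus_points(loci)
  snp_by_chrom <- lapply(split(pts$pos, pts$chrom), sort)
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(pk)
  # pre-draw destination regions for all iterations, peak by peak
  region_draw <- matrix(0L, nrow = n_iter, ncol = B)
  for (b in seq_len(B)) {
    slots <- bw - lens[b] + 1
    ok <- which(slots > 0)
    if (length(ok) == 0) {
      stop("placement error: peak of length ", lens[b],
           " fits in no background region", call. = FALSE)
    }
    region_draw[, b] <- if (length(ok) == 1) rep(ok, n_iter) else
      sample(ok, n_iter, replace = TRUE, prob = slots[ok])
  }
  u <- matrix(stats::runif(n_iter * B), nrow = n_iter)
  null_counts <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    j <- region_draw[it, ]
    starts <- bg$start[j] + floor(u[it, ] * (bw[j] - lens + 1))
    ends <- starts + lens
    chs <- bg$chrom[j]
    hit <- logical(B)
    for (ch in unique(chs)) {
      pos <- snp_by_chrom[[ch]]
      if (is.null(pos)) next
      i <- which(chs == ch)
      hit[i] <- findInterval(ends[i] - 1, pos) -
        findInterval(starts[i] - 1, pos) > 0
    }
    null_counts[it] <- sum(hit)
  }
  empirical_result(observed, null_counts, n_iter, variant,
                   mode = "peak", direction = "peaks")
}
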