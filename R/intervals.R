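#' @title Interval algebra for loci, peaks and genes
#' @description Helpers for BED-style region sets. All data-frame coordinates
#'   in the package are 0-based, half-open; `GRanges` objects (1-based,
#'   closed) are used as the public container for peaks, enhancers and other
#'   region sets, with conversion at the boundary.
#' @name intervals
NULL

# GRanges <-> 0-based half-open data.frame -----------------------------------

regions_to_df <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- as.character(mc$name)
  if (!is.null(mc$dataset)) df$dataset <- as.character(mc$dataset)
  df
}

df_to_regions <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid region: need 0 <= start < end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if (!is.null(df$name)) S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(df$dataset)) S4Vectors::mcols(gr)$dataset <- df$dataset
  gr
}

#' Read / write BED interval files
#'
#' Thin wrappers over `rtracklayer` so every region set enters and leaves
#' the package as standard BED (0-based, half-open on disk; `GRanges` in
#' memory).
#'
#' @param path file path.
#' @param gr a `GRanges`.
#' @return `read_bed` returns a `GRanges`; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Internal per-chromosome sorted disjoint-interval index ----------------------
# Used by the counting operations and the permutation loop; membership tests
# are O(log n) via findInterval. `window` expands every interval by `window`
# bp on each side, which implements the proximity convention: the gap between
# a SNP base and the nearest peak base is <= window iff the SNP falls in the
# expanded interval (window = 0 reduces to direct overlap).

interval_index <- function(regions, window = 0) {
  if (methods::is(regions, "GRanges")) regions <- regions_to_df(regions)
  if (nrow(regions) == 0) return(list())
  s <- pmax(0, regions$start - window)
  e <- regions$end + window
  out <- list()
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    ss <- s[i]; ee <- e[i]
    o <- order(ss, ee)
    ss <- ss[o]; ee <- ee[o]
    # merge overlapping/abutting intervals into a disjoint sorted set
    ms <- numeric(0); me <- numeric(0)
    cs <- ss[1]; ce <- ee[1]
    if (length(ss) > 1) {
      for (k in 2:length(ss)) {
        if (ss[k] <= ce) {
          ce <- max(ce, ee[k])
        } else {
          ms <- c(ms, cs); me <- c(me, ce)
          cs <- ss[k]; ce <- ee[k]
        }
      }
    }
    ms <- c(ms, cs); me <- c(me, ce)
    out[[ch]] <- list(start = ms, end = me)
  }
  out
}

points_in_index <- function(index, chrom, pos) {
  hit <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    idx <- index[[ch]]
    if (is.null(idx)) next
    j <- findInterval(pos[i], idx$start)
    hit[i] <- j > 0 & pos[i] < idx$end[pmax(j, 1)]
  }
  hit
}

span_in_index <- function(index, chrom, start, end) {
  hit <- logical(length(start))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    idx <- index[[ch]]
    if (is.null(idx)) next
    k <- findInterval(end[i] - 1, idx$start)
    hit[i] <- k > 0 & idx$end[pmax(k, 1)] > start[i]
  }
  hit
}

# members of a risk_loci object as chrom/pos vectors
locus_points <- function(loci) {
  mem <- loci$members
  n <- vapply(mem, nrow, integer(1))
  data.frame(locus = rep(seq_len(nrow(loci)), n),
             chrom = rep(loci$chrom, n),
             pos = unlist(lapply(mem, `[[`, "pos"), use.names = FALSE))
}

#' Consensus peaks across replicate datasets
#'
#' Clusters peaks from several ChIP-seq datasets by single-linkage >= 1 bp
#' overlap and keeps clusters supported by at least `min_datasets` distinct
#' datasets; each retained cluster is emitted as the union span of its
#' members. This reproduces the stringent binding-site definition in which
#' only sites present in two or more datasets count.
#'
#' @param peak_sets named list of `GRanges`, one per dataset (names are the
#'   dataset ids).
#' @param min_datasets minimum number of distinct supporting datasets.
#' @return `GRanges` of consensus peaks with an `n_datasets` column.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 200))
#' consensus_peaks(list(ds1 = a, ds2 = b))
#' @export
consensus_peaks <- function(peak_sets, min_datasets = 2L) {
  if (is.null(names(peak_sets)) || anyDuplicated(names(peak_sets))) {
    stop("peak_sets must be a list with unique dataset names", call. = FALSE)
  }
  if (min_datasets > length(peak_sets)) {
    stop("min_datasets (", min_datasets, ") exceeds the number of datasets (",
         length(peak_sets), ")", call. = FALSE)
  }
  tagged <- lapply(names(peak_sets), function(nm) {
    gr <- peak_sets[[nm]]
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$dataset <- rep(nm, length(gr))
    gr
  })
  all <- sort(do.call(c, unname(tagged)), ignore.strand = TRUE)
  if (length(all) == 0) return(all)
  # min.gapwidth = 0 merges only ranges sharing >= 1 bp (not book-ended ones)
  clusters <- GenomicRanges::reduce(all, min.gapwidth = 0L,
                                    ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(clusters, all, minoverlap = 1L,
                                    ignore.strand = TRUE)
  support <- tapply(S4Vectors::mcols(all)$dataset[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(d) length(unique(d)))
  n_ds <- integer(length(clusters))
  n_ds[as.integer(names(support))] <- as.integer(support)
  S4Vectors::mcols(clusters)$n_datasets <- n_ds
  clusters[n_ds >= min_datasets]
}

#' Count risk loci overlapping a peak set
#'
#' Locus-wise counting: the number of loci with at least one hit, where in
#' `snp` mode a hit is a member SNP whose base falls inside a peak, and in
#' `span` mode the haplotype-block span intersects a peak. A locus counts at
#' most once however many peaks it touches.
#'
#' @param loci a `risk_loci` object (see [clump()]).
#' @param peaks `GRanges` of peaks.
#' @param mode `"snp"` (default, matches "an associated SNP directly
#'   overlapped a binding site") or `"span"`.
#' @return integer count of loci.
#' @export
count_locus_overlaps <- function(loci, peaks, mode = c("snp", "span")) {
  mode <- match.arg(mode)
  if (nrow(loci) == 0) return(0L)
  idx <- interval_index(peaks)
  if (length(idx) == 0) return(0L)
  if (mode == "snp") {
    pts <- locus_points(loci)
    hit <- points_in_index(idx, pts$chrom, pts$pos)
    length(unique(pts$locus[hit]))
  } else {
    sum(span_in_index(idx, loci$chrom, loci$start, loci$end))
  }
}

#' Count peaks hit by risk loci
#'
#' Peak-wise counting for the converse test: the number of distinct peaks
#' containing at least one locus member SNP (`snp` mode) or intersecting at
#' least one block span (`span` mode). One locus sitting inside two peaks
#' contributes two.
#'
#' @inheritParams count_locus_overlaps
#' @return integer count of peaks.
#' @export
count_peak_overlaps <- function(loci, peaks, mode = c("snp", "span")) {
  mode <- match.arg(mode)
  pk <- if (methods::is(peaks, "GRanges")) regions_to_df(peaks) else peaks
  if (nrow(pk) == 0 || nrow(loci) == 0) return(0L)
  if (mode == "snp") {
    pts <- locus_points(loci)
    hit <- logical(nrow(pk))
    for (ch in unique(pk$chrom)) {
      pos <- sort(pts$pos[pts$chrom == ch])
      i <- which(pk$chrom == ch)
      if (length(pos) == 0) next
      hit[i] <- findInterval(pk$end[i] - 1, pos) -
        findInterval(pk$start[i] - 1, pos) > 0
    }
    sum(hit)
  } else {
    idx <- interval_index(data.frame(chrom = loci$chrom, start = loci$start,
                                     end = loci$end))
    sum(span_in_index(idx, pk$chrom, pk$start, pk$end))
  }
}

#' Count loci overlapping or proximal to peaks
#'
#' A locus counts when the gap between its closest member SNP and the
#' nearest peak edge is at most `window` bp (inclusive); direct overlaps
#' count with gap 0. With `window = 0` this equals
#' `count_locus_overlaps(mode = "snp")`.
#'
#' @inheritParams count_locus_overlaps
#' @param window proximity window in bp (default 25 kb, the extended
#'   cis-element window used around binding peaks).
#' @return integer count of loci.
#' @export
count_proximal <- function(loci, peaks, window = 25000) {
  stopifnot(window >= 0)
  if (nrow(loci) == 0) return(0L)
  idx <- interval_index(peaks, window = window)
  if (length(idx) == 0) return(0L)
  pts <- locus_points(loci)
  hit <- points_in_index(idx, pts$chrom, pts$pos)
  length(unique(pts$locus[hit]))
}

#' Assign candidate target genes to a risk locus
#'
#' The union of (i) genes whose span lies within `near_window` bp of the
#' locus span and (ii) genes whose promoter (TSS +/- `tss_window`)
#' intersects the distal anchor of a chromatin interaction whose other
#' anchor overlaps the locus. Interactions stand in for Capture-C calls.
#'
#' @param locus one row of a `risk_loci` object.
#' @param genes gene models: data.frame with columns `id`, `chrom`,
#'   `start`, `end`, `strand`, `tss` (0-based).
#' @param interactions optional interaction table: data.frame with columns
#'   `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2` (paired anchors,
#'   0-based half-open). Matching is symmetric in the two anchors.
#' @param near_window,tss_window windows in bp.
#' @return character vector of gene ids (sorted, unique).
#' @export
assign_genes <- function(locus, genes, interactions = NULL,
                         near_window = 25000, tss_window = 2000) {
  stopifnot(nrow(locus) == 1)
  if (nrow(genes) == 0) return(character(0))
  near <- genes$chrom == locus$chrom &
    genes$start < locus$end + near_window &
    genes$end > locus$start - near_window
  via_interaction <- rep(FALSE, nrow(genes))
  if (!is.null(interactions) && nrow(interactions) > 0) {
    a1 <- interactions$chrom1 == locus$chrom &
      interactions$start1 < locus$end & interactions$end1 > locus$start
    a2 <- interactions$chrom2 == locus$chrom &
      interactions$start2 < locus$end & interactions$end2 > locus$start
    targets <- rbind(
      data.frame(chrom = interactions$chrom2[a1],
                 start = interactions$start2[a1],
                 end = interactions$end2[a1]),
      data.frame(chrom = interactions$chrom1[a2],
                 start = interactions$start1[a2],
                 end = interactions$end1[a2]))
    if (nrow(targets) > 0) {
      for (k in seq_len(nrow(targets))) {
        prom_lo <- genes$tss - tss_window
        prom_hi <- genes$tss + tss_window + 1  # half-open, ends inclusive
        via_interaction <- via_interaction |
          (genes$chrom == targets$chrom[k] &
             prom_lo < targets$end[k] & prom_hi > targets$start[k])
      }
    }
  }
  sort(unique(genes$id[near | via_interaction]))
}

#' Read / write gene models and interaction tables
#'
#' Gene models travel as a BED-like TSV (`id`, `chrom`, `start`, `end`,
#' `strand`, `tss`); interactions as a BEDPE-style six-column paired-anchor
#' TSV. Coordinates 0-based half-open.
#'
#' @param path file path.
#' @param genes,interactions data.frames as described in [assign_genes()].
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end", "strand", "tss") %in%
                  names(df)))
  if (any(df$tss < df$start | df$tss >= df$end)) {
    stop("gene TSS must lie within the gene span", call. = FALSE)
  }
  df
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_models
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
                %in% names(df)))
  df
}

#' @rdname read_gene_models
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
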