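#' @title Synthetic-data generators
#' @description Every input the pipeline consumes can be generated with
#'   planted ground truth: an LD-block-structured genotype panel, GWAS
#'   summary statistics with planted associations inside and outside peak
#'   intervals, replicate peak sets and an enhancer background, gene models
#'   and chromatin interactions, and negative-binomial count matrices with
#'   planted condition and genotype effects. Each generator draws from a
#'   seed derived deterministically from `plan$seed`, so a plan fixes the
#'   whole dataset.
#' @name synthetic-data
NULL

plan_seed <- function(plan, offset) {
  as.integer((plan$seed + 7919L * offset) %% .Machine$integer.max)
}

# place n intervals of the given lengths uniformly on the genome:
# chromosome chosen with probability proportional to the number of valid
# start positions, start uniform among them
place_uniform <- function(genome, lens) {
  chroms <- names(genome)
  out <- data.frame(chrom = character(length(lens)),
                    start = numeric(length(lens)),
                    end = numeric(length(lens)), stringsAsFactors = FALSE)
  for (i in seq_along(lens)) {
    slots <- as.numeric(genome) - lens[i] + 1
    ok <- slots > 0
    if (!any(ok)) {
      stop("placement error: feature of length ", lens[i],
           " fits on no chromosome", call. = FALSE)
    }
    ch <- sample(chroms[ok], 1, prob = slots[ok])
    start <- floor(stats::runif(1, 0, genome[[ch]] - lens[i] + 1))
    out$chrom[i] <- ch; out$start[i] <- start; out$end[i] <- start + lens[i]
  }
  out
}

#' Simulate binding-site peaks, replicate datasets and enhancers
#'
#' Generates the "true" peak set, `n_peak_datasets` replicate ChIP-seq-like
#' observations of it (edges jittered, a fraction of peaks missed per
#' replicate, plus dataset-specific spurious peaks that no other dataset
#' shares), and an enhancer background region set. A fraction
#' `frac_peaks_in_enhancers` of true peaks is placed inside enhancers so
#' the background-constrained shuffle has somewhere to put them.
#'
#' @param plan a [simulation_plan()].
#' @param genome a [genome_layout()].
#' @return list with `GRanges` elements `peaks`, `enhancers` and a named
#'   list `peak_sets` of replicate `GRanges`.
#' @export
simulate_regions <- function(plan, genome) {
  validate_plan(plan)
  set.seed(plan_seed(plan, 1L))
  enh_len <- floor(stats::runif(plan$enhancer_count,
                                plan$enhancer_len_range[1],
                                plan$enhancer_len_range[2] + 1))
  enh <- place_uniform(genome, enh_len)
  pk_len <- floor(stats::runif(plan$peak_count, plan$peak_len_range[1],
                               plan$peak_len_range[2] + 1))
  n_in <- round(plan$frac_peaks_in_enhancers * plan$peak_count)
  pk <- vector("list", plan$peak_count)
  for (i in seq_len(plan$peak_count)) {
    if (i <= n_in) {
      slots <- enh$end - enh$start - pk_len[i] + 1
      ok <- which(slots > 0)
      if (length(ok) > 0) {
        j <- if (length(ok) == 1) ok else sample(ok, 1, prob = slots[ok])
        start <- enh$start[j] +
          floor(stats::runif(1, 0, slots[j]))
        pk[[i]] <- data.frame(chrom = enh$chrom[j], start = start,
                              end = start + pk_len[i])
        next
      }
    }
    pk[[i]] <- place_uniform(genome, pk_len[i])
  }
  peaks <- do.call(rbind, pk)
  peaks$name <- sprintf("peak_%03d", seq_len(nrow(peaks)))
  peak_sets <- list()
  for (d in seq_len(plan$n_peak_datasets)) {
    keep <- stats::runif(nrow(peaks)) >= plan$peak_dropout
    obs <- peaks[keep, , drop = FALSE]
    jit <- function(n) floor(stats::runif(n, -plan$peak_jitter,
                                          plan$peak_jitter + 1))
    obs$start <- pmax(0, obs$start + jit(nrow(obs)))
    obs$end <- pmax(obs$start + 1, obs$end + jit(nrow(obs)))
    n_noise <- round(plan$peak_noise_rate * plan$peak_count)
    if (n_noise > 0) {
      noise_len <- floor(stats::runif(n_noise, plan$peak_len_range[1],
                                      plan$peak_len_range[2] + 1))
      noise <- place_uniform(genome, noise_len)
      noise$name <- sprintf("noise_d%d_%03d", d, seq_len(n_noise))
      obs <- rbind(obs, noise)
    }
    peak_sets[[paste0("dataset", d)]] <- df_to_regions(obs)
  }
  list(peaks = df_to_regions(peaks),
       enhancers = df_to_regions(enh[, c("chrom", "start", "end")]),
       peak_sets = peak_sets)
}

# sample an anchor position inside a peak / away from peaks, keeping all
# anchors mutually separated
pick_anchors <- function(plan, genome, peaks_df, n_in, n_out) {
  sep <- plan$min_causal_sep
  anchors <- data.frame(chrom = character(0), pos = numeric(0),
                        in_peak = logical(0))
  far_enough <- function(ch, pos) {
    same <- anchors$chrom == ch
    !any(same & abs(anchors$pos - pos) < sep)
  }
  if (n_in > 0) {
    if (is.null(peaks_df) || nrow(peaks_df) == 0) {
      stop("sizing error: in-peak associations requested but no peaks given",
           call. = FALSE)
    }
    ord <- sample(nrow(peaks_df))
    for (j in ord) {
      if (sum(anchors$in_peak) >= n_in) break
      pos <- floor((peaks_df$start[j] + peaks_df$end[j]) / 2)
      if (far_enough(peaks_df$chrom[j], pos)) {
        anchors <- rbind(anchors, data.frame(chrom = peaks_df$chrom[j],
                                             pos = pos, in_peak = TRUE))
      }
    }
    if (sum(anchors$in_peak) < n_in) {
      stop("sizing error: cannot place ", n_in, " separated in-peak anchors",
           call. = FALSE)
    }
  }
  peak_idx <- if (!is.null(peaks_df)) {
    interval_index(peaks_df, window = plan$ld_block_len)
  } else list()
  tries <- 0
  while (sum(!anchors$in_peak) < n_out) {
    tries <- tries + 1
    if (tries > 10000) {
      stop("sizing error: cannot place ", n_out,
           " separated outside-peak anchors", call. = FALSE)
    }
    cand <- place_uniform(genome, 1)
    if (length(peak_idx) &&
        points_in_index(peak_idx, cand$chrom, cand$start)) next
    if (!far_enough(cand$chrom, cand$start)) next
    anchors <- rbind(anchors, data.frame(chrom = cand$chrom,
                                         pos = cand$start, in_peak = FALSE))
  }
  anchors
}

#' Simulate an LD-block-structured genotype panel
#'
#' Dosage columns are organised into haplotype blocks: within a block every
#' SNP is a copy of a block template with each entry independently
#' resampled with probability `1 - sqrt(within_block_r2)`, which makes the
#' expected pairwise dosage correlation with the template
#' `sqrt(within_block_r2)` and hence pairwise r^2 concentrate near the
#' target; SNPs in different blocks are generated independently. When
#' `peaks` is supplied, the blocks that will carry planted associations are
#' anchored so that their index SNP falls inside (or well away from) a
#' peak, with all anchors mutually separated by `min_causal_sep`.
#'
#' @param plan a [simulation_plan()].
#' @param genome a [genome_layout()].
#' @param peaks optional `GRanges` of peaks for anchoring planted blocks.
#' @return a [genotype_panel()] whose map carries `block_id`, `role`
#'   (`causal_peak`, `causal_out`, `sub_peak`, `sub_out` or `null`) and
#'   `is_anchor` columns consumed by [simulate_gwas()].
#' @export
simulate_panel <- function(plan, genome, peaks = NULL) {
  validate_plan(plan)
  if (plan$n_samples < 2) stop("need n_samples >= 2", call. = FALSE)
  set.seed(plan_seed(plan, 2L))
  peaks_df <- if (!is.null(peaks)) regions_to_df(peaks) else NULL
  n_blocks <- ceiling(plan$n_snps / plan$snps_per_block)
  n_special <- plan$n_causal_in_peaks + plan$n_causal_outside +
    plan$n_sub_in_peaks + plan$n_sub_outside
  if (n_special > n_blocks) {
    stop("sizing error: more planted associations than haplotype blocks",
         call. = FALSE)
  }
  if (is.null(peaks_df)) {
    # no peaks to anchor to: every planted block is placed without the
    # peak constraint and labelled as an outside-peak association
    n_in <- 0L
    n_out <- n_special
    roles <- c(rep("causal_out",
                   plan$n_causal_in_peaks + plan$n_causal_outside),
               rep("sub_out", plan$n_sub_in_peaks + plan$n_sub_outside))
  } else {
    n_in <- plan$n_causal_in_peaks + plan$n_sub_in_peaks
    n_out <- plan$n_causal_outside + plan$n_sub_outside
    roles <- c(rep("causal_peak", plan$n_causal_in_peaks),
               rep("sub_peak", plan$n_sub_in_peaks),
               rep("causal_out", plan$n_causal_outside),
               rep("sub_out", plan$n_sub_outside))
  }
  anchors <- pick_anchors(plan, genome, peaks_df, n_in, n_out)
  # anchors rows: in-peak first, then outside, matching `roles`
  anchors <- anchors[order(!anchors$in_peak), , drop = FALSE]

  flip <- 1 - sqrt(plan$within_block_r2)
  map <- list(); cols <- list(); snp <- 0L
  for (b in seq_len(n_blocks)) {
    k <- min(plan$snps_per_block, plan$n_snps - (b - 1L) * plan$snps_per_block)
    if (b <= n_special) {
      role <- roles[b]
      ch <- anchors$chrom[b]
      anchor_pos <- anchors$pos[b]
      lo <- max(0, anchor_pos - plan$ld_block_len / 2)
    } else {
      role <- "null"
      blk <- place_uniform(genome, min(plan$ld_block_len, min(genome)))
      ch <- blk$chrom; lo <- blk$start; anchor_pos <- NA
    }
    hi <- min(genome[[ch]], lo + plan$ld_block_len)
    pos <- sort(sample(seq(floor(lo), floor(hi) - 1), k))
    is_anchor <- rep(FALSE, k)
    if (!is.na(anchor_pos)) {
      pos[which.min(abs(pos - anchor_pos))] <- anchor_pos
      pos <- sort(unique(pos))
      while (length(pos) < k) {
        pos <- sort(unique(c(pos, sample(seq(floor(lo), floor(hi) - 1),
                                         k - length(pos)))))
      }
      is_anchor[match(anchor_pos, pos)] <- TRUE
    }
    maf <- stats::runif(1, plan$maf_range[1], plan$maf_range[2])
    template <- stats::rbinom(plan$n_samples, 2, maf)
    guard <- 0
    while (stats::sd(template) == 0 && guard < 100) {
      template <- stats::rbinom(plan$n_samples, 2, maf)
      guard <- guard + 1
    }
    block_cols <- matrix(0L, nrow = plan$n_samples, ncol = k)
    for (j in seq_len(k)) {
      if (is_anchor[j] || plan$within_block_r2 == 1) {
        block_cols[, j] <- template
      } else {
        col <- template
        resample <- stats::runif(plan$n_samples) < flip
        col[resample] <- stats::rbinom(sum(resample), 2, maf)
        block_cols[, j] <- col
      }
    }
    ids <- sprintf("rs%07d", snp + seq_len(k))
    snp <- snp + k
    map[[b]] <- data.frame(id = ids, chrom = ch, pos = pos,
                           block_id = b, role = role, is_anchor = is_anchor,
                           stringsAsFactors = FALSE)
    cols[[b]] <- block_cols
  }
  map <- do.call(rbind, map)
  dosage <- do.call(cbind, cols)
  # resolve rare cross-block position collisions deterministically
  while (anyDuplicated(map[, c("chrom", "pos")])) {
    dup <- which(duplicated(map[, c("chrom", "pos")]))
    map$pos[dup] <- map$pos[dup] + 1
  }
  o <- order(match(map$chrom, names(genome)), map$pos)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- map$id
  rownames(dosage) <- sprintf("sample_%03d", seq_len(plan$n_samples))
  genotype_panel(dosage, map)
}

#' Simulate GWAS summary statistics with planted associations
#'
#' Background SNPs receive i.i.d. Uniform(0, 1) p-values. Anchor SNPs of
#' `causal_*` blocks receive genome-wide-significant p-values
#' (`log10 p ~ U(-25, -9)`), anchor SNPs of `sub_*` blocks receive
#' sub-threshold p-values (`log10 p ~ U(-7.2, -4.2)`), and the remaining
#' members of a planted block receive attenuated versions of their anchor's
#' signal (the log10 p scaled by `U(0.55, 0.9)`), emulating LD decay of an
#' association signal.
#'
#' @param plan a [simulation_plan()].
#' @param genome a [genome_layout()].
#' @param panel a panel from [simulate_panel()] (its map must carry block
#'   roles).
#' @param peaks the `GRanges` the panel was anchored to (used to check the
#'   plant is feasible).
#' @return summary-statistics data.frame (`chrom`, `pos`, `id`, `pvalue`).
#' @export
simulate_gwas <- function(plan, genome, panel, peaks = NULL) {
  validate_plan(plan)
  map <- panel$map
  if (is.null(map$role)) {
    stop("panel map carries no block roles; use simulate_panel()",
         call. = FALSE)
  }
  need <- c(causal_peak = plan$n_causal_in_peaks,
            causal_out = plan$n_causal_outside,
            sub_peak = plan$n_sub_in_peaks,
            sub_out = plan$n_sub_outside)
  have <- table(map$role[map$is_anchor])
  for (r in names(need)) {
    if (need[[r]] > 0 &&
        (!r %in% names(have) || have[[r]] < need[[r]])) {
      stop("sizing error: panel provides ", if (r %in% names(have))
        have[[r]] else 0L, " '", r, "' anchors but the plan requests ",
        need[[r]], call. = FALSE)
    }
  }
  set.seed(plan_seed(plan, 3L))
  pvalue <- stats::runif(nrow(map))
  for (b in unique(map$block_id[map$role != "null"])) {
    rows <- which(map$block_id == b)
    role <- map$role[rows[1]]
    anchor <- rows[map$is_anchor[rows]]
    lp <- if (startsWith(role, "causal")) {
      -stats::runif(1, 9, 25)
    } else {
      -stats::runif(1, 4.2, 7.2)
    }
    pvalue[anchor] <- 10^lp
    others <- setdiff(rows, anchor)
    pvalue[others] <- 10^(lp * stats::runif(length(others), 0.55, 0.9))
  }
  pvalue <- pmin(pvalue, 1)
  data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
             pvalue = pvalue, stringsAsFactors = FALSE)
}

#' Simulate gene models
#'
#' Gene spans with strand and TSS; a fixed fraction is anchored with its
#' TSS near a peak (regulatory elements cluster around promoters in real
#' annotations, and it gives locus-to-gene assignment something to find),
#' the rest placed uniformly.
#'
#' @param plan a [simulation_plan()].
#' @param genome a [genome_layout()].
#' @param peaks optional `GRanges`; when given, 30% of genes are placed
#'   with their TSS within 15 kb of a peak edge.
#' @return gene-model data.frame (`id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`).
#' @export
simulate_genes <- function(plan, genome, peaks = NULL) {
  validate_plan(plan)
  set.seed(plan_seed(plan, 4L))
  n <- plan$n_genes
  lens <- floor(stats::runif(n, plan$gene_len_range[1],
                             plan$gene_len_range[2] + 1))
  placed <- place_uniform(genome, lens)
  if (!is.null(peaks) && length(peaks) > 0) {
    pk <- regions_to_df(peaks)
    n_near <- round(0.3 * n)
    for (i in seq_len(n_near)) {
      j <- sample(nrow(pk), 1)
      tss <- pk$start[j] + floor(stats::runif(1, -15000, 15000))
      tss <- min(max(tss, 0), genome[[pk$chrom[j]]] - lens[i] - 1)
      placed$chrom[i] <- pk$chrom[j]
      placed$start[i] <- tss
      placed$end[i] <- tss + lens[i]
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", placed$start, placed$end - 1)
  data.frame(id = sprintf("gene_%04d", seq_len(n)), chrom = placed$chrom,
             start = placed$start, end = placed$end, strand = strand,
             tss = tss, stringsAsFactors = FALSE)
}

#' Simulate a chromatin-interaction table
#'
#' For each supplied viewpoint region, emits an interaction to the
#' promoter region of a randomly chosen distal gene (more than
#' `min_distance` away on the same chromosome when possible), standing in
#' for Capture-C interaction calls.
#'
#' @param plan a [simulation_plan()].
#' @param viewpoints data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. risk-locus spans.
#' @param genes gene models from [simulate_genes()].
#' @param min_distance minimum viewpoint-to-promoter distance in bp.
#' @return interaction data.frame (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`).
#' @export
simulate_interactions <- function(plan, viewpoints, genes,
                                  min_distance = 50e3) {
  validate_plan(plan)
  set.seed(plan_seed(plan, 5L))
  out <- list()
  for (i in seq_len(nrow(viewpoints))) {
    vp <- viewpoints[i, ]
    distal <- genes[genes$chrom == vp$chrom &
                      (genes$tss < vp$start - min_distance |
                         genes$tss > vp$end + min_distance), , drop = FALSE]
    if (nrow(distal) == 0) next
    g <- distal[sample(nrow(distal), 1), ]
    out[[length(out) + 1]] <- data.frame(
      chrom1 = vp$chrom, start1 = vp$start, end1 = vp$end,
      chrom2 = g$chrom, start2 = max(0, g$tss - 1000), end2 = g$tss + 1000)
  }
  if (length(out) == 0) {
    return(data.frame(chrom1 = character(0), start1 = numeric(0),
                      end1 = numeric(0), chrom2 = character(0),
                      start2 = numeric(0), end2 = numeric(0)))
  }
  do.call(rbind, out)
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts for gene g in sample s are drawn from a negative binomial with
#' mean `baseline_g * 2^(phi_cond_g * condition_s + phi_geno_g *
#' genotype_s)` and dispersion `plan$nb_dispersion`
#' (`Var = mu + alpha mu^2`). Baselines are log-uniform over
#' `plan$nb_mean_range`. By default the planted log2 fold-changes in
#' `plan$condition_log2fc_effects` / `plan$genotype_log2fc_effects` are
#' assigned to the first genes; pass explicit per-gene vectors to override.
#'
#' @param plan a [simulation_plan()].
#' @param n_genes number of genes.
#' @param group_labels condition indicator per sample (0/1, logical, or a
#'   two-level factor). May be `NULL` if `genotypes` is given.
#' @param genotypes optional 0/1/2 dosage per sample.
#' @param condition_effects,genotype_effects optional per-gene log2
#'   fold-change vectors (length `n_genes`).
#' @return list with `counts` (gene x sample integer matrix), `truth`
#'   (per-gene data.frame of planted parameters) and the annotations used.
#' @export
simulate_counts <- function(plan, n_genes, group_labels = NULL,
                            genotypes = NULL, condition_effects = NULL,
                            genotype_effects = NULL) {
  validate_plan(plan)
  if (is.null(group_labels) && is.null(genotypes)) {
    stop("need group_labels and/or genotypes", call. = FALSE)
  }
  cond <- if (is.null(group_labels)) NULL else {
    if (is.factor(group_labels)) as.integer(group_labels) - 1L
    else as.numeric(group_labels)
  }
  n_samples <- if (!is.null(cond)) length(cond) else length(genotypes)
  if (!is.null(cond) && !is.null(genotypes) &&
      length(cond) != length(genotypes)) {
    stop("group_labels and genotypes must have the same length",
         call. = FALSE)
  }
  pad <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) < n_genes) x <- c(x, rep(0, n_genes - length(x)))
    x[seq_len(n_genes)]
  }
  ce <- pad(condition_effects,
            if (is.null(cond)) 0 else plan$condition_log2fc_effects)
  ge <- pad(genotype_effects,
            if (is.null(genotypes)) 0 else plan$genotype_log2fc_effects)
  set.seed(plan_seed(plan, 6L))
  baseline <- exp(stats::runif(n_genes, log(plan$nb_mean_range[1]),
                               log(plan$nb_mean_range[2])))
  counts <- matrix(0L, nrow = n_genes, ncol = n_samples)
  for (g in seq_len(n_genes)) {
    lfc <- rep(0, n_samples)
    if (!is.null(cond)) lfc <- lfc + ce[g] * cond
    if (!is.null(genotypes)) lfc <- lfc + ge[g] * genotypes
    mu <- baseline[g] * 2^lfc
    counts[g, ] <- stats::rnbinom(n_samples, size = 1 / plan$nb_dispersion,
                                  mu = mu)
  }
  rownames(counts) <- sprintf("gene_%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("sample_%03d", seq_len(n_samples))
  list(counts = counts,
       truth = data.frame(gene = rownames(counts), baseline = baseline,
                          condition_log2fc = ce, genotype_log2fc = ge,
                          dispersion = plan$nb_dispersion),
       condition = cond, genotype = genotypes)
}

#' Read / write a count matrix
#'
#' TSV with a `gene` column followed by one integer column per sample.
#'
#' @param path file path.
#' @param counts gene x sample integer matrix.
#' @return the matrix (reader) or `path` invisibly (writer).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot("gene" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
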