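test_that("make_genome builds the requested layout and rejects infeasible plans", {
  plan <- simulation_plan(n_chroms = 2L, chrom_len = 1e6)
  g <- make_genome(plan)
  expect_equal(unname(as.numeric(g)), c(1e6, 1e6))
  expect_identical(make_genome(plan), g)  # deterministic
  bad <- simulation_plan(n_chroms = 1L, chrom_len = 1e4,
                         peak_count = 1000L, peak_len_range = c(500, 2000))
  expect_error(make_genome(bad), "infeasible")
})

test_that("genome_layout validates its invariants", {
  expect_error(genome_layout(c(1e6, 2e6)), "named")
  expect_error(genome_layout(c(a = 1e6, a = 2e6)), "unique")
  expect_error(genome_layout(c(a = -5)), "positive")
})

test_that("panel dosages are valid and within-block LD hits its target", {
  plan <- small_plan(seed = 3L)
  genome <- make_genome(plan)
  panel <- simulate_panel(plan, genome)
  expect_true(all(panel$dosage %in% 0:2))
  expect_equal(nrow(panel$dosage), plan$n_samples)
  expect_equal(ncol(panel$dosage), plan$n_snps)
  # within-block pairwise r2 concentrates near the target
  r2s <- c()
  for (b in unique(panel$map$block_id)[1:20]) {
    ids <- panel$map$id[panel$map$block_id == b]
    poly <- ids[apply(panel$dosage[, ids, drop = FALSE], 2, sd) > 0]
    if (length(poly) < 2) next
    r2s <- c(r2s, compute_r2(panel, poly[1], poly[2]))
  }
  expect_gt(mean(r2s), plan$within_block_r2 - 0.25)
  expect_lt(abs(mean(r2s) - plan$within_block_r2), 0.25)
})

test_that("within_block_r2 = 1 duplicates dosage columns inside a block", {
  plan <- small_plan(seed = 4L, within_block_r2 = 1)
  panel <- simulate_panel(plan, make_genome(plan))
  b <- panel$map$block_id[1]
  ids <- panel$map$id[panel$map$block_id == b]
  cols <- panel$dosage[, ids, drop = FALSE]
  expect_true(all(apply(cols, 1, function(r) length(unique(r)) == 1)))
  expect_equal(compute_r2(panel, ids[1], ids[2]), 1)
})

test_that("across-block r2 matches the independence expectation 1/(n-1)", {
  # expected squared sample correlation of two independent vectors of
  # length n is 1/(n-1); check by averaging over many cross-block pairs
  plan <- small_plan(seed = 5L, n_samples = 200L)
  panel <- simulate_panel(plan, make_genome(plan))
  map <- panel$map
  set.seed(11)
  r2s <- replicate(200, {
    b <- sample(unique(map$block_id), 2)
    a <- sample(map$id[map$block_id == b[1]], 1)
    c <- sample(map$id[map$block_id == b[2]], 1)
    tryCatch(compute_r2(panel, a, c), error = function(e) NA)
  })
  expect_lt(abs(mean(r2s, na.rm = TRUE) - 1 / (plan$n_samples - 1)), 0.004)
})

test_that("generators are deterministic for a fixed plan seed", {
  plan <- small_plan(seed = 9L)
  genome <- make_genome(plan)
  expect_identical(simulate_regions(plan, genome),
                   simulate_regions(plan, genome))
  reg <- simulate_regions(plan, genome)
  p1 <- simulate_panel(plan, genome, reg$peaks)
  p2 <- simulate_panel(plan, genome, reg$peaks)
  expect_identical(p1, p2)
  expect_identical(simulate_gwas(plan, genome, p1, reg$peaks),
                   simulate_gwas(plan, genome, p2, reg$peaks))
})

test_that("planted GWAS signal sits where the plan says", {
  plan <- small_plan(seed = 6L)
  genome <- make_genome(plan)
  reg <- simulate_regions(plan, genome)
  panel <- simulate_panel(plan, genome, reg$peaks)
  stats <- simulate_gwas(plan, genome, panel, reg$peaks)
  expect_true(all(stats$pvalue > 0 & stats$pvalue <= 1))
  anchors <- panel$map[panel$map$is_anchor, ]
  supra_anchors <- anchors[startsWith(anchors$role, "causal"), ]
  expect_equal(nrow(supra_anchors),
               plan$n_causal_in_peaks + plan$n_causal_outside)
  p_anchor <- stats$pvalue[match(supra_anchors$id, stats$id)]
  expect_true(all(p_anchor < 5e-8))
  # in-peak anchors really are inside peaks
  pk <- as.data.frame(reg$peaks)
  in_peak <- supra_anchors[supra_anchors$role == "causal_peak", ]
  gr_anchor <- gr(in_peak$chrom, in_peak$pos, in_peak$pos + 1)
  expect_true(all(GenomicRanges::countOverlaps(gr_anchor, reg$peaks) > 0))
  # sub-threshold anchors live strictly inside the window
  sub_anchors <- anchors[startsWith(anchors$role, "sub"), ]
  p_sub <- stats$pvalue[match(sub_anchors$id, stats$id)]
  expect_true(all(p_sub > 5e-8 & p_sub < 1e-4))
})

test_that("a null plan produces (almost) no genome-wide-significant SNPs", {
  plan <- small_plan(seed = 7L, n_causal_in_peaks = 0L,
                     n_causal_outside = 0L, n_sub_in_peaks = 0L,
                     n_sub_outside = 0L)
  genome <- make_genome(plan)
  panel <- simulate_panel(plan, genome)
  stats <- simulate_gwas(plan, genome, panel)
  # expected count n_snps * 5e-8 is ~2e-5; none should appear
  expect_equal(sum(stats$pvalue <= 5e-8), 0)
})

test_that("simulate_gwas raises a sizing error when the panel lacks anchors", {
  plan <- small_plan(seed = 8L)
  genome <- make_genome(plan)
  panel <- simulate_panel(plan, genome)  # no peaks -> no in-peak anchors
  plan2 <- plan
  plan2$n_causal_in_peaks <- 5L
  expect_error(simulate_gwas(plan2, genome, panel), "sizing error")
})

test_that("simulated counts recover planted fold-changes and moments", {
  plan <- small_plan(seed = 10L, nb_dispersion = 0.05)
  cond <- rep(c(0, 1), each = 10)
  sim <- simulate_counts(plan, n_genes = 50, group_labels = cond,
                         condition_effects = c(2, rep(0, 49)))
  lfc <- log2(rowMeans(sim$counts[, cond == 1]) /
                rowMeans(sim$counts[, cond == 0]))
  expect_lt(abs(lfc[1] - 2), 0.3)
  expect_lt(max(abs(lfc[-1])), 1)  # null genes centred at zero
  # dispersion -> 0 approaches the Poisson limit variance = mean
  plan_pois <- small_plan(seed = 11L, nb_dispersion = 1e-6)
  simp <- simulate_counts(plan_pois, n_genes = 200,
                          group_labels = rep(0:1, each = 50),
                          condition_effects = rep(0, 200))
  m <- rowMeans(simp$counts)
  v <- apply(simp$counts, 1, var)
  expect_lt(abs(median(v / m) - 1), 0.15)
})

test_that("generated files round-trip through the package readers", {
  plan <- small_plan(seed = 12L)
  genome <- make_genome(plan)
  reg <- simulate_regions(plan, genome)
  panel <- simulate_panel(plan, genome, reg$peaks)
  stats <- simulate_gwas(plan, genome, panel, reg$peaks)

  f <- tempfile(fileext = ".tsv")
  write_summary_stats(stats, f)
  expect_equal(read_summary_stats(f), stats[, c("chrom", "pos", "id",
                                                "pvalue")])
  fd <- tempfile(fileext = ".tsv")
  write_dosage(panel, fd)
  rt <- read_dosage(fd)
  expect_equal(unname(rt$dosage), unname(panel$dosage))
  expect_equal(rt$map$pos, panel$map$pos)

  fb <- tempfile(fileext = ".bed")
  write_bed(reg$peaks, fb)
  rt_peaks <- read_bed(fb)
  expect_equal(GenomicRanges::start(rt_peaks), GenomicRanges::start(reg$peaks))
  expect_equal(GenomicRanges::end(rt_peaks), GenomicRanges::end(reg$peaks))

  cm <- simulate_counts(plan, 20, group_labels = rep(0:1, each = 3))
  fc <- tempfile(fileext = ".tsv")
  write_counts(cm$counts, fc)
  expect_equal(read_counts(fc), cm$counts)

  # same seed twice -> byte-identical files
  f2 <- tempfile(fileext = ".tsv")
  write_summary_stats(simulate_gwas(plan, genome, panel, reg$peaks), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the published-loci fixture matches the printed table", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$pvalue > 0))
  r <- tab[tab$locus == "11q13.3", ]
  expect_equal(r$index_snp, "rs11263654")
  expect_equal(r$pvalue, 1.65e-23)
  expect_equal(r$proximity, "overlap")
  expect_equal(tab$proximity[tab$locus == "14q24.2"], "none")
  expect_true(tab$interaction[tab$locus == "2p21"])
  expect_equal(sum(tab$interaction), 1)
  expect_true(all(tab$proximity %in% c("overlap", "within-25kb", "none")))
  regs <- unlist(lapply(tab$genes, function(g) g$regulation))
  expect_true(all(regs %in% c("up", "down", "flat", "ne")))
})
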