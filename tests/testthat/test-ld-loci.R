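# Independent brute-force clumping oracle: recomputes the full exclusion
# set from scratch at every iteration, with no shared code beyond cor().
brute_clump <- function(stats, panel, cfg, tier = "supra") {
  if (tier == "supra") {
    cand <- stats[stats$pvalue <= cfg$p_threshold, , drop = FALSE]
  } else {
    cand <- stats[stats$pvalue > cfg$p_threshold &
                    stats$pvalue < cfg$p_window_low, , drop = FALSE]
  }
  cand <- cand[cand$id %in% colnames(panel$dosage), , drop = FALSE]
  excl_of <- function(index_row, pool) {
    out <- logical(nrow(pool))
    for (j in seq_len(nrow(pool))) {
      if (pool$chrom[j] != index_row$chrom) next
      if (abs(pool$pos[j] - index_row$pos) < cfg$exclude_dist) {
        out[j] <- TRUE
      } else {
        a <- panel$dosage[, index_row$id]
        b <- panel$dosage[, pool$id[j]]
        if (sd(a) > 0 && sd(b) > 0 && cor(a, b)^2 >= cfg$exclude_r2) {
          out[j] <- TRUE
        }
      }
    }
    out
  }
  if (tier == "sub") {
    supra_idx <- brute_clump(stats, panel, cfg, "supra")
    for (id in supra_idx) {
      row <- stats[stats$id == id, ]
      keep <- !excl_of(row, cand) & cand$id != id
      cand <- cand[keep, , drop = FALSE]
    }
  }
  chrom_levels <- unique(stats$chrom)
  picked <- character(0)
  while (nrow(cand) > 0) {
    o <- order(cand$pvalue, match(cand$chrom, chrom_levels), cand$pos)
    cand <- cand[o, , drop = FALSE]
    index <- cand[1, , drop = FALSE]
    picked <- c(picked, index$id)
    keep <- !excl_of(index, cand) & cand$id != index$id
    cand <- cand[keep, , drop = FALSE]
  }
  picked
}

test_that("compute_r2 matches direct arithmetic and is symmetric", {
  panel <- make_panel(matrix(c(0, 1, 1, 2, 0, 1, 2, 2), ncol = 2,
                             dimnames = list(NULL, c("a", "b"))))
  # hand calculation: cov = 2/3, var_a = 2/3, var_b = 11/12 -> r2 = 8/11
  expect_equal(compute_r2(panel, "a", "b"), 8 / 11)
  expect_equal(compute_r2(panel, "b", "a"), compute_r2(panel, "a", "b"))
  expect_equal(compute_r2(panel, "a", "a"), 1)
})

test_that("compute_r2 rejects monomorphic and unknown SNPs", {
  panel <- make_panel(matrix(c(0, 1, 2, 1, 1, 1), ncol = 2,
                             dimnames = list(NULL, c("poly", "mono"))))
  expect_error(compute_r2(panel, "poly", "mono"), "monomorphic")
  expect_error(compute_r2(panel, "poly", "nope"), "not found")
})

test_that("clump keeps the strongest SNP when all candidates are linked", {
  dos <- matrix(rep(c(0, 1, 2, 0, 1, 2), 3), ncol = 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  panel <- make_panel(dos, pos = c(100, 200, 300))
  stats <- make_stats("chr1", c(100, 200, 300), c("s1", "s2", "s3"),
                      c(1e-9, 1e-12, 1e-10))
  loci <- clump(stats, panel, clump_config(exclude_dist = 1000), "supra")
  expect_equal(nrow(loci), 1)
  expect_equal(loci$index_snp, "s2")  # smallest p
})

test_that("loci on different chromosomes are independent", {
  set.seed(1)
  dos <- matrix(sample(0:2, 40, replace = TRUE), ncol = 2,
                dimnames = list(NULL, c("s1", "s2")))
  panel <- make_panel(dos, pos = c(100, 100), chrom = c("chr1", "chr2"))
  stats <- make_stats(c("chr1", "chr2"), c(100, 100), c("s1", "s2"),
                      c(1e-9, 1e-10))
  loci <- clump(stats, panel, clump_config(), "supra")
  expect_equal(nrow(loci), 2)
})

test_that("clump follows the manual trace of the iterative algorithm", {
  # SNPs at 100 (p=1e-10), 600 (p=1e-9), 5000 (p=1e-8); exclude_dist 1 kb;
  # pairwise r2 < 0.2 -> survivors at 100 and 5000, the SNP at 600 absorbed
  set.seed(42)
  dos <- cbind(s1 = sample(0:2, 200, TRUE), s2 = sample(0:2, 200, TRUE),
               s3 = sample(0:2, 200, TRUE))
  panel <- make_panel(dos, pos = c(100, 600, 5000))
  expect_lt(compute_r2(panel, "s1", "s2"), 0.2)
  expect_lt(compute_r2(panel, "s1", "s3"), 0.2)
  stats <- make_stats("chr1", c(100, 600, 5000), c("s1", "s2", "s3"),
                      c(1e-10, 1e-9, 1e-8))
  loci <- clump(stats, panel,
                clump_config(exclude_dist = 1000, block_r2 = 0.99), "supra")
  expect_equal(loci$index_snp, c("s1", "s3"))
  expect_equal(loci$index_pos, c(100, 5000))
})

test_that("define_block is inclusive at the r2 threshold and spans members", {
  # construct b so that r2(a, b) is exactly the block threshold 0.8 would
  # be fragile; instead use a duplicated column (r2 = 1) and an unlinked one
  set.seed(7)
  a <- sample(0:2, 100, TRUE)
  dos <- cbind(idx = a, dup = a, far = sample(0:2, 100, TRUE))
  panel <- make_panel(dos, pos = c(1000, 5000, 9000))
  stats <- make_stats("chr1", c(1000, 5000, 9000),
                      c("idx", "dup", "far"), c(1e-9, 0.5, 0.5))
  blk <- define_block("idx", stats, panel, clump_config())
  expect_setequal(blk$members[[1]]$id, c("idx", "dup"))
  expect_equal(c(blk$start, blk$end), c(1000, 5001))
  # exact-threshold inclusivity via a threshold set to the realised r2
  r2_far <- compute_r2(panel, "idx", "far")
  cfg_at <- clump_config(exclude_r2 = r2_far / 2, block_r2 = r2_far)
  blk2 <- define_block("idx", stats, panel, cfg_at)
  expect_true("far" %in% blk2$members[[1]]$id)  # >= is inclusive
})

test_that("a SNP with no linked partners forms a singleton 1-bp block", {
  set.seed(8)
  dos <- cbind(a = sample(0:2, 100, TRUE), b = sample(0:2, 100, TRUE))
  panel <- make_panel(dos, pos = c(1000, 2000))
  stats <- make_stats("chr1", c(1000, 2000), c("a", "b"), c(1e-9, 0.5))
  blk <- define_block("a", stats, panel, clump_config())
  expect_equal(blk$n_members, 1)
  expect_equal(blk$end - blk$start, 1)
})

test_that("clump equals the brute-force oracle on random small panels", {
  for (seed in 1:6) {
    set.seed(seed)
    n_snp <- 40
    n <- 50
    # blocks of correlated SNPs to make LD exclusion bite
    base <- matrix(sample(0:2, n * 8, TRUE), nrow = n)
    dos <- base[, rep(1:8, length.out = n_snp)]
    flip <- matrix(runif(n * n_snp) < 0.2, nrow = n)
    dos[flip] <- sample(0:2, sum(flip), TRUE)
    colnames(dos) <- paste0("s", 1:n_snp)
    chrom <- rep(c("chr1", "chr2"), each = n_snp / 2)
    pos <- rep(seq(0, by = 40e3, length.out = n_snp / 2), 2)
    panel <- make_panel(dos, pos = pos, chrom = chrom)
    stats <- make_stats(chrom, pos, colnames(dos),
                        10^-runif(n_snp, 0, 12))
    cfg <- clump_config(exclude_dist = 100e3)
    for (tier in c("supra", "sub")) {
      got <- clump(stats, panel, cfg, tier)
      want <- brute_clump(stats, panel, cfg, tier)
      expect_equal(got$index_snp, want,
                   info = paste("seed", seed, "tier", tier))
    }
  }
})

test_that("survivor pairwise constraints hold for every clumped output", {
  plan <- small_plan(seed = 21L)
  genome <- make_genome(plan)
  reg <- simulate_regions(plan, genome)
  panel <- simulate_panel(plan, genome, reg$peaks)
  stats <- simulate_gwas(plan, genome, panel, reg$peaks)
  cfg <- clump_config()
  supra <- clump(stats, panel, cfg, "supra")
  sub <- clump(stats, panel, cfg, "sub")
  check_pairs <- function(loci) {
    for (i in seq_len(nrow(loci))) {
      for (j in seq_len(nrow(loci))) {
        if (i >= j || loci$chrom[i] != loci$chrom[j]) next
        expect_gte(abs(loci$index_pos[i] - loci$index_pos[j]),
                   cfg$exclude_dist)
        expect_lt(compute_r2(panel, loci$index_snp[i], loci$index_snp[j]),
                  cfg$exclude_r2)
      }
    }
  }
  check_pairs(supra)
  check_pairs(sub)
  # sub-threshold indices are disjoint (distance and LD) from supra indices
  for (i in seq_len(nrow(sub))) {
    for (j in seq_len(nrow(supra))) {
      if (sub$chrom[i] == supra$chrom[j]) {
        expect_gte(abs(sub$index_pos[i] - supra$index_pos[j]),
                   cfg$exclude_dist)
        expect_lt(compute_r2(panel, sub$index_snp[i], supra$index_snp[j]),
                  cfg$exclude_r2)
      }
    }
  }
  # p-value tiers respected and deterministic re-run
  expect_true(all(supra$index_p <= cfg$p_threshold))
  expect_true(all(sub$index_p > cfg$p_threshold &
                    sub$index_p < cfg$p_window_low))
  expect_identical(clump(stats, panel, cfg, "supra"), supra)
})

test_that("stats-only SNPs cannot index a locus and trigger a warning", {
  set.seed(9)
  dos <- cbind(known = sample(0:2, 50, TRUE))
  panel <- make_panel(dos, pos = 1000)
  stats <- make_stats("chr1", c(1000, 800000), c("known", "ghost"),
                      c(1e-9, 1e-12))
  expect_warning(loci <- clump(stats, panel, clump_config(), "supra"),
                 "absent from the panel")
  expect_equal(loci$index_snp, "known")
})

test_that("empty candidate sets give an empty locus table, not an error", {
  set.seed(10)
  panel <- make_panel(cbind(a = sample(0:2, 30, TRUE)), pos = 100)
  stats <- make_stats("chr1", 100, "a", 0.5)
  out <- clump(stats, panel, clump_config(), "supra")
  expect_s3_class(out, "risk_loci")
  expect_equal(nrow(out), 0)
})
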