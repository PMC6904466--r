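# Brute-force oracles: all-pairs scans over plain coordinate triples, no
# shared machinery with the implementation.

brute_locus_overlaps <- function(loci, peaks_df, mode = "snp",
                                 window = 0) {
  hits <- 0L
  for (i in seq_len(nrow(loci))) {
    found <- FALSE
    for (j in seq_len(nrow(peaks_df))) {
      if (loci$chrom[i] != peaks_df$chrom[j]) next
      s <- peaks_df$start[j] - window
      e <- peaks_df$end[j] + window
      if (mode == "snp") {
        for (p in loci$members[[i]]$pos) {
          if (p >= s && p < e) { found <- TRUE; break }
        }
      } else {
        if (loci$start[i] < e && loci$end[i] > s) found <- TRUE
      }
      if (found) break
    }
    if (found) hits <- hits + 1L
  }
  hits
}

brute_peak_overlaps <- function(loci, peaks_df) {
  hits <- 0L
  for (j in seq_len(nrow(peaks_df))) {
    found <- FALSE
    for (i in seq_len(nrow(loci))) {
      if (loci$chrom[i] != peaks_df$chrom[j]) next
      for (p in loci$members[[i]]$pos) {
        if (p >= peaks_df$start[j] && p < peaks_df$end[j]) {
          found <- TRUE; break
        }
      }
      if (found) break
    }
    if (found) hits <- hits + 1L
  }
  hits
}

# single-linkage clustering by repeated merging, then support filtering
brute_consensus <- function(df, min_datasets) {
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$end[i] > df$start[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (cl in unique(comp)) {
    rows <- df[comp == cl, , drop = FALSE]
    if (length(unique(rows$dataset)) >= min_datasets) {
      out <- rbind(out, data.frame(chrom = rows$chrom[1],
                                   start = min(rows$start),
                                   end = max(rows$end)))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 1e5) {
  start <- floor(runif(n, 0, span))
  data.frame(chrom = sample(chroms, n, TRUE), start = start,
             end = start + floor(runif(n, 1, 500)))
}

test_that("consensus keeps multi-dataset clusters as union spans", {
  a <- gr("chr1", 0, 100)
  b <- gr("chr1", 90, 200)
  out <- consensus_peaks(list(ds1 = a, ds2 = b))
  expect_equal(length(out), 1)
  expect_equal(GenomicRanges::start(out), 1)   # 0-based 0
  expect_equal(GenomicRanges::end(out), 200)
  # identical peak in 2 of 2 sets
  out2 <- consensus_peaks(list(ds1 = a, ds2 = a))
  expect_equal(length(out2), 1)
  # peak in only 1 of 5 sets is dropped
  empty <- GenomicRanges::GRanges()
  out3 <- consensus_peaks(list(d1 = a, d2 = empty, d3 = empty,
                               d4 = empty, d5 = empty))
  expect_equal(length(out3), 0)
  # book-ended peaks (0-bp overlap) do not merge
  c2 <- gr("chr1", 100, 200)
  out4 <- consensus_peaks(list(ds1 = a, ds2 = c2))
  expect_equal(length(out4), 0)
  expect_error(consensus_peaks(list(ds1 = a), min_datasets = 2),
               "exceeds")
})

test_that("consensus equals brute-force single-linkage on random sets", {
  for (seed in 1:5) {
    set.seed(seed)
    sets <- lapply(1:3, function(d) random_peaks(25))
    names(sets) <- paste0("d", 1:3)
    got <- consensus_peaks(lapply(sets, function(s)
      gr(s$chrom, s$start, s$end)), min_datasets = 2)
    tagged <- do.call(rbind, lapply(names(sets), function(nm)
      cbind(sets[[nm]], dataset = nm)))
    want <- brute_consensus(tagged, 2)
    got_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(got)),
                         start = GenomicRanges::start(got) - 1,
                         end = GenomicRanges::end(got))
    got_df <- got_df[order(got_df$chrom, got_df$start), , drop = FALSE]
    rownames(got_df) <- rownames(want) <- NULL
    expect_equal(got_df, want, info = paste("seed", seed))
  }
})

test_that("consensus is invariant to input-set ordering", {
  set.seed(6)
  sets <- lapply(1:4, function(d) {
    s <- random_peaks(20)
    gr(s$chrom, s$start, s$end)
  })
  names(sets) <- paste0("d", 1:4)
  a <- consensus_peaks(sets, 2)
  b <- consensus_peaks(rev(sets), 2)
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
})

test_that("locus/peak counting respects half-open SNP semantics", {
  p <- 5000
  loci <- make_loci("chr1", list(p))
  expect_equal(count_locus_overlaps(loci, gr("chr1", p, p + 10)), 1)
  expect_equal(count_locus_overlaps(loci, gr("chr1", p - 10, p)), 0)
  expect_equal(count_locus_overlaps(loci, GenomicRanges::GRanges()), 0)
})

test_that("a locus counts once however many peaks it hits, and conversely", {
  loci <- make_loci("chr1", list(c(1000, 2000)))
  two_peaks <- gr("chr1", c(900, 1900), c(1100, 2100))
  expect_equal(count_locus_overlaps(loci, two_peaks), 1)
  expect_equal(count_peak_overlaps(loci, two_peaks), 2)
  # two loci in one peak -> one peak counted
  loci2 <- make_loci("chr1", list(1000, 1050))
  expect_equal(count_peak_overlaps(loci2, gr("chr1", 900, 1100)), 1)
  expect_equal(count_peak_overlaps(loci2, GenomicRanges::GRanges()), 0)
})

test_that("proximity counting is inclusive at the window and monotone", {
  p <- 50000
  loci <- make_loci("chr1", list(p))
  # peak edge exactly 25 kb from the SNP base
  pk <- gr("chr1", p + 25000, p + 26000)
  expect_equal(count_proximal(loci, pk, window = 25000), 1)
  expect_equal(count_proximal(loci, pk, window = 24999), 0)
  # window 0 equals direct overlap counting
  set.seed(7)
  pkr <- random_peaks(100)
  pks <- gr(pkr$chrom, pkr$start, pkr$end)
  loci_r <- make_loci(sample(c("chr1", "chr2"), 20, TRUE),
                      as.list(floor(runif(20, 0, 1e5))))
  expect_equal(count_proximal(loci_r, pks, window = 0),
               count_locus_overlaps(loci_r, pks, mode = "snp"))
  prev <- -1
  for (w in c(0, 10, 100, 1000, 10000)) {
    cur <- count_proximal(loci_r, pks, window = w)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("all counting modes equal the brute-force all-pairs scan", {
  for (seed in 1:5) {
    set.seed(seed)
    pkr <- random_peaks(200)
    pks <- gr(pkr$chrom, pkr$start, pkr$end)
    members <- lapply(1:15, function(i)
      sort(floor(runif(sample(1:5, 1), 0, 1e5))))
    loci <- make_loci(sample(c("chr1", "chr2"), 15, TRUE), members)
    expect_equal(count_locus_overlaps(loci, pks, "snp"),
                 brute_locus_overlaps(loci, pkr, "snp"))
    expect_equal(count_locus_overlaps(loci, pks, "span"),
                 brute_locus_overlaps(loci, pkr, "span"))
    expect_equal(count_peak_overlaps(loci, pks, "snp"),
                 brute_peak_overlaps(loci, pkr))
    for (w in c(100, 5000)) {
      expect_equal(count_proximal(loci, pks, window = w),
                   brute_locus_overlaps(loci, pkr, "snp", window = w))
    }
  }
})

test_that("gene assignment honours proximity and promoter interactions", {
  locus <- make_loci("chr1", list(100000))
  genes <- data.frame(
    id = c("near", "far", "looped"),
    chrom = "chr1",
    start = c(110000, 300000, 500000),
    end = c(120000, 310000, 510000),
    strand = c("+", "+", "+"),
    tss = c(110000, 300000, 500000))
  # no interactions: only the near gene (10 kb away)
  expect_equal(assign_genes(locus, genes), "near")
  # interaction from the locus to a region covering looped's promoter
  inter <- data.frame(chrom1 = "chr1", start1 = 99000, end1 = 101000,
                      chrom2 = "chr1", start2 = 499500, end2 = 500500)
  expect_setequal(assign_genes(locus, genes, inter), c("near", "looped"))
  # promoter window: target 1 kb beyond the TSS still hits TSS +/- 2 kb
  inter2 <- data.frame(chrom1 = "chr1", start1 = 99000, end1 = 101000,
                       chrom2 = "chr1", start2 = 501000, end2 = 501500)
  expect_true("looped" %in% assign_genes(locus, genes, inter2))
  # a gene 30 kb away with no interaction stays excluded
  genes30 <- data.frame(id = "g30", chrom = "chr1", start = 130001,
                        end = 140000, strand = "+", tss = 130001)
  expect_equal(assign_genes(locus, genes30), character(0))
  expect_equal(assign_genes(locus, genes[0, ]), character(0))
})

test_that("interval round trip preserves BED coordinates exactly", {
  set.seed(8)
  pkr <- random_peaks(30)
  pks <- gr(pkr$chrom, pkr$start, pkr$end)
  f <- tempfile(fileext = ".bed")
  write_bed(pks, f)
  lines <- readLines(f)
  expect_equal(length(lines), 30)
  first <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.numeric(first[2]), pkr$start[1])  # 0-based on disk
  expect_equal(as.numeric(first[3]), pkr$end[1])
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pks))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pks))
})
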