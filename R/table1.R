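#' Published renal-cancer susceptibility loci (fixture)
#'
#' The thirteen genome-wide-significant renal-cell-carcinoma susceptibility
#' loci as printed in the source study's summary table: locus name, index
#' SNP, association p-value, the locus's proximity to a HIF-binding site
#' (`"overlap"`, `"within-25kb"` or `"none"`), whether the locus shows a
#' long-range chromatin interaction with a HIF-binding site, and the
#' per-gene regulation calls for the proximal/interacting protein-coding
#' genes (`up`, `down`, `flat`, `ne` = not expressed). The regulation
#' arrows are carried as labels only; no attempt is made to simulate these
#' specific genes.
#'
#' @return data.frame with one row per locus and a `genes` list-column of
#'   per-gene regulation labels.
#' @examples
#' tab <- table1_fixture()
#' nrow(tab)                                    # 13
#' sum(tab$proximity == "overlap")              # 4
#' sum(tab$proximity != "none")                 # 7
#' @export
table1_fixture <- function() {
  g <- function(...) {
    x <- c(...)
    data.frame(gene = names(x), regulation = unname(x),
               stringsAsFactors = FALSE)
  }
  tab <- data.frame(
    locus = c("11q13.3", "2p21", "12p12.1", "14q24.2", "12q24.31",
              "8q24.21", "11q22.3", "2q22.3", "1p32.3", "4q23",
              "3p22.1", "15q22.31", "3q26.31"),
    index_snp = c("rs11263654", "rs2121267", "rs11534749", "rs28840762",
                  "rs10846748", "rs6470588", "rs117706999", "rs11888238",
                  "rs6676515", "rs7697932", "rs9821249", "rs12905354",
                  "rs234043"),
    pvalue = c(1.65e-23, 6.95e-19, 6.19e-17, 1.08e-15, 1.70e-12,
               2.82e-12, 6.60e-10, 8.15e-10, 3.04e-09, 4.70e-09,
               1.12e-08, 2.28e-08, 4.10e-08),
    proximity = c("overlap", "none", "overlap", "none", "within-25kb",
                  "overlap", "none", "none", "none", "within-25kb",
                  "none", "within-25kb", "overlap"),
    interaction = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  tab$genes <- I(list(
    g(CCND1 = "up", MYEOV = "ne", ORAOV1 = "up"),
    g(EPAS1 = "down"),
    g(BHLHE41 = "flat", ITPR2 = "up", SSPN = "ne"),
    g(DPF3 = "ne"),
    g(SCARB1 = "up"),
    g(MYC = "up"),
    g(DDX10 = "up", EXPH5 = "ne", ATM = "up", NPAT = "flat",
      C11orf65 = "ne", KDELC2 = "down"),
    g(ZEB2 = "up"),
    g(FAF1 = "flat", DMRTA2 = "ne"),
    g(),
    g(EIF1B = "down", ENTPD3 = "ne", RPL14 = "down", ZNF619 = "up",
      ZNF620 = "ne", ZNF621 = "up"),
    g(DIS3L = "flat", MAP2K1 = "up", MEGF11 = "ne", SMAD6 = "flat",
      SNAPC5 = "down", TIPIN = "up", ZWILCH = "up", RPL4 = "flat"),
    g(ECT2 = "up", TNFSF10 = "up")))
  tab
}

#' Materialise the published loci as synthetic coordinates
#'
#' Builds a synthetic coordinate system (one chromosome per published
#' locus) in which the qualitative relations recorded by
#' [table1_fixture()] hold exactly, so the package's counting operations
#' can recompute the published locus counts: a locus labelled `overlap`
#' has its index SNP inside a peak; `within-25kb` has a 10 kb gap to the
#' nearest peak; `none` has no peak within 25 kb; the interacting locus is
#' linked by a chromatin-interaction record to a distal peak more than
#' 25 kb away. Coordinates are synthetic; only the printed relations are
#' encoded.
#'
#' @return list with elements `loci` (a `risk_loci` object), `peaks`
#'   (`GRanges`), `interactions` (paired-anchor data.frame), `genome`
#'   (a [genome_layout()]) and `table` (the fixture rows).
#' @export
table1_regions <- function() {
  tab <- table1_fixture()
  n <- nrow(tab)
  genome <- genome_layout(setNames(rep(2e6, n), tab$locus))
  snp_pos <- 1e6
  loci <- new_risk_loci(data.frame(
    locus_id = tab$locus, chrom = tab$locus,
    start = snp_pos, end = snp_pos + 1,
    index_snp = tab$index_snp, index_pos = snp_pos,
    index_p = tab$pvalue, tier = "supra", n_members = 1L,
    members = I(lapply(tab$index_snp, function(id)
      data.frame(id = id, pos = snp_pos, stringsAsFactors = FALSE))),
    stringsAsFactors = FALSE))
  pk <- list()
  for (i in seq_len(n)) {
    if (tab$proximity[i] == "overlap") {
      pk[[length(pk) + 1]] <- data.frame(
        chrom = tab$locus[i], start = snp_pos - 100, end = snp_pos + 200,
        name = paste0(tab$locus[i], "_site"))
    } else if (tab$proximity[i] == "within-25kb") {
      pk[[length(pk) + 1]] <- data.frame(
        chrom = tab$locus[i], start = snp_pos + 10000,
        end = snp_pos + 11000, name = paste0(tab$locus[i], "_site"))
    }
    if (tab$interaction[i]) {
      pk[[length(pk) + 1]] <- data.frame(
        chrom = tab$locus[i], start = snp_pos + 200000,
        end = snp_pos + 200500, name = paste0(tab$locus[i], "_distal_site"))
    }
  }
  peaks <- df_to_regions(do.call(rbind, pk))
  it <- tab$interaction
  interactions <- data.frame(
    chrom1 = tab$locus[it], start1 = snp_pos - 1000, end1 = snp_pos + 1000,
    chrom2 = tab$locus[it], start2 = snp_pos + 199900,
    end2 = snp_pos + 200600, stringsAsFactors = FALSE)
  list(loci = loci, peaks = peaks, interactions = interactions,
       genome = genome, table = tab)
}

#' Summary counts over the published loci
#'
#' Recomputes, with the package's own counting operations on the synthetic
#' materialisation from [table1_regions()], the headline locus counts: the
#' number of loci whose index SNP directly overlaps a binding site, the
#' number overlapping or within 25 kb, and the number with any potential
#' link to a binding site (proximity or long-range interaction).
#'
#' @return named list of integer counts.
#' @export
table1_summary <- function() {
  tr <- table1_regions()
  overlap <- count_locus_overlaps(tr$loci, tr$peaks, mode = "snp")
  proximal <- count_proximal(tr$loci, tr$peaks, window = 25000)
  # loci whose interaction target lands on a peak
  peak_idx <- interval_index(tr$peaks)
  interacting <- 0L
  prox_idx <- interval_index(tr$peaks, window = 25000)
  for (i in seq_len(nrow(tr$loci))) {
    lc <- tr$loci[i, ]
    pts <- lc$members[[1]]
    is_prox <- any(points_in_index(prox_idx, rep(lc$chrom, nrow(pts)),
                                   pts$pos))
    hits <- tr$interactions$chrom1 == lc$chrom &
      tr$interactions$start1 < lc$end & tr$interactions$end1 > lc$start
    target_on_peak <- FALSE
    if (any(hits)) {
      t <- tr$interactions[hits, , drop = FALSE]
      target_on_peak <- any(span_in_index(peak_idx, t$chrom2, t$start2,
                                          t$end2))
    }
    if (!is_prox && target_on_peak) interacting <- interacting + 1L
  }
  list(n_loci = nrow(tr$loci), overlap = overlap, proximal = proximal,
       associated = proximal + interacting)
}
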