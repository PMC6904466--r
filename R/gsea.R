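#' Combined ranking metric for differential expression
#'
#' The pre-ranked GSEA input metric `pi = phi * (-log10 pv)`, combining
#' the log2 fold-change `phi` between two conditions with the significance
#' `pv` of that differential expression; the sign follows `phi`.
#'
#' @param phi log2 fold-change(s).
#' @param pv p-value(s) in (0, 1].
#' @return numeric metric, same length as the inputs.
#' @examples
#' rank_metric(1, 0.1)    # 1
#' rank_metric(-2, 0.01)  # -4
#' @export
rank_metric <- function(phi, pv) {
  if (any(pv <= 0) || any(pv > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  phi * (-log10(pv))
}

# deterministic ranking: pi descending, ties broken by gene id
order_ranked <- function(ranked) {
  ranked[order(-ranked$pi, ranked$gene), , drop = FALSE]
}

as_ranked <- function(ranked) {
  stopifnot("gene" %in% names(ranked))
  if (!"pi" %in% names(ranked)) {
    stopifnot(all(c("phi", "pv") %in% names(ranked)))
    ranked$pi <- rank_metric(ranked$phi, ranked$pv)
  }
  if (anyDuplicated(ranked$gene)) {
    stop("duplicated gene ids in ranked list", call. = FALSE)
  }
  order_ranked(ranked)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list from top to bottom: meeting a set member
#' increments the running sum by `|pi|^weight` normalised over the set's
#' members, meeting a non-member decrements it by `1 / (N - N_set)`. The
#' enrichment score is the extremum of largest magnitude; `weight = 0`
#' recovers the classic Kolmogorov-Smirnov statistic, `weight = 1` the
#' standard weighted form.
#'
#' @param ranked data.frame with `gene` and either `pi` or both `phi` and
#'   `pv` columns; sorted internally by `pi` descending (ties broken by
#'   gene id).
#' @param set character vector of member gene ids; members absent from the
#'   ranked universe are dropped with a warning.
#' @param weight exponent on `|pi|` for hit increments.
#' @return list with `es`, the `running_sum` trace (length N) and the
#'   ordered `gene` vector.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  ranked <- as_ranked(ranked)
  n <- nrow(ranked)
  missing <- setdiff(set, ranked$gene)
  if (length(missing) > 0) {
    warning(length(missing), " set gene(s) absent from the ranked universe",
            " were dropped")
    set <- intersect(set, ranked$gene)
  }
  if (length(set) == 0) stop("empty gene set after matching", call. = FALSE)
  inset <- ranked$gene %in% set
  n_set <- sum(inset)
  if (n_set >= n) {
    stop("gene set covers the whole universe (degenerate denominator)",
         call. = FALSE)
  }
  w <- abs(ranked$pi)^weight
  nr <- sum(w[inset])
  inc <- if (nr > 0) w / nr else rep(1 / n_set, n)  # all-zero-pi fallback
  step <- ifelse(inset, inc, -1 / (n - n_set))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running, gene = ranked$gene, inset = inset)
}

#' Pre-ranked gene-set enrichment test
#'
#' Computes the weighted enrichment score of `set` on the ranked list and
#' compares it with `n_perm` null scores obtained by drawing random gene
#' sets of the same size from the universe (gene-label permutation, the
#' pre-ranked convention). The p-value is one-sided in the direction of
#' the observed score: the fraction of same-sign null scores at least as
#' large in magnitude. The normalised score divides by the mean magnitude
#' of same-sign null scores.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of null sets.
#' @param seed RNG seed.
#' @param plus_one use the add-one p-value convention `(m+1)/(k+1)`.
#' @return an object of class `gsea_result`: `es`, `nes`, `p_perm`,
#'   `running_sum`, null summaries, `n_perm` and `seed`.
#' @export
gsea_test <- function(ranked, set, weight = 1, n_perm = 10000, seed = NULL,
                      plus_one = FALSE) {
  if (n_perm < 1) stop("config error: n_perm must be >= 1", call. = FALSE)
  ranked <- as_ranked(ranked)
  obs <- enrichment_score(ranked, set, weight)
  n_set <- sum(obs$inset)
  n <- nrow(ranked)
  if (!is.null(seed)) set.seed(seed)
  w <- abs(ranked$pi)^weight
  miss_all <- -1 / (n - n_set)
  null_es <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pick <- sample.int(n, n_set)
    inset <- logical(n)
    inset[pick] <- TRUE
    nr <- sum(w[pick])
    step <- if (nr > 0) ifelse(inset, w / nr, miss_all) else
      ifelse(inset, 1 / n_set, miss_all)
    running <- cumsum(step)
    null_es[i] <- running[which.max(abs(running))]
  }
  same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else
    null_es[null_es < 0]
  k <- length(same_sign)
  m <- sum(abs(same_sign) >= abs(obs$es))
  p <- if (k == 0) 0 else if (plus_one) (m + 1) / (k + 1) else m / k
  nes <- if (k == 0) NA_real_ else obs$es / mean(abs(same_sign))
  structure(list(es = obs$es, nes = nes, p_perm = p,
                 at_resolution_floor = m == 0,
                 running_sum = obs$running_sum, gene = obs$gene,
                 inset = obs$inset, n_set = n_set, n_perm = n_perm,
                 n_same_sign = k, seed = seed, weight = weight),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> set of ", x$n_set, " genes, weight ", x$weight, "\n",
      "  ES = ", signif(x$es, 3), ", NES = ", signif(x$nes, 3), "\n",
      sep = "")
  if (x$at_resolution_floor) {
    cat("  permutation p < ",
        format(1 / max(x$n_same_sign, 1), digits = 2),
        " (no same-sign null score reached |ES|)\n", sep = "")
  } else {
    cat("  permutation p = ", format(x$p_perm, digits = 3), " (",
        x$n_perm, " label permutations)\n", sep = "")
  }
  invisible(x)
}

#' Read a ranked gene list / gene sets
#'
#' The ranked list travels as TSV with columns `gene` and either `pi` or
#' both `phi` and `pv`; gene sets as GMT (set name, description, member
#' genes, tab-separated).
#'
#' @param path file path.
#' @return `read_ranked_table`: a data.frame; `read_gmt`: named list of
#'   character vectors.
#' @export
read_ranked_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_ranked(df)
}

#' @rdname read_ranked_table
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' @rdname read_ranked_table
#' @param ranked a ranked data.frame.
#' @export
write_ranked_table <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
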