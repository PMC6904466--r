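#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's counts are divided by
#' the geometric mean across samples (over genes expressed in every
#' sample) and the median ratio taken. If no gene is expressed in all
#' samples, falls back to total-count scaling (normalised to geometric
#' mean 1) with a warning.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) {
    stop("every sample needs at least one nonzero count", call. = FALSE)
  }
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    warning("no gene expressed in all samples; falling back to ",
            "total-count scaling")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  sub <- counts[all_nonzero, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  apply(sub / ref, 2, stats::median)
}

# --- negative binomial GLM internals ---------------------------------------
# log link, mean mu = exp(offset + X beta), variance mu + alpha mu^2

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# iteratively reweighted least squares for beta at fixed dispersion
nb_irls <- function(y, X, offset, alpha, beta = NULL, tol = 1e-8,
                    maxit = 50) {
  if (is.null(beta)) {
    eta0 <- log(pmax(mean(y), 0.5)) - mean(offset)
    beta <- c(eta0, rep(0, ncol(X) - 1))
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- offset + drop(X %*% beta)
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) break
    new_beta <- drop(fit)
    if (max(abs(new_beta - beta)) <
        tol * max(1, max(abs(beta)))) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  eta <- offset + drop(X %*% beta)
  list(beta = beta, mu = pmin(exp(eta), 1e12), converged = converged)
}

# profile maximum likelihood over log(alpha) at fixed beta
nb_alpha_ml <- function(y, mu, lower = 1e-8, upper = 1e4) {
  f <- function(la) -nb_loglik(y, mu, exp(la))
  opt <- stats::optimize(f, lower = log(lower), upper = log(upper))
  exp(opt$minimum)
}

#' Fit a negative-binomial GLM to one gene
#'
#' Log-link negative-binomial regression `mu = exp(offset + X beta)` with
#' per-gene dispersion: coefficients by iteratively reweighted least
#' squares (relative tolerance `1e-8`), dispersion by profiled maximum
#' likelihood, alternated until the log-likelihood stabilises. With
#' `alpha` supplied the dispersion is held fixed (used for the null fit of
#' the likelihood-ratio test).
#'
#' @param y integer counts, one per sample.
#' @param x covariate vector (numeric, e.g. genotype dosage or a 0/1
#'   condition), a factor (categorical coding), or `NULL` for an
#'   intercept-only model.
#' @param offsets per-sample log size factors (default all zero).
#' @param alpha optional fixed dispersion (> 0).
#' @return an object of class `nb_glm_fit`: `beta` (named, log scale),
#'   `alpha`, `loglik`, `df_model`, `converged`, `mu`.
#' @export
fit_nb_glm <- function(y, x = NULL, offsets = NULL, alpha = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(offsets)) offsets <- rep(0, n)
  stopifnot(length(offsets) == n)
  if (is.null(x)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stopifnot(length(x) == n)
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      if (nlevels(x) < 2) {
        stop("degenerate design: covariate is constant", call. = FALSE)
      }
      X <- stats::model.matrix(~x)
      colnames(X) <- c("(Intercept)", paste0("x", levels(x)[-1]))
    } else {
      if (stats::sd(x) == 0) {
        stop("degenerate design: covariate is constant", call. = FALSE)
      }
      X <- cbind("(Intercept)" = 1, x = x)
    }
  }
  fixed_alpha <- !is.null(alpha)
  if (fixed_alpha && alpha <= 0) {
    stop("dispersion must be > 0", call. = FALSE)
  }
  if (!fixed_alpha) {
    # method-of-moments start, floored away from zero
    mu0 <- pmax(mean(y), 0.5)
    alpha <- max((stats::var(y) - mu0) / mu0^2, 0.01)
  }
  beta <- NULL
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(25)) {
    fit <- nb_irls(y, X, offsets, alpha, beta = beta)
    beta <- fit$beta
    if (!fixed_alpha) alpha <- nb_alpha_ml(y, fit$mu)
    ll_new <- nb_loglik(y, fit$mu, alpha)
    if (is.finite(ll_new) && abs(ll_new - ll) < 1e-10 * (1 + abs(ll_new))) {
      ll <- ll_new
      converged <- fit$converged
      break
    }
    ll <- ll_new
    if (fixed_alpha && fit$converged) {
      converged <- TRUE
      break
    }
  }
  structure(list(beta = setNames(beta, colnames(X)), alpha = alpha,
                 loglik = ll, df_model = ncol(X), converged = converged,
                 mu = fit$mu, offsets = offsets),
            class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat("<nb_glm_fit> logLik ", signif(x$loglik, 6), ", dispersion ",
      signif(x$alpha, 4), if (!x$converged) " (not converged)", "\n",
      sep = "")
  print(signif(x$beta, 4))
  invisible(x)
}

#' Genotype-stratified expression test (negative-binomial LRT)
#'
#' Fits gene expression across samples to a negative-binomial GLM against
#' genotype and compares it, by likelihood ratio, with a model that
#' ignores genotype; significance comes from the upper tail of the
#' chi-square distribution. The dispersion is estimated under the full
#' model and held fixed for the null fit (standard LRT practice for NB
#' GLMs, keeping the two likelihoods on the same dispersion). Genotype
#' enters additively as 0/1/2 dosage by default, or as a categorical
#' factor with `coding = "categorical"`.
#'
#' @param y integer counts per sample.
#' @param genotype 0/1/2 dosage per sample.
#' @param offsets per-sample log size factors.
#' @param coding `"additive"` (df = 1) or `"categorical"` (df = groups -
#'   1).
#' @return an object of class `lrt_result`: `lrt_stat`, `df`, `p_chi2`,
#'   plus the two fits.
#' @export
lrt_genotype <- function(y, genotype, offsets = NULL,
                         coding = c("additive", "categorical")) {
  coding <- match.arg(coding)
  if (length(unique(genotype)) < 2) {
    stop("degenerate design: a single genotype group is present",
         call. = FALSE)
  }
  x <- if (coding == "additive") as.numeric(genotype) else factor(genotype)
  full <- fit_nb_glm(y, x, offsets = offsets)
  null <- fit_nb_glm(y, NULL, offsets = offsets, alpha = full$alpha)
  lrt <- 2 * (full$loglik - null$loglik)
  if (lrt < -1e-8) {
    warning("negative likelihood-ratio statistic (", signif(lrt, 3),
            ") clipped to 0")
  }
  lrt <- max(lrt, 0)
  df <- full$df_model - 1L
  structure(list(lrt_stat = lrt, df = df,
                 p_chi2 = stats::pchisq(lrt, df, lower.tail = FALSE),
                 full = full, null = null, coding = coding),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt_result> LRT = ", signif(x$lrt_stat, 4), " on ", x$df,
      " df, chi-square p = ", format(x$p_chi2, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Paired two-sample test on expression values
#'
#' Wilcoxon signed-rank test on paired differences (the paired member of
#' the Wilcoxon family): exact two-sided p for up to 25 informative pairs,
#' normal approximation with continuity correction beyond that;
#' zero differences are dropped per the usual convention. All-zero
#' differences give a degenerate result with p = 1 and a flag.
#'
#' @param values_a,values_b paired numeric vectors (same length, aligned).
#' @return list with `p_value`, `statistic`, `n_pairs` (informative
#'   pairs), `degenerate`.
#' @export
paired_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("pairing error: input lengths differ", call. = FALSE)
  }
  d <- values_a - values_b
  d <- d[!is.na(d)]
  n_inf <- sum(d != 0)
  if (n_inf == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_pairs = 0L,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d[d != 0], alternative = "two.sided", mu = 0,
                       exact = n_inf <= 25, correct = TRUE))
  list(p_value = min(wt$p.value, 1), statistic = unname(wt$statistic),
       n_pairs = n_inf, degenerate = FALSE)
}

#' Per-gene differential expression and ranking table
#'
#' For each gene, fits the negative-binomial GLM with a 0/1 condition
#' covariate (offsets from median-of-ratios size factors), takes the
#' log2 fold-change `phi` from the condition coefficient and the p-value
#' from the likelihood-ratio test, and combines them into the ranking
#' metric `pi = phi * (-log10 pv)` used by [gsea_test()]. All-zero genes
#' are excluded.
#'
#' @param counts gene x sample count matrix.
#' @param condition 0/1, logical, or two-level factor per sample.
#' @param min_count optional minimum total count per gene (genes below it
#'   are dropped alongside all-zero genes).
#' @return data.frame with columns `gene`, `phi`, `pv`, `pi`, sorted by
#'   `pi` descending.
#' @export
differential_rank_table <- function(counts, condition, min_count = 1) {
  cond <- if (is.factor(condition)) as.integer(condition) - 1L
          else as.numeric(condition)
  if (length(unique(cond)) != 2) {
    stop("condition must define exactly two groups", call. = FALSE)
  }
  if (min(table(cond)) < 2) {
    warning("a condition group has fewer than 2 samples; estimates will ",
            "be unstable")
  }
  keep <- rowSums(counts) >= max(min_count, 1)
  counts <- counts[keep, , drop = FALSE]
  offsets <- log(size_factors(counts))
  out <- data.frame(gene = rownames(counts), phi = NA_real_,
                    pv = NA_real_, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    full <- fit_nb_glm(y, cond, offsets = offsets)
    null <- fit_nb_glm(y, NULL, offsets = offsets, alpha = full$alpha)
    lrt <- max(2 * (full$loglik - null$loglik), 0)
    out$phi[g] <- full$beta[["x"]] / log(2)
    out$pv[g] <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  }
  out$pv <- pmax(out$pv, .Machine$double.xmin)  # keep -log10 finite
  out$pi <- rank_metric(out$phi, out$pv)
  order_ranked(out)
}
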