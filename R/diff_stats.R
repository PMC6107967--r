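#' Relative-log-expression (median-of-ratios) size factors
#'
#' The classical median-of-ratios estimator: for each sample, the median over
#' features (restricted to rows positive in every sample) of the ratio of
#' the sample's count to the feature's geometric mean across samples.
#'
#' @param m Non-negative integer count matrix, features x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
rle_size_factors <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 1L) {
    sf <- 1
    names(sf) <- colnames(m)
    return(sf)
  }
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "supply user normalization factors instead")
  mp <- m[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(mp)))
  sf <- apply(mp, 2, function(col) stats::median(col / geo))
  names(sf) <- colnames(m)
  sf
}

# Mean-dispersion trend alpha(mu) = a1/mu + a0, fitted by iteratively
# reweighted least squares on per-feature moment estimates, with outliers
# above 15x the current trend dropped between iterations.
.fit_dispersion_trend <- function(mu, disp) {
  ok <- is.finite(mu) & is.finite(disp) & mu > 0 & disp > 1e-8
  if (sum(ok) < 3L) {
    md <- if (any(ok)) stats::median(disp[ok]) else 0.05
    return(function(m) rep(max(md, 1e-4), length(m)))
  }
  mu_f <- mu[ok]; disp_f <- disp[ok]
  a0 <- stats::median(disp_f); a1 <- 0
  for (it in 1:5) {
    pred <- a1 / mu_f + a0
    keep <- disp_f < 15 * pmax(pred, 1e-8)
    fit <- tryCatch(stats::lm(disp_f[keep] ~ I(1 / mu_f[keep])),
                    error = function(e) NULL)
    if (is.null(fit)) break
    a0 <- max(unname(stats::coef(fit)[1]), 1e-6)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  }
  function(m) pmax(a1 / pmax(m, 1e-8) + a0, 1e-6)
}

#' Negative-binomial differential test between two conditions
#'
#' A DESeq2-style workflow: counts are normalized by size factors;
#' per-feature NB dispersions are estimated by method-of-moments and shrunk
#' in log space toward a fitted mean-dispersion trend (`a1/mu + a0`); the
#' log2 fold change (condition 2 over condition 1, with a pseudocount on
#' both sides) is tested with a Wald statistic whose standard error comes
#' from the NB variance of the per-condition means; p-values are adjusted by
#' Benjamini-Hochberg across tested features. Features with zero counts in
#' all samples are reported `NA` and excluded from the adjustment.
#'
#' Numeric agreement with any particular NB implementation is not promised;
#' behavior is validated distributionally (type-I error, fold-change bias)
#' in the package tests.
#'
#' @param m Count matrix, features x samples (rownames = feature ids).
#' @param conditions Character/factor vector of length `ncol(m)` with
#'   exactly two levels; the second level is the numerator of the fold
#'   change.
#' @param size_factors Optional per-sample factors; default
#'   [rle_size_factors].
#' @param pseudocount Normalized-count pseudocount for the fold change
#'   (default 0.5).
#' @param prior_weight Weight of the trend in the log-space dispersion
#'   shrinkage, in pseudo-degrees-of-freedom (default 4).
#' @return `data.frame` with `feature`, `base_mean`, `mean_1`, `mean_2`,
#'   `log2fc`, `p`, `fdr`. The `"conditions"` attribute records level order;
#'   `"single_replicate"` flags designs with one sample per condition
#'   (dispersion then comes entirely from the trend).
#' @export
nb_differential <- function(m, conditions, size_factors = NULL,
                            pseudocount = 0.5, prior_weight = 4) {
  m <- as.matrix(m)
  conditions <- as.character(conditions)
  lev <- unique(conditions)   # order of first appearance, not alphabetical
  if (length(lev) != 2L)
    stop("exactly two conditions required, got: ", paste(lev, collapse = ", "))
  if (length(conditions) != ncol(m))
    stop("conditions length does not match sample count")
  if (is.null(size_factors)) size_factors <- rle_size_factors(m)
  q <- sweep(m, 2, size_factors, "/")
  i1 <- which(conditions == lev[1]); i2 <- which(conditions == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  single_rep <- (n1 == 1L && n2 == 1L)

  mu1 <- rowMeans(q[, i1, drop = FALSE])
  mu2 <- rowMeans(q[, i2, drop = FALSE])
  base_mean <- rowMeans(q)

  # Moment dispersion from pooled within-condition variance of normalized
  # counts: Var(k/s) = mu/s + alpha * mu^2.
  resid_ss <- rowSums((q[, i1, drop = FALSE] - mu1)^2) +
    rowSums((q[, i2, drop = FALSE] - mu2)^2)
  df <- max(n1 + n2 - 2L, 0L)
  inv_s <- mean(1 / size_factors)
  if (df > 0) {
    v <- resid_ss / df
    disp_mom <- (v - base_mean * inv_s) / base_mean^2
    disp_mom[!is.finite(disp_mom)] <- NA_real_
  } else {
    disp_mom <- rep(NA_real_, nrow(m))
  }
  trend <- .fit_dispersion_trend(base_mean, disp_mom)
  disp_tr <- trend(base_mean)
  w_gene <- df / 2
  disp <- disp_tr
  if (w_gene > 0) {
    has <- !is.na(disp_mom) & disp_mom > 0
    disp[has] <- exp((w_gene * log(disp_mom[has]) +
                        prior_weight * log(disp_tr[has])) /
                       (w_gene + prior_weight))
  }

  log2fc <- log2((mu2 + pseudocount) / (mu1 + pseudocount))
  var_mean <- function(mu, idx) {
    mu_f <- pmax(mu, pseudocount)
    sapply(seq_along(mu_f), function(i) {
      sum(mu_f[i] / size_factors[idx] + disp[i] * mu_f[i]^2) / length(idx)^2
    })
  }
  v1 <- var_mean(mu1, i1); v2 <- var_mean(mu2, i2)
  se <- sqrt(v1 / pmax(mu1, pseudocount)^2 + v2 / pmax(mu2, pseudocount)^2) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  all_zero <- rowSums(m) == 0
  p[all_zero] <- NA_real_
  log2fc[all_zero] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[!all_zero] <- stats::p.adjust(p[!all_zero], method = "BH")

  out <- data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                    base_mean = base_mean, mean_1 = mu1, mean_2 = mu2,
                    log2fc = log2fc, p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- lev
  attr(out, "single_replicate") <- single_rep
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher test for pausing-index change without replicates
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `rbind(c(pp1, gb1), c(pp2, gb2))` of promoter-proximal and gene-body
#' counts in the two conditions.
#'
#' @param pp1,gb1 Counts in condition 1.
#' @param pp2,gb2 Counts in condition 2.
#' @return List with `odds_ratio` (conditional MLE, `NA` when a margin is
#'   zero) and `p` (1 when a margin is zero).
#' @export
pindex_change_fisher <- function(pp1, gb1, pp2, gb2) {
  tab <- rbind(c(pp1, gb1), c(pp2, gb2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Cochran-Mantel-Haenszel test for consistent pausing-index change
#'
#' Stratified analysis over replicate pairs: each stratum is the 2x2 table
#' of (pp, gb) counts for one replicate of each condition. Returns the
#' Mantel-Haenszel common odds ratio and the continuity-corrected CMH
#' chi-square p-value.
#'
#' @param strata List of 2x2 matrices (>= 2), each
#'   `rbind(c(pp1, gb1), c(pp2, gb2))`.
#' @return List with `common_or` and `p` (both `NA` when every stratum is
#'   degenerate).
#' @export
pindex_change_cmh <- function(strata) {
  stopifnot(length(strata) >= 2L)
  ok <- vapply(strata, function(t) {
    all(dim(t) == c(2L, 2L)) && all(t >= 0) &&
      all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, logical(1))
  if (!any(ok)) return(list(common_or = NA_real_, p = NA_real_))
  arr <- array(unlist(lapply(strata[ok], function(t) t(t))),
               dim = c(2, 2, sum(ok)))
  # array is filled column-major; transpose each stratum so arr[i,j,k]
  # matches strata[[k]][i,j]
  arr <- aperm(arr, c(2, 1, 3))
  mh <- stats::mantelhaen.test(arr, correct = TRUE)
  list(common_or = unname(mh$estimate), p = mh$p.value)
}

#' Histogram of between-replicate transcriptional changes
#'
#' For each condition with at least two replicates, computes per-feature
#' log2 ratios between all replicate pairs after size-factor normalization,
#' as a diagnostic of normalization quality: an adequate normalization
#' centers the histogram at zero.
#'
#' @param m Count matrix, features x samples.
#' @param conditions Condition label per sample.
#' @param size_factors Per-sample factors (default [rle_size_factors]).
#' @param pseudocount Added to normalized counts before the ratio
#'   (default 0.5).
#' @param breaks Passed to [graphics::hist] binning via [base::cut]; a
#'   single number of bins or a vector of break points (default 81 bins over
#'   +/- 4).
#' @return Named list (one element per eligible condition) of `data.frame`s
#'   with `mid` (bin midpoint) and `count`; conditions with a single
#'   replicate are skipped with a message.
#' @export
replicate_change_histogram <- function(m, conditions, size_factors = NULL,
                                       pseudocount = 0.5,
                                       breaks = seq(-4, 4, length.out = 82)) {
  m <- as.matrix(m)
  conditions <- as.character(conditions)
  if (is.null(size_factors)) size_factors <- rle_size_factors(m)
  q <- sweep(m, 2, size_factors, "/")
  out <- list()
  for (cond in unique(conditions)) {
    idx <- which(conditions == cond)
    if (length(idx) < 2L) {
      message("condition '", cond, "' has a single replicate; histogram skipped")
      next
    }
    pairs <- utils::combn(idx, 2)
    lr <- unlist(lapply(seq_len(ncol(pairs)), function(k) {
      log2((q[, pairs[1, k]] + pseudocount) / (q[, pairs[2, k]] + pseudocount))
    }), use.names = FALSE)
    lr <- pmin(pmax(lr, min(breaks)), max(breaks))
    h <- graphics::hist(lr, breaks = breaks, plot = FALSE)
    out[[cond]] <- data.frame(mid = h$mids, count = h$counts)
  }
  out
}
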