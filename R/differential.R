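#' Median-of-ratios size factors
#'
#' Computes per-sample size factors as the median, over peaks with strictly
#' positive counts in every sample, of the ratio of each count to the
#' peak's geometric mean across samples.  Factors are not rescaled
#' afterwards.
#'
#' @param counts non-negative integer matrix, peaks by samples.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  stop_if(any(counts < 0), "counts must be non-negative")
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  stop_if(!any(pos),
          paste("no peak has positive counts in every sample;",
                "consider adding a pseudo-count"))
  lc <- log(counts[pos, , drop = FALSE])
  log_geo <- rowMeans(lc)
  s <- apply(lc, 2, function(col) exp(median(col - log_geo)))
  stats::setNames(s, colnames(counts))
}

#' Estimate per-peak negative-binomial dispersions
#'
#' Method-of-moments estimates on normalized counts,
#' `alpha_raw = max(0, (var - mean) / mean^2)`, shrunk toward a fitted
#' mean-dispersion trend `alpha_tr(mu) = a0 + a1/mu` by weighted averaging
#' in log space (weight `w` on the trend).  When `group` is supplied the
#' variance is the pooled within-group (residual) variance, so condition
#' differences do not inflate the dispersion.
#'
#' All-zero peaks have no defined dispersion and are returned as `NA`;
#' callers must exclude them from testing.
#'
#' @param counts non-negative integer matrix, peaks by samples.
#' @param s per-sample size factors.
#' @param group optional factor of sample conditions for residual-based
#'   variance estimation.
#' @param w shrinkage weight on the trend, in `[0, 1]`.
#' @return numeric vector of shrunk dispersions (NA for all-zero peaks),
#'   with the raw estimates in attribute `"raw"` and the trend coefficients
#'   in attribute `"trend"`.
#' @export
estimate_dispersions <- function(counts, s, group = NULL, w = 0.5) {
  stop_if(ncol(counts) < 2, "dispersion estimation needs >= 2 samples")
  q <- sweep(counts, 2, s, "/")
  m <- rowMeans(q)
  if (is.null(group)) {
    v <- apply(q, 1, var)
  } else {
    group <- as.factor(group)
    stop_if(length(group) != ncol(counts),
            "group must have one entry per sample")
    resid2 <- q
    for (g in levels(group)) {
      idx <- group == g
      resid2[, idx] <- (q[, idx, drop = FALSE] -
                          rowMeans(q[, idx, drop = FALSE]))^2
    }
    df <- ncol(counts) - nlevels(group)
    stop_if(df < 1, "need replication within groups to estimate dispersion")
    v <- rowSums(resid2) / df
  }
  zero <- m == 0
  raw <- pmax(0, (v - m) / m^2)
  raw[zero] <- NA_real_

  # mean-dispersion trend a0 + a1/mu fitted on peaks with informative raw
  # estimates; coefficients clamped to be non-negative
  use <- !zero & raw > 0 & is.finite(raw)
  if (sum(use) >= 10) {
    fit <- tryCatch(lm(raw[use] ~ I(1 / m[use])), error = function(e) NULL)
    a <- if (is.null(fit)) c(mean(raw[use]), 0) else pmax(coef(fit), 0)
  } else {
    a <- c(mean(raw[use]) %||% 0.1, 0)
    if (!is.finite(a[1])) a[1] <- 0.1
  }
  trend <- pmax(a[1] + a[2] / m, 1e-8)

  # log-space shrinkage; raw estimates are floored at half the trend so the
  # geometric average stays defined for raw zeros and the few-replicate
  # noise in the raw estimate cannot drive the shrunk value far below the
  # trend (which would anti-conservatively inflate Wald statistics)
  floor_raw <- pmax(raw, trend / 2)
  shrunk <- exp((1 - w) * log(floor_raw) + w * log(trend))
  shrunk[zero] <- NA_real_
  attr(shrunk, "raw") <- raw
  attr(shrunk, "trend") <- c(a0 = a[1], a1 = a[2])
  shrunk
}

# NB log-likelihood pieces for one peak (log link, fixed alpha)
nb_loglik_eta <- function(y, eta, alpha) {
  mu <- exp(eta)
  if (alpha < 1e-12) return(sum(y * eta - mu))
  sum(y * log(mu / (mu + 1 / alpha)) - (1 / alpha) * log1p(alpha * mu))
}

#' Negative-binomial Wald test for one two-condition comparison
#'
#' Fits, per peak, the NB generalized linear model with log link, design
#' `intercept + condition indicator` and log size factors as offsets, by
#' iteratively reweighted least squares at fixed dispersion.  The reported
#' standard error comes from the observed-information Hessian at the MLE
#' (the curvature of the profile likelihood); the Wald `z = log2FC / se`
#' gets a two-sided normal p-value.
#'
#' @param counts matrix of the samples involved (peaks by samples).
#' @param s per-sample size factors.
#' @param alpha per-peak dispersions (`NA` entries are skipped and flagged).
#' @param condition logical or 0/1 vector: TRUE/1 for the later day.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return data frame: peak_id, baseMean (mean of normalized counts),
#'   log2FC (positive = higher at the later day), se, wald_p, converged.
#' @export
nb_wald_test <- function(counts, s, alpha, condition, max_iter = 50,
                         tol = 1e-8) {
  condition <- as.numeric(condition)
  stop_if(!all(condition %in% c(0, 1)), "condition must be binary")
  stop_if(length(unique(condition)) != 2,
          "both conditions need at least one sample")
  X <- cbind(1, condition)
  off <- log(s)
  n_peaks <- nrow(counts)
  out <- data.frame(peak_id = rownames(counts) %||% seq_len(n_peaks),
                    baseMean = rowMeans(sweep(counts, 2, s, "/")),
                    log2FC = NA_real_, se = NA_real_, wald_p = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  cap <- 15  # |log fold-change| bound guarding separation at zero groups
  for (i in seq_len(n_peaks)) {
    a <- alpha[i]
    if (is.na(a)) next
    y <- counts[i, ]
    q <- y / s
    m0 <- mean(q[condition == 0])
    m1 <- mean(q[condition == 1])
    beta <- c(log(pmax(m0, 1e-8)),
              max(-cap, min(cap, log(pmax(m1, 1e-8) / pmax(m0, 1e-8)))))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta) + off
      mu <- exp(eta)
      W <- mu / (1 + a * mu)                     # expected information
      z <- (y - mu) / mu
      XtW <- t(X * W)
      upd <- tryCatch(solve(XtW %*% X, XtW %*% (drop(X %*% beta) + z)),
                      error = function(e) NULL)
      if (is.null(upd)) break
      new_beta <- drop(upd)
      new_beta[2] <- max(-cap, min(cap, new_beta[2]))
      delta <- max(abs(new_beta - beta))
      beta <- new_beta
      if (delta < tol) { ok <- TRUE; break }
    }
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    Wobs <- mu * (1 + a * y) / (1 + a * mu)^2    # observed information
    H <- t(X * Wobs) %*% X
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov) || !ok) {
      out$log2FC[i] <- beta[2] / log(2)
      out$se[i] <- NA_real_
      out$wald_p[i] <- 1
      next
    }
    se <- sqrt(cov[2, 2])
    out$log2FC[i] <- beta[2] / log(2)
    out$se[i] <- se / log(2)
    out$wald_p[i] <- if (se == 0 && beta[2] == 0) 1 else
      2 * pnorm(-abs(beta[2] / se))
    out$converged[i] <- TRUE
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] with
#' input validation).
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1 and monotone in rank.
#' @export
bh_adjust <- function(pvals) {
  stop_if(any(pvals < 0 | pvals > 1, na.rm = TRUE),
          "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Differential accessibility between consecutive timepoints
#'
#' For each requested day pair, subsets the count matrix to the samples of
#' the two days, normalizes within the pair (median-of-ratios), estimates
#' dispersions from within-day replicate variability, runs the NB Wald test
#' and adjusts p-values within the pair (Benjamini-Hochberg).
#'
#' @param counts peak-by-sample count matrix spanning all timepoints.
#' @param samples sample sheet with columns sample_id, day, replicate,
#'   matching `colnames(counts)`.
#' @param pairs list of `c(day_a, day_b)` with `day_a < day_b`; default all
#'   consecutive pairs of the observed days.
#' @param padj_threshold significance cutoff on the adjusted p-value.
#' @param w dispersion-shrinkage weight (see [estimate_dispersions()]).
#' @return named list (one element per pair, `"day<a>_vs_day<b>"`) of data
#'   frames: peak_id, pair_a, pair_b, baseMean, log2FC, se, wald_p, padj,
#'   significant, direction (`up_later` / `up_earlier` / `ns`).
#' @export
consecutive_comparisons <- function(counts, samples, pairs = NULL,
                                    padj_threshold = 0.05, w = 0.5) {
  days <- sort(unique(samples$day))
  if (is.null(pairs)) {
    pairs <- Map(c, days[-length(days)], days[-1])
  }
  res <- list()
  for (pair in pairs) {
    stop_if(!all(pair %in% days),
            sprintf("pair (%s) references a missing day; available: %s",
                    paste(pair, collapse = ", "),
                    paste(days, collapse = ", ")))
    sel <- samples$day %in% pair
    sub <- counts[, samples$sample_id[sel], drop = FALSE]
    cond <- as.numeric(samples$day[sel] == pair[2])
    keep <- rowSums(sub) > 0
    s <- size_factors_median_of_ratios(sub[keep, , drop = FALSE])
    a <- estimate_dispersions(sub[keep, , drop = FALSE], s,
                              group = samples$day[sel], w = w)
    tab <- nb_wald_test(sub[keep, , drop = FALSE], s, a, cond)
    tab$padj <- bh_adjust(tab$wald_p)
    tab$significant <- !is.na(tab$padj) & tab$padj < padj_threshold
    tab$direction <- ifelse(!tab$significant, "ns",
                            ifelse(tab$log2FC > 0, "up_later", "up_earlier"))
    tab <- cbind(peak_id = tab$peak_id, pair_a = pair[1], pair_b = pair[2],
                 tab[, setdiff(names(tab), "peak_id")])
    res[[sprintf("day%g_vs_day%g", pair[1], pair[2])]] <- tab
  }
  res
}

#' Differential test between two days starting from intervals
#'
#' Implements the interval-level route of a consecutive-day comparison:
#' pool the two days' peak sets by merging overlapping peaks, count
#' fragments in the merged peaks for every involved sample, then normalize
#' and test.
#'
#' @param peaksets_by_day named list (names = days) of peak interval data
#'   frames.
#' @param fragments_by_sample named list of fragment interval data frames,
#'   names matching `samples$sample_id`.
#' @param samples sample sheet restricted to (or spanning) the two days.
#' @param pair `c(day_a, day_b)`.
#' @param ... passed to [consecutive_comparisons()].
#' @return the single-pair result data frame.
#' @export
compare_days_from_intervals <- function(peaksets_by_day, fragments_by_sample,
                                        samples, pair, ...) {
  stop_if(!all(as.character(pair) %in% names(peaksets_by_day)),
          "peak sets for both days are required")
  merged <- merge_intervals(peaksets_by_day[as.character(pair)])$merged
  sel <- samples$day %in% pair
  sub_samples <- samples[sel, , drop = FALSE]
  counts <- count_fragments(fragments_by_sample[sub_samples$sample_id],
                            merged)
  consecutive_comparisons(counts, sub_samples, pairs = list(pair), ...)[[1]]
}
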