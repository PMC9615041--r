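#' Two-proportion Z test
#'
#' `Z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with
#' `pbar = (k1 + k2) / (n1 + n2)`, no continuity correction; the two-sided
#' p-value comes from the standard normal distribution.  When the pooled
#' proportion is 0 or 1 the statistic is defined as 0 with p = 1.
#'
#' @param k1,n1 successes and size of the first population.
#' @param k2,n2 successes and size of the second population.
#' @return one-row data frame: k1, n1, k2, n2, p1, p2, pooled, Z, p.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stop_if(n1 < 1 || n2 < 1, "population sizes must be >= 1")
  stop_if(k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2,
          "counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
             pooled = pooled, Z = z, p = p)
}

#' Compare annotation-class composition of dynamic vs. remaining peaks
#'
#' Runs one two-proportion Z test per annotation class on each axis
#' (location: promoter-TSS / TES / exon / intergenic; transcript: mRNA /
#' tRNA / other), comparing the dynamic peak fraction (population 1)
#' against all other peaks (population 2).  Per-test significance at
#' `p <= alpha` with no multiple-testing correction by default; set
#' `adjust = TRUE` for an optional Benjamini-Hochberg column used for the
#' significance call instead.
#'
#' @param annotations peak annotation data frame (see [annotate_peaks()]).
#' @param dynamic_flags logical vector, one per annotation row.
#' @param alpha per-test significance level.
#' @param adjust apply Benjamini-Hochberg across the classes of each axis.
#' @return data frame: axis, class, k1, n1, k2, n2, p1, p2, Z, p,
#'   (padj when `adjust`), significant.
#' @export
compare_composition <- function(annotations, dynamic_flags, alpha = 0.05,
                                adjust = FALSE) {
  stop_if(length(dynamic_flags) != nrow(annotations),
          "one dynamic flag per annotated peak is required")
  n1 <- sum(dynamic_flags)
  n2 <- sum(!dynamic_flags)
  if (n1 == 0 || n2 == 0) {
    warning("one of the populations is empty; returning an empty table")
    return(data.frame(axis = character(), class = character(),
                      k1 = integer(), n1 = integer(), k2 = integer(),
                      n2 = integer(), p1 = numeric(), p2 = numeric(),
                      Z = numeric(), p = numeric(),
                      significant = logical()))
  }
  axes <- list(location = annotations$location_class,
               transcript = annotations$transcript_class)
  out <- list()
  for (axis in names(axes)) {
    values <- axes[[axis]]
    for (cls in sort(unique(values))) {
      k1 <- sum(values == cls & dynamic_flags)
      k2 <- sum(values == cls & !dynamic_flags)
      row <- two_proportion_z(k1, n1, k2, n2)
      out[[length(out) + 1]] <- cbind(axis = axis, class = cls,
                                      row[, c("k1", "n1", "k2", "n2",
                                              "p1", "p2", "Z", "p")])
    }
  }
  res <- do.call(rbind, out)
  if (adjust) {
    res$padj <- ave(res$p, res$axis, FUN = bh_adjust)
    res$significant <- res$padj <= alpha
  } else {
    res$significant <- res$p <= alpha
  }
  res
}
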