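# Shared fixtures built in code.

# the study's five assay days, duplicated libraries
study_times <- rep(c(0, 3, 7, 10, 28), each = 2)

# six temporal archetype mean shapes (log2 units, unit amplitude) at the
# five assay days: steps only at the 0->3 and 7->10 transitions
archetype_shapes <- rbind(c(0, 0.5, 0.5, 1, 1),
                          c(0, -0.5, -0.5, -1, -1),
                          c(0, 1, 1, 1, 1),
                          c(0, -1, -1, -1, -1),
                          c(0, 1, 1, 0, 0),
                          c(0, -1, -1, 0, 0))

# standardized noisy profile drawn around one archetype at a given
# signal-to-noise ratio (noise SD = shape SD / snr)
archetype_profile_y <- function(k, snr = 3, times = study_times) {
  mu <- archetype_shapes[k, rep(1:5, each = 2)]
  x <- mu + rnorm(length(times), 0, sd(mu) / snr + 1e-9)
  standardize_profile(x, times)$y
}

# tiny stranded gene table for annotation tests
toy_genes <- function() {
  data.frame(
    gene_id = c("GA", "GB", "GT"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(5000L, 20000L, 5000L),
    end = c(7000L, 22000L, 5300L),
    tss = c(5000L, 22000L, 5000L),
    tes = c(7000L, 20000L, 5300L),
    exon_starts = c("5000", "20000", "5000"),
    exon_ends = c("7000", "22000", "5300"),
    biotype = c("mRNA", "mRNA", "tRNA"),
    stringsAsFactors = FALSE)
}

make_intervals <- function(chrom, start, end, name = NULL) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             name = name %||% sprintf("iv_%d", seq_along(start)),
             strand = NA_character_, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force profile-likelihood oracle for the NB Wald test: dense grid
# over the group log-fold-change with inner maximization over the
# intercept, quadratic refinement at the optimum, curvature-based SE
nb_profile_oracle <- function(y, s, alpha, condition) {
  nb_ll <- function(b0, b2) {
    mu <- s * exp(b0 + b2 * condition)
    sum(y * log(mu / (mu + 1 / alpha)) - (1 / alpha) * log1p(alpha * mu))
  }
  prof <- function(b2) {
    optimize(function(b0) nb_ll(b0, b2), c(-5, 15), maximum = TRUE,
             tol = 1e-10)$objective
  }
  grid <- seq(-8, 8, by = 0.02)
  vals <- vapply(grid, prof, numeric(1))
  b2 <- grid[which.max(vals)]
  for (step in c(0.02, 0.002, 2e-4, 2e-5, 2e-6)) {
    repeat {
      cand <- b2 + step * c(-1, 0, 1)
      pick <- which.max(vapply(cand, prof, numeric(1)))
      if (pick == 2) break
      b2 <- cand[pick]
    }
  }
  h <- 1e-4
  curv <- (prof(b2 + h) - 2 * prof(b2) + prof(b2 - h)) / h^2
  list(log2FC = b2 / log(2), se = sqrt(-1 / curv) / log(2))
}
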