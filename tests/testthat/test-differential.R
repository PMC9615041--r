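test_that("median-of-ratios size factors match hand computation", {
  # identical columns -> unit factors
  m <- matrix(c(4, 9, 4, 9), 2)
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))
  # geometric means sqrt(200), sqrt(1800), sqrt(5000); ratio medians
  m <- matrix(c(10, 30, 50, 20, 60, 100), 3)
  expect_equal(unname(size_factors_median_of_ratios(m)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # single sample
  expect_equal(unname(size_factors_median_of_ratios(matrix(5:7, 3, 1))), 1)
  # no peak positive everywhere
  expect_error(size_factors_median_of_ratios(matrix(c(1, 0, 0, 1), 2)),
               "pseudo-count")
})

test_that("dispersion estimation recovers Poisson and NB generators", {
  withr::local_seed(21)
  n <- 200
  mu <- runif(400, 50, 500)
  pois <- t(vapply(mu, function(m) rpois(n, m), numeric(n)))
  a_pois <- estimate_dispersions(pois, rep(1, n))
  expect_lte(median(a_pois, na.rm = TRUE), 0.05)

  nb <- t(vapply(mu, function(m) rnbinom(n, mu = m, size = 5), numeric(n)))
  a_nb <- estimate_dispersions(nb, rep(1, n))
  expect_gte(median(a_nb, na.rm = TRUE), 0.1)
  expect_lte(median(a_nb, na.rm = TRUE), 0.4)

  # var < mean -> raw truncated at zero
  m <- rbind(c(10, 10, 10, 11), c(100, 1, 200, 5))
  raw <- attr(estimate_dispersions(m, rep(1, 4)), "raw")
  expect_equal(raw[1], 0)
  # all-zero peaks flagged NA
  m0 <- rbind(c(0, 0, 0, 0), c(5, 6, 7, 8))
  expect_true(is.na(estimate_dispersions(m0, rep(1, 4))[1]))
})

test_that("the NB Wald test is exact under symmetry and invariant to scaling", {
  counts <- rbind(c(10L, 20L, 10L, 20L), c(7L, 7L, 7L, 7L))
  rownames(counts) <- c("a", "b")
  cond <- c(0, 0, 1, 1)
  res <- nb_wald_test(counts, rep(1, 4), c(0.1, 0.1), cond)
  expect_equal(res$log2FC, c(0, 0), tolerance = 1e-9)
  expect_equal(res$wald_p, c(1, 1), tolerance = 1e-9)

  # doubling day_b counts together with its size factors leaves the
  # normalized group means equal, so the fold-change stays exactly zero
  doubled <- rbind(c(10L, 20L, 20L, 40L))
  rownames(doubled) <- "a"
  res2 <- nb_wald_test(doubled, c(1, 1, 2, 2), 0.1, cond)
  expect_equal(res2$log2FC, 0, tolerance = 1e-9)
  expect_equal(res2$wald_p, 1, tolerance = 1e-9)
})

test_that("Wald estimates match a brute-force profile-likelihood oracle", {
  withr::local_seed(31)
  cond <- c(0, 0, 0, 1, 1, 1)
  s <- c(0.9, 1, 1.2, 0.8, 1.1, 1)
  for (i in 1:50) {
    alpha <- runif(1, 0.01, 0.3)
    mu <- runif(1, 30, 300)
    lfc <- rnorm(1, 0, 1)
    y <- rnbinom(6, mu = s * mu * 2^(lfc * cond), size = 1 / alpha)
    if (sum(y[cond == 0]) == 0 || sum(y[cond == 1]) == 0) next
    m <- matrix(y, 1, dimnames = list("pk", NULL))
    fit <- nb_wald_test(m, s, alpha, cond)
    oracle <- nb_profile_oracle(y, s, alpha, cond)
    expect_equal(fit$log2FC, oracle$log2FC, tolerance = 1e-3)
    expect_equal(fit$se, oracle$se, tolerance = 1e-3)
  }
})

test_that("swapping the two days negates log2FC and preserves p", {
  withr::local_seed(41)
  cond <- c(0, 0, 1, 1)
  y <- matrix(rnbinom(40, mu = 100, size = 10), 10)
  rownames(y) <- paste0("p", 1:10)
  a <- nb_wald_test(y, rep(1, 4), rep(0.1, 10), cond)
  b <- nb_wald_test(y, rep(1, 4), rep(0.1, 10), 1 - cond)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-6)
  expect_equal(a$wald_p, b$wald_p, tolerance = 1e-6)
})

test_that("bh_adjust reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_error(bh_adjust(c(0.1, 1.7)), "\\[0, 1\\]")
})

test_that("consecutive comparisons validate days and respect the null", {
  st <- simulate_study(simulation_config(n_peaks = 50, seed = 51))
  expect_error(consecutive_comparisons(st$counts, st$samples,
                                       pairs = list(c(0, 5))),
               "available")
  # identical replicate columns copied across both days -> nothing significant
  counts <- st$counts[, st$samples$day %in% c(0, 3)]
  counts[, 3:4] <- counts[, 1:2]
  samples <- st$samples[st$samples$day %in% c(0, 3), ]
  res <- consecutive_comparisons(counts, samples, pairs = list(c(0, 3)))
  expect_equal(sum(res[[1]]$significant), 0)
})

test_that("injected effects are recovered and the null pairs stay quiet", {
  st <- simulate_study(simulation_config(n_peaks = 800, seed = 61))
  res <- consecutive_comparisons(st$counts, st$samples)
  wave <- summarize_wave(res)
  expect_equal(wave$n_sig, wave$n_up + wave$n_down)
  on_wave <- wave$pair %in% c("day0_vs_day3", "day7_vs_day10")
  expect_gt(sum(wave$n_sig[on_wave]), 0)
  expect_lte(sum(wave$n_sig[!on_wave]),
             1.5 * 0.05 * 800 + 1)  # FDR-calibrated null pairs
  # significant calls point in the true direction
  d03 <- res[["day0_vs_day3"]]
  truth <- st$truth$lfc_0_3[match(d03$peak_id, st$truth$peak_id)]
  sig <- d03$significant
  expect_true(all(sign(d03$log2FC[sig]) == sign(truth[sig])))
})

test_that("the interval route (merge, count, test) runs end to end", {
  withr::local_seed(71)
  # two days x two replicates of fragments over two true peaks; day-3
  # samples get 4x fragments in peak B
  peak_a <- c(1000, 1600); peak_b <- c(5000, 5600)
  mk_frags <- function(n_a, n_b) {
    s <- c(sample(peak_a[1]:(peak_a[2] - 150), n_a, TRUE),
           sample(peak_b[1]:(peak_b[2] - 150), n_b, TRUE))
    make_intervals("chr1", s, s + 150)
  }
  frags <- list(d0_r1 = mk_frags(300, 100), d0_r2 = mk_frags(310, 90),
                d3_r1 = mk_frags(295, 400), d3_r2 = mk_frags(305, 410))
  peaksets <- list(
    "0" = make_intervals("chr1", c(peak_a[1], peak_b[1]),
                         c(peak_a[2], peak_b[2]), name = c("a0", "b0")),
    "3" = make_intervals("chr1", c(peak_a[1] - 50, peak_b[1] + 50),
                         c(peak_a[2] - 50, peak_b[2] + 50),
                         name = c("a3", "b3")))
  samples <- data.frame(sample_id = names(frags), day = c(0, 0, 3, 3),
                        replicate = c(1, 2, 1, 2))
  res <- compare_days_from_intervals(peaksets, frags, samples, c(0, 3))
  expect_equal(nrow(res), 2)
  b_row <- which.max(res$log2FC)
  expect_gt(res$log2FC[b_row], 1)      # ~4x / libsize shift
  expect_true(res$significant[b_row])
})

test_that("the reimplementation tracks an independent NB engine", {
  st <- simulate_study(simulation_config(n_peaks = 300, seed = 77))
  sel <- st$samples$day %in% c(0, 3)
  sub <- st$counts[, st$samples$sample_id[sel]]
  # size factors: same median-of-ratios definition, bitwise agreement
  expect_equal(unname(size_factors_median_of_ratios(sub)),
               unname(DESeq2::estimateSizeFactorsForMatrix(sub)),
               tolerance = 1e-12)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    sub, data.frame(day = factor(st$samples$day[sel])), ~ day)
  r <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  mine <- consecutive_comparisons(sub, st$samples[sel, ],
                                  pairs = list(c(0, 3)))[[1]]
  m <- match(mine$peak_id, rownames(r))
  expect_gt(cor(mine$log2FC, r$log2FoldChange[m]), 0.999)
  # same peaks called significant despite the different dispersion scheme
  expect_equal(mine$significant, r$padj[m] < 0.05)
})
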