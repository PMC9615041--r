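test_that("profile standardization centers, scales, and flags degeneracy", {
  p <- standardize_profile(c(1, 2, 3, 4), c(0, 3, 7, 10))
  expect_equal(sum(p$y), 0, tolerance = 1e-12)
  expect_equal(mean(p$y^2), 1, tolerance = 1e-12)
  # population-SD convention: divisor n, giving sqrt(5/4) here
  expect_equal(p$y, (c(1, 2, 3, 4) - 2.5) / sqrt(5 / 4))
  expect_false(p$constant)

  const <- standardize_profile(c(5, 5, 5, 5), c(0, 3, 7, 10))
  expect_true(const$constant)
  expect_equal(const$y, rep(0, 4))

  expect_error(standardize_profile(c(1, 2, 3), c(0, 3, 7)), "at least 4")
})

test_that("gp_loglik matches closed forms and a dense-solve oracle", {
  # n = 1, pure unit white noise at y = 0
  expect_equal(gp_loglik(0, 0, 0, 1, 1), -0.5 * log(2 * pi))
  # sigma_f2 = 0 equals the white-noise closed form
  y <- c(0.3, -1, 0.7, 0)
  t4 <- c(0, 3, 7, 10)
  sn2 <- 0.8
  expect_equal(gp_loglik(y, t4, 0, 5, sn2),
               sum(log(exp(-y^2 / (2 * sn2)) / sqrt(2 * pi * sn2))))
  # random instances vs explicit inverse/determinant
  withr::local_seed(5)
  for (i in 1:25) {
    n <- 6
    times <- sort(runif(n, 0, 28))
    yy <- rnorm(n)
    sf2 <- runif(1, 0.1, 3); ell <- runif(1, 1, 20); s2 <- runif(1, 0.1, 2)
    C <- sf2 * exp(-0.5 * outer(times, times, `-`)^2 / ell^2) + diag(s2, n)
    oracle <- -0.5 * drop(t(yy) %*% solve(C) %*% yy) -
      0.5 * log(det(C)) - 0.5 * n * log(2 * pi)
    expect_equal(gp_loglik(yy, times, sf2, ell, s2), oracle,
                 tolerance = 1e-8)
  }
})

test_that("the static fit equals its closed form and a numeric optimizer", {
  p <- standardize_profile(rnorm(10), study_times)
  fit <- fit_static(p)
  expect_equal(fit$loglik, -5 * (1 + log(2 * pi)))
  # unstandardized profile: sigma2_hat free
  p2 <- list(y = c(1, -1))
  fit2 <- fit_static(p2)
  expect_equal(fit2$params$sigma_n2, 1)
  expect_equal(fit2$loglik, -(1 + log(2 * pi)))
  # numeric maximization of the white-noise likelihood agrees
  p3 <- list(y = c(0.2, -0.9, 1.4, -0.1))
  opt <- optimize(function(s2) {
    sum(log(exp(-p3$y^2 / (2 * s2)) / sqrt(2 * pi * s2)))
  }, c(1e-4, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(fit_static(p3)$loglik, opt$objective, tolerance = 1e-6)
})

test_that("the dynamic fit is seeded-deterministic and respects nesting", {
  withr::local_seed(9)
  p <- standardize_profile(rnorm(10), study_times)
  f1 <- fit_rbf_white(p, seed = 4)
  f2 <- fit_rbf_white(p, seed = 4)
  expect_identical(f1, f2)
  # nesting: dynamic loglik never below static
  for (i in 1:20) {
    pp <- standardize_profile(rnorm(10), study_times)
    expect_gte(fit_rbf_white(pp, seed = i)$loglik, fit_static(pp)$loglik)
  }
})

test_that("the LR test separates smooth signals from white noise", {
  withr::local_seed(12)
  n_prof <- 120
  # under the null, the dynamic fit rarely improves much on the static fit
  null_gain <- vapply(seq_len(n_prof), function(i) {
    p <- standardize_profile(rnorm(10), study_times)
    fit_rbf_white(p, seed = i)$loglik - fit_static(p)$loglik
  }, numeric(1))
  expect_gte(mean(null_gain <= 0.5), 0.75)
  # under a smooth RBF draw the gain is large
  times_u <- c(0, 3, 7, 10, 28)
  K <- 1 * exp(-0.5 * outer(times_u, times_u, `-`)^2 / 25)
  L <- chol(K + diag(1e-8, 5))
  alt_gain <- vapply(seq_len(n_prof), function(i) {
    f <- drop(rnorm(5) %*% L)
    x <- f[rep(1:5, each = 2)] + rnorm(10, 0, sqrt(0.05))
    p <- standardize_profile(x, study_times)
    fit_rbf_white(p, seed = i)$loglik - fit_static(p)$loglik
  }, numeric(1))
  expect_gte(mean(alt_gain > 2), 0.9)
})

test_that("lr_test applies the chi-square convention and thresholds", {
  mk <- function(ll) structure(list(loglik = ll), class = "gp_fit")
  r <- lr_test(mk(-10), mk(-10))
  expect_equal(r$LR, 0)
  expect_equal(r$chi2_p, 1)
  expect_false(r$dynamic_strict || r$dynamic_loose)
  # -LR at the 5% chi-square(1) critical value
  r <- lr_test(mk(-10 + 3.841 / 2), mk(-10))
  expect_equal(r$chi2_p, 0.05, tolerance = 1e-3)
  expect_true(r$dynamic_loose)
  # loose but not strict
  r <- lr_test(mk(-10 + 0.15), mk(-10))
  expect_equal(r$LR, -0.3)
  expect_equal(r$chi2_p, pchisq(0.3, 1, lower.tail = FALSE))
  expect_true(r$dynamic_loose)
  expect_false(r$dynamic_strict)
  # strict implies loose
  r <- lr_test(mk(-10 + 10), mk(-10))
  expect_true(r$dynamic_strict && r$dynamic_loose)
})

test_that("archetype profiles are flagged dynamic at moderate noise", {
  withr::local_seed(33)
  flags <- vapply(1:60, function(i) {
    y <- archetype_profile_y(((i - 1) %% 6) + 1, snr = 3)
    p <- list(peak_id = "x", times = study_times, y = y, constant = FALSE)
    class(p) <- "tc_profile"
    dyn <- fit_rbf_white(p, seed = i)
    lr_test(dyn, fit_static(p))$dynamic_loose
  }, logical(1))
  expect_gte(mean(flags), 0.8)
})

test_that("test_dynamics handles constant peaks and returns one row each", {
  st <- simulate_study(simulation_config(n_peaks = 25, seed = 3))
  counts <- st$counts
  counts[1, ] <- 50L  # constant profile
  dyn <- test_dynamics(counts, st$samples, size_factors = rep(1, 10),
                       n_starts = 4, seed = 1)
  expect_equal(nrow(dyn), 25)
  expect_true(dyn$constant[1])
  expect_false(dyn$dynamic_loose[1])
  expect_true(all(dyn$LR <= 1e-6))
})
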