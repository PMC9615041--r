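# Mixture of hierarchical Gaussian processes for temporal profiles.
#
# Model: cluster k has a latent mean function g_k ~ GP(0, K_f) (RBF);
# a profile assigned to k is y_i = g_k(t) + e_i with e_i ~ GP(0, K_y),
# K_y = within-cluster RBF + white noise.  EM alternates
#   E: r_ik  propto  pi_k N(y_i; m_k, V_k + K_y)
#   M: pi_k = sum_i r_ik / N;  (m_k, V_k) by responsibility-weighted GP
#      regression:  V_k = (K_f^-1 + R_k K_y^-1)^-1,
#                    m_k = V_k K_y^-1 sum_i r_ik y_i
# with the five kernel hyperparameters refreshed every few iterations by
# bounded optimization of the observed-data mixture log likelihood.

gpmix_kernels <- function(times, theta) {
  d2 <- outer(times, times, `-`)^2
  K_f <- theta[["sf2"]] * exp(-0.5 * d2 / theta[["lf"]]^2)
  K_y <- theta[["sw2"]] * exp(-0.5 * d2 / theta[["lw"]]^2) +
    diag(theta[["sn2"]], length(times))
  list(K_f = K_f, K_y = K_y)
}

# log N(y_i; m, S) for every row of Y at once
gpmix_mvn_loglik <- function(Y, m, S) {
  L <- chol(S + diag(1e-10, ncol(Y)))
  B <- backsolve(L, t(Y) - m, transpose = TRUE)
  -0.5 * colSums(B^2) - sum(log(diag(L))) - 0.5 * ncol(Y) * log(2 * pi)
}

# one M-step + E-step given responsibilities; returns state and loglik
gpmix_step <- function(Y, r, kern, weights_floor = 1e-10) {
  N <- nrow(Y); n <- ncol(Y); K <- ncol(r)
  Kf_inv <- chol2inv(chol(kern$K_f + diag(1e-8, n)))
  Ky_inv <- chol2inv(chol(kern$K_y))
  pi_k <- pmax(colSums(r) / N, weights_floor)
  pi_k <- pi_k / sum(pi_k)
  m <- matrix(0, K, n); V <- vector("list", K)
  logp <- matrix(0, N, K)
  for (k in seq_len(K)) {
    R_k <- sum(r[, k])
    V[[k]] <- chol2inv(chol(Kf_inv + R_k * Ky_inv))
    m[k, ] <- drop(V[[k]] %*% (Ky_inv %*% colSums(r[, k] * Y)))
    logp[, k] <- log(pi_k[k]) + gpmix_mvn_loglik(Y, m[k, ],
                                                 V[[k]] + kern$K_y)
  }
  mx <- apply(logp, 1, max)
  lse <- mx + log(rowSums(exp(logp - mx)))
  r_new <- exp(logp - lse)
  list(r = r_new, pi_k = pi_k, m = m, V = V, loglik = sum(lse))
}

theta_default <- c(sf2 = 1, lf = 8, sw2 = 0.1, lw = 8, sn2 = 0.3)
theta_lower <- c(sf2 = 1e-6, lf = 1, sw2 = 1e-6, lw = 1, sn2 = 1e-4)
theta_upper <- c(sf2 = 10, lf = 56, sw2 = 10, lw = 56, sn2 = 10)

#' Cluster dynamic profiles with a mixture of hierarchical GPs
#'
#' Fits, by EM, a truncated finite mixture in which each component is a
#' hierarchical Gaussian process: an RBF-kernel cluster mean function plus
#' a within-cluster GP-plus-noise deviation.  Kernel hyperparameters are
#' refreshed every `hyper_every` iterations by bounded optimization of the
#' mixture log likelihood; the best of `n_restarts` seeded restarts is
#' kept; components whose total responsibility falls below `min_occupancy`
#' are pruned.  Cluster labels are arbitrary (compare partitions with an
#' adjusted Rand index, not label by label).
#'
#' @param profiles list of `tc_profile` objects sharing one time vector,
#'   or a numeric matrix (profiles by observations) plus `times`.
#' @param times observation days (required when `profiles` is a matrix).
#' @param K_max maximum number of mixture components.
#' @param min_occupancy minimum total responsibility for a component to
#'   count as non-empty.
#' @param n_restarts number of EM restarts.
#' @param seed seed controlling restarts and initialization.
#' @param max_iter,tol EM iteration cap and lower-bound tolerance.
#' @param hyper_every refresh the kernel hyperparameters every this many
#'   iterations.
#' @param grid_length number of grid points for posterior mean curves.
#' @return list of class `gp_mixture` with elements `model` (weights,
#'   means, posterior covariances, hyperparameters theta, times, `curves`:
#'   per-cluster posterior mean and SD on a dense day grid, loglik) and
#'   `result` (assignments data frame: peak_id, cluster, responsibility;
#'   n_nonempty).
#' @export
fit_gp_mixture <- function(profiles, times = NULL, K_max = 12,
                           min_occupancy = 1.0, n_restarts = 5, seed = 1,
                           max_iter = 100, tol = 1e-4, hyper_every = 5,
                           grid_length = 101) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      inherits(profiles[[1]], "tc_profile")) {
    times <- profiles[[1]]$times
    ids <- vapply(profiles, function(p) as.character(p$peak_id), "")
    Y <- do.call(rbind, lapply(profiles, function(p) {
      stop_if(!isTRUE(all.equal(p$times, times)),
              "all profiles must share one time vector")
      p$y
    }))
  } else {
    Y <- as.matrix(profiles)
    stop_if(is.null(times), "times must be given with a profile matrix")
    ids <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  }
  N <- nrow(Y)
  n_distinct <- nrow(unique(Y))
  if (N < K_max) {
    warning(sprintf("only %d profiles; reducing K_max from %d", N, K_max))
  }
  K <- max(1L, min(K_max, N, n_distinct))

  run_em <- function(restart_seed) {
    km <- with_seed(restart_seed, {
      if (K == 1) list(cluster = rep(1L, N)) else
        kmeans(Y, centers = K, nstart = 1, iter.max = 30)
    })
    r <- matrix(1e-6, N, K)
    r[cbind(seq_len(N), km$cluster)] <- 1
    r <- r / rowSums(r)
    theta <- theta_default
    kern <- gpmix_kernels(times, theta)
    prev <- -Inf
    st <- NULL
    for (it in seq_len(max_iter)) {
      st <- gpmix_step(Y, r, kern)
      r <- st$r
      if (it %% hyper_every == 0) {
        obj <- function(lpar) {
          th <- exp(lpar); names(th) <- names(theta_default)
          -gpmix_step(Y, r, gpmix_kernels(times, th))$loglik
        }
        opt <- tryCatch(optim(log(theta), obj, method = "L-BFGS-B",
                              lower = log(theta_lower),
                              upper = log(theta_upper),
                              control = list(maxit = 15)),
                        error = function(e) NULL)
        if (!is.null(opt) && -opt$value >= st$loglik) {
          theta <- exp(opt$par); names(theta) <- names(theta_default)
          kern <- gpmix_kernels(times, theta)
          st <- gpmix_step(Y, r, kern)
          r <- st$r
        }
        prev <- -Inf  # objective re-based after a hyperparameter update
      }
      if (abs(st$loglik - prev) < tol) break
      prev <- st$loglik
    }
    list(state = st, theta = theta, kern = kern, r = r)
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- run_em(seed + 1000L * rs)
    if (is.null(best) || fit$state$loglik > best$state$loglik) best <- fit
  }

  # Agglomerative merge phase: a truncated mixture happily splits one
  # temporal behaviour across several components; greedily merge any pair
  # whose merged model costs less than the BIC price of the extra
  # component (one mean curve + one weight).
  penalty <- 0.5 * (ncol(Y) + 1) * log(N)
  st <- best$state
  repeat {
    K_cur <- ncol(st$r)
    if (K_cur <= 1) break
    best_merge <- NULL
    for (k in seq_len(K_cur - 1)) {
      for (l in seq((k + 1), K_cur)) {
        r2 <- st$r[, -l, drop = FALSE]
        r2[, k] <- st$r[, k] + st$r[, l]
        st2 <- gpmix_step(Y, r2, best$kern)
        for (em in 1:2) st2 <- gpmix_step(Y, st2$r, best$kern)
        if (is.null(best_merge) || st2$loglik > best_merge$loglik) {
          best_merge <- st2
        }
      }
    }
    if (!is.null(best_merge) &&
        st$loglik - best_merge$loglik < penalty) {
      st <- best_merge
    } else break
  }
  occupancy <- colSums(st$r)
  keep <- occupancy >= min_occupancy
  if (!any(keep)) keep[which.max(occupancy)] <- TRUE
  if (!all(keep)) {
    r <- st$r[, keep, drop = FALSE]
    r <- r / rowSums(r)
    st <- gpmix_step(Y, r, best$kern)
  }
  K_final <- ncol(st$r)
  occupancy <- colSums(st$r)

  grid <- seq(min(times), max(times), length.out = grid_length)
  d2_gt <- outer(grid, times, `-`)^2
  d2_gg <- outer(grid, grid, `-`)^2
  th <- best$theta
  Kf_gt <- th[["sf2"]] * exp(-0.5 * d2_gt / th[["lf"]]^2)
  Kf_gg <- th[["sf2"]] * exp(-0.5 * d2_gg / th[["lf"]]^2)
  Kf <- best$kern$K_f
  curves <- do.call(rbind, lapply(seq_len(K_final), function(k) {
    R_k <- occupancy[k]
    ybar <- colSums(st$r[, k] * Y) / R_k
    A <- Kf + best$kern$K_y / R_k + diag(1e-8, length(times))
    W <- Kf_gt %*% solve(A)
    mean_g <- drop(W %*% ybar)
    var_g <- pmax(diag(Kf_gg - W %*% t(Kf_gt)), 0)
    data.frame(cluster = k, t = grid, mean = mean_g, sd = sqrt(var_g))
  }))

  assignments <- data.frame(
    peak_id = ids,
    cluster = max.col(st$r),
    responsibility = st$r[cbind(seq_len(N), max.col(st$r))],
    stringsAsFactors = FALSE)
  structure(list(
    model = list(weights = st$pi_k, means = st$m, post_cov = st$V,
                 theta = best$theta, times = times, curves = curves,
                 loglik = st$loglik, responsibilities = st$r),
    result = list(assignments = assignments,
                  n_nonempty = sum(occupancy >= min_occupancy),
                  occupancy = occupancy)),
    class = "gp_mixture")
}

#' Summarize a fitted GP mixture
#'
#' @param fit a `gp_mixture` from [fit_gp_mixture()].
#' @return data frame with one row per retained cluster: cluster, size
#'   (hard assignments; sizes sum to the number of clustered profiles),
#'   occupancy (total responsibility), and the posterior mean curve
#'   evaluated at each observed day (`mean_day<d>` columns).
#' @export
cluster_summary <- function(fit) {
  stopifnot(inherits(fit, "gp_mixture"))
  asg <- fit$result$assignments
  K <- length(fit$model$weights)
  days <- sort(unique(fit$model$times))
  curves <- fit$model$curves
  rows <- lapply(seq_len(K), function(k) {
    ck <- curves[curves$cluster == k, ]
    at_days <- vapply(days, function(d) {
      ck$mean[which.min(abs(ck$t - d))]
    }, numeric(1))
    row <- data.frame(cluster = k, size = sum(asg$cluster == k),
                      occupancy = fit$result$occupancy[k])
    for (j in seq_along(days)) {
      row[[sprintf("mean_day%g", days[j])]] <- at_days[j]
    }
    row
  })
  do.call(rbind, rows)
}
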