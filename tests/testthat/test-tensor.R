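# Variational Bayesian CP core: conjugate updates, ELBO, ARD pruning,
# prediction, and agreement with independent oracles.

test_that("init_state honours shapes, determinism and the overcomplete start", {
  g <- gen_cp_tensor(c(20, 20, 3), 2, 100, 0, seed = 1)
  cfg <- cp_prior_config(R_init = 10, seed = 1)
  expect_warning(st <- init_state(g$tensor, cfg), "overcomplete|exceeds")
  expect_equal(vapply(st$means, dim, integer(2)),
               matrix(c(20L, 10L, 20L, 10L, 3L, 10L), 2))
  st2 <- suppressWarnings(init_state(g$tensor, cfg))
  expect_identical(st, st2)

  empty <- observed_tensor(array(NA_real_, c(2, 2, 2)),
                           array(FALSE, c(2, 2, 2)))
  expect_error(init_state(empty, cfg), "no observed")
})

test_that("a row with no observed entries reverts to its prior", {
  g <- gen_cp_tensor(c(6, 6, 3), 2, 100, 0, seed = 2)
  mask <- g$tensor$mask
  mask[3, , ] <- FALSE                       # row 3 of mode 1 fully missing
  tens <- observed_tensor(g$tensor$values, mask)
  cfg <- cp_prior_config(R_init = 3, seed = 2)
  st <- init_state(tens, cfg)
  st <- update_lambda(st, cfg)               # make E[Lambda] well-defined
  st <- update_factor_mode(st, tens, 1)
  elam <- st$lambda_shape / st$lambda_rate
  expect_equal(st$means[[1]][3, ], rep(0, 3))
  expect_equal(st$covs[[1]][, , 3], diag(1 / elam), tolerance = 1e-6)
})

test_that("factor update maximizes the bound over that block", {
  g <- gen_cp_tensor(c(2, 2, 2), 1, 50, 0, seed = 3)
  cfg <- cp_prior_config(R_init = 2, seed = 3)
  st <- init_state(g$tensor, cfg)
  for (n in 1:3) st <- update_factor_mode(st, g$tensor, n)
  st <- update_lambda(st, cfg)
  st <- update_tau(st, g$tensor, cfg)
  st <- update_factor_mode(st, g$tensor, 1)
  lb0 <- lower_bound(st, g$tensor, cfg)

  # numerical maximization over the updated block's means cannot do better
  f <- function(v) {
    s2 <- st
    s2$means[[1]] <- matrix(v, 2, 2)
    lower_bound(s2, g$tensor, cfg)
  }
  opt <- stats::optim(as.vector(st$means[[1]]) + 0.05, function(v) -f(v),
                      method = "BFGS", control = list(maxit = 200))
  expect_lte(-opt$value, lb0 + 1e-6 * abs(lb0))
  # and random mean perturbations strictly lower the bound
  perturbed <- vapply(1:10, function(i)
    f(as.vector(st$means[[1]]) +
        withr::with_seed(i, stats::rnorm(4, sd = 0.05))), numeric(1))
  expect_true(all(perturbed <= lb0 + 1e-10 * abs(lb0)))
})

test_that("lambda and tau updates are the conjugate Gamma solutions", {
  cfg <- cp_prior_config(R_init = 2, c0 = 1e-3, d0 = 1e-3, seed = 1)
  g <- gen_cp_tensor(c(5, 4, 3), 2, 100, 0, seed = 1)
  st <- init_state(g$tensor, cfg)
  # plant an exactly-dead component: zero means, zero covariance
  st$means <- lapply(st$means, function(M) { M[, 2] <- 0; M })
  st$covs <- lapply(st$covs, function(V) { V[2, , ] <- 0; V[, 2, ] <- 0; V })
  st <- update_lambda(st, cfg)
  expect_equal(st$lambda_shape[2], 1e-3 + (5 + 4 + 3) / 2)
  expect_equal(st$lambda_rate[2], 1e-3)      # zero expected power
  # symmetric components get identical posteriors
  st2 <- init_state(g$tensor, cfg)
  st2$means <- lapply(st2$means, function(M) { M[, 2] <- M[, 1]; M })
  st2$covs <- lapply(st2$covs, function(V) { V[2, 2, ] <- V[1, 1, ]; V })
  st2 <- update_lambda(st2, cfg)
  expect_equal(st2$lambda_rate[1], st2$lambda_rate[2])

  # tau: shape counts observed entries; rate adds half the expected residual
  st3 <- update_tau(st, g$tensor, cfg)
  expect_equal(st3$tau_shape, cfg$a0 + sum(g$tensor$mask) / 2)
  expect_gte(st3$tau_rate, cfg$b0)
  # fixed point: re-applying tau update changes nothing
  expect_equal(update_tau(st3, g$tensor, cfg)$tau_rate, st3$tau_rate)
})

test_that("every update is non-decreasing in the bound (monotonicity audit)", {
  for (s in 1:6) {
    g <- gen_cp_tensor(c(8, 7, 3), 2, 20, 0.15, seed = s)
    cfg <- cp_prior_config(R_init = 4, seed = s)
    st <- init_state(g$tensor, cfg)
    lb <- lower_bound(st, g$tensor, cfg)
    for (it in 1:4) {
      for (n in 1:3) {
        st <- update_factor_mode(st, g$tensor, n)
        lb2 <- lower_bound(st, g$tensor, cfg)
        expect_gte(lb2, lb - 1e-8 * abs(lb))
        lb <- lb2
      }
      st <- update_lambda(st, cfg)
      lb2 <- lower_bound(st, g$tensor, cfg)
      expect_gte(lb2, lb - 1e-8 * abs(lb))
      lb <- lb2
      st <- update_tau(st, g$tensor, cfg)
      lb2 <- lower_bound(st, g$tensor, cfg)
      expect_gte(lb2, lb - 1e-8 * abs(lb))
      lb <- lb2
    }
  }
})

test_that("lower bound is pure and matches a Monte-Carlo estimate", {
  g <- gen_cp_tensor(c(2, 2, 2), 1, 20, 0, seed = 5)
  cfg <- cp_prior_config(R_init = 2, seed = 5)
  st <- init_state(g$tensor, cfg)
  for (it in 1:10) {
    for (n in 1:3) st <- update_factor_mode(st, g$tensor, n)
    st <- update_lambda(st, cfg)
    st <- update_tau(st, g$tensor, cfg)
  }
  lb <- lower_bound(st, g$tensor, cfg)
  expect_identical(lb, lower_bound(st, g$tensor, cfg))

  # independent estimate: E_q[ln p(Y, Theta)] by sampling from q, plus
  # the analytic entropy of q
  R <- st$rank
  d <- g$tensor$shape
  gamma_entropy <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)
  h <- sum(vapply(1:3, function(n) sum(vapply(seq_len(d[n]), function(i)
    0.5 * determinant(st$covs[[n]][, , i], logarithm = TRUE)$modulus +
      0.5 * R * (1 + log(2 * pi)), numeric(1))), numeric(1))) +
    sum(gamma_entropy(st$lambda_shape, st$lambda_rate)) +
    gamma_entropy(st$tau_shape, st$tau_rate)
  draws <- withr::with_seed(99, vapply(1:3000, function(m) {
    A <- lapply(1:3, function(n) {
      M <- st$means[[n]]
      for (i in seq_len(d[n]))
        M[i, ] <- M[i, ] + drop(stats::rnorm(R) %*% chol(st$covs[[n]][, , i]))
      M
    })
    lam <- stats::rgamma(R, st$lambda_shape, rate = st$lambda_rate)
    tau <- stats::rgamma(1, st$tau_shape, rate = st$tau_rate)
    xh <- bf_cp_compose(A)
    obs <- g$tensor$mask
    lp <- sum(stats::dnorm(g$tensor$values[obs], xh[obs],
                           sd = 1 / sqrt(tau), log = TRUE)) +
      sum(vapply(1:3, function(n) sum(stats::dnorm(A[[n]], 0,
        sd = rep(1 / sqrt(lam), each = d[n]), log = TRUE)), numeric(1))) +
      sum(stats::dgamma(lam, cfg$c0, rate = cfg$d0, log = TRUE)) +
      stats::dgamma(tau, cfg$a0, rate = cfg$b0, log = TRUE)
    lp
  }, numeric(1)))
  mc <- mean(draws) + as.numeric(h)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mc - lb), 4 * se + 1e-6)
})

test_that("pruning removes planted dead components and nothing else", {
  g <- gen_cp_tensor(c(6, 6, 3), 2, 100, 0, seed = 6)
  cfg <- cp_prior_config(R_init = 3, seed = 6)
  st <- init_state(g$tensor, cfg)
  expect_identical(prune_rank(st, cfg)$rank, st$rank)  # healthy: no-op
  st$means <- lapply(st$means, function(M) { M[, 3] <- 0; M })
  st$covs <- lapply(st$covs, function(V) { V[3, , ] <- 0; V[, 3, ] <- 0;
    V[3, 3, ] <- 1e-12; V })
  pr <- prune_rank(st, cfg)
  expect_equal(pr$rank, 2L)
  expect_equal(ncol(pr$means[[1]]), 2L)
  expect_length(pr$lambda_shape, 2L)
})

test_that("noiseless data is fit exactly and rank is recovered", {
  # rank-1 noiseless: exact reconstruction
  g <- gen_cp_tensor(c(10, 10, 3), 1, Inf, 0, seed = 1)
  st <- suppressWarnings(bcpf(g$tensor, cp_prior_config(R_init = 3,
                                                        max_iter = 200,
                                                        seed = 1)))
  relerr <- sqrt(sum((reconstruct(st) - g$truth$latent_tensor)^2) /
                   sum(g$truth$latent_tensor^2))
  expect_lt(relerr, 1e-6)
  expect_equal(st$rank, 1L)

  # high-SNR rank-3 data, overcomplete start: automatic rank determination
  hits <- sum(vapply(1:6, function(s) {
    g <- gen_cp_tensor(c(15, 15, 4), 3, 1e4, 0, seed = s)
    st <- suppressWarnings(bcpf(g$tensor,
          cp_prior_config(R_init = 8, max_iter = 80, seed = s)))
    st$rank == 3L
  }, logical(1)))
  expect_gte(hits, 5)
})

test_that("fit trace is monotone and deterministic under seed", {
  g <- gen_cp_tensor(c(12, 12, 3), 2, 50, 0.2, seed = 8)
  cfg <- cp_prior_config(R_init = 5, max_iter = 50, seed = 8)
  st <- suppressWarnings(bcpf(g$tensor, cfg))
  expect_true(elbo_monotone(st$elbo_trace))
  st2 <- suppressWarnings(bcpf(g$tensor, cfg))
  expect_identical(st$means, st2$means)
  # non-convergence is flagged, not thrown
  st3 <- suppressWarnings(bcpf(g$tensor,
        cp_prior_config(R_init = 5, max_iter = 3, seed = 8)))
  expect_false(st3$converged)
})

test_that("held-out RMSE shrinks as noise precision grows", {
  med_rmse <- vapply(c(1, 10, 100), function(tau) {
    stats::median(vapply(1:3, function(s) {
      g <- gen_cp_tensor(c(15, 15, 3), 2, tau, 0.25, seed = s)
      st <- suppressWarnings(bcpf(g$tensor,
            cp_prior_config(R_init = 5, max_iter = 60, seed = s)))
      held <- !g$tensor$mask
      sqrt(mean((reconstruct(st)[held] - g$truth$latent_tensor[held])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_rmse) < 0))
})

test_that("reconstruct equals the triple-loop oracle and is gauge-invariant", {
  fs <- fit_small_state(seed = 9, shape = c(6, 6, 3), rank = 2, R_init = 3)
  st <- fs$st
  expect_equal(reconstruct(st), bf_cp_compose(st$means), tolerance = 1e-10)

  # simultaneous column permutation leaves the reconstruction unchanged
  R <- st$rank
  if (R > 1) {
    perm <- rev(seq_len(R))
    stp <- st
    stp$means <- lapply(st$means, function(M) M[, perm, drop = FALSE])
    expect_equal(reconstruct(stp), reconstruct(st), tolerance = 1e-12)
  }
  # reciprocal column rescaling across modes is a gauge freedom
  sts <- st
  sts$means[[1]] <- sts$means[[1]] * 2
  sts$means[[2]] <- sts$means[[2]] / 4
  sts$means[[3]] <- sts$means[[3]] * 2
  expect_equal(reconstruct(sts), reconstruct(st), tolerance = 1e-12)
})

test_that("reconstruction error matches an ALS oracle at fixed known rank", {
  g <- gen_cp_tensor(c(12, 12, 3), 2, 50, 0, seed = 10)
  st <- suppressWarnings(bcpf(g$tensor,
        cp_prior_config(R_init = 2, max_iter = 150, seed = 10)))
  err_vb <- sqrt(mean((reconstruct(st)[g$tensor$mask] -
                         g$tensor$values[g$tensor$mask])^2))
  xh_als <- bf_cp_als(g$tensor$values, 2, iters = 100, seed = 10)
  err_als <- sqrt(mean((xh_als[g$tensor$mask] -
                          g$tensor$values[g$tensor$mask])^2))
  expect_lt(abs(err_vb - err_als), 0.1 * err_als)
})

test_that("predictive distribution tracks observation and uncertainty", {
  # converged noiseless entries are predicted exactly
  g <- gen_cp_tensor(c(8, 8, 3), 1, Inf, 0, seed = 11)
  st <- suppressWarnings(bcpf(g$tensor,
        cp_prior_config(R_init = 2, max_iter = 200, seed = 11)))
  pr <- predict(st, indices = cbind(1:4, 1:4, 1))
  expect_equal(pr$mean, g$tensor$values[cbind(1:4, 1:4, 1)],
               tolerance = 1e-6)

  # rank-1 unit factors give mean 1 everywhere (closed form)
  unit <- init_state(gen_cp_tensor(c(3, 3, 3), 1, 100, 0, seed = 1)$tensor,
                     cp_prior_config(R_init = 1, seed = 1))
  unit$means <- lapply(unit$means, function(M) matrix(1, nrow(M), 1))
  unit$covs <- lapply(unit$covs, function(V) array(0, dim(V)))
  expect_equal(predict(unit)$mean, rep(1, 27))

  # masked entries carry more predictive variance than observed ones
  g2 <- gen_cp_tensor(c(14, 14, 3), 2, 50, 0.3, seed = 12)
  st2 <- suppressWarnings(bcpf(g2$tensor,
         cp_prior_config(R_init = 4, max_iter = 60, seed = 12)))
  pr2 <- predict(st2)
  obs <- g2$tensor$mask[as.matrix(pr2[, 1:3])]
  expect_gt(mean(pr2$variance[!obs]), mean(pr2$variance[obs]))
})
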