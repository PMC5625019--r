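# Variational Bayesian CP factorization of an incomplete noisy tensor with
# automatic rank determination (ARD).
#
# Model: Y = X + eps, eps ~ N(0, 1/tau) i.i.d. over observed entries;
#   X = sum_r a_r^(1) o a_r^(2) o a_r^(3);
#   rows of A^(n) ~ N(0, Lambda^-1), Lambda = diag(lambda_1..lambda_R) shared
#   across modes; lambda_r ~ Ga(c0, d0); tau ~ Ga(a0, b0).
# Mean-field posterior q factorizes over {A^(n)} rows, lambda and tau; every
# update is the conjugate exponential-family solution of the mean-field
# functional, so each one cannot decrease the evidence lower bound.

#' Prior and run configuration for the Bayesian CP factorization
#'
#' @param a0,b0 Gamma prior shape/rate on the noise precision tau.
#' @param c0,d0 Gamma hyperprior shape/rate on each component precision
#'   lambda_r (shared scalars; per-component vectors of length `R_init` are
#'   also accepted).
#' @param R_init initial (maximum) rank; by default `min(I1, I2)` of the
#'   tensor being fitted. Effective rank is inferred by ARD pruning.
#' @param max_iter maximum number of full update sweeps.
#' @param tol relative lower-bound change declaring convergence.
#' @param prune_threshold component kept only while its expected column
#'   power, relative to the largest component, stays above this value.
#'   The default 1e-2 sits between the covariance floor that shrunk (dead)
#'   components retain under the broad Gamma hyperpriors (around 1e-3
#'   relative) and the power of genuine components (order 1 relative).
#' @param seed integer seed controlling initialization.
#' @return list of class `cp_prior_config`.
#' @export
cp_prior_config <- function(a0 = 1e-6, b0 = 1e-6, c0 = 1e-6, d0 = 1e-6,
                            R_init = NULL, max_iter = 500L, tol = 1e-6,
                            prune_threshold = 1e-2, seed = 1L) {
  stopifnot(a0 > 0, b0 > 0, all(c0 > 0), all(d0 > 0),
            max_iter >= 1, tol > 0, prune_threshold > 0)
  if (!is.null(R_init)) R_init <- .stopifnot_count(R_init, "R_init")
  structure(list(a0 = a0, b0 = b0, c0 = c0, d0 = d0, R_init = R_init,
                 max_iter = as.integer(max_iter), tol = tol,
                 prune_threshold = prune_threshold, seed = as.integer(seed)),
            class = "cp_prior_config")
}

# ---- internal tensor algebra ------------------------------------------------

.unfold <- function(x, mode) {
  d <- dim(x)
  switch(mode,
         matrix(x, d[1]),
         matrix(aperm(x, c(2, 1, 3)), d[2]),
         matrix(aperm(x, c(3, 1, 2)), d[3]))
}

# column-wise Khatri-Rao product; rows of B cycle fastest, matching the
# column order of the mode-n unfolding
.kr <- function(A, B) {
  A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE] *
    B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE]
}

.cp_compose <- function(A, shape = NULL) {
  shape <- shape %||% vapply(A, nrow, integer(1))
  array(A[[1]] %*% t(.kr(A[[3]], A[[2]])), shape)
}

# I_n x R^2 matrix of row second moments vec(E[a_i a_i^T])
.smat <- function(M, Varr) {
  R <- ncol(M); I <- nrow(M)
  out <- matrix(0, I, R * R)
  for (i in seq_len(I))
    out[i, ] <- as.vector(tcrossprod(M[i, ]) + Varr[, , i])
  out
}

.zero_filled <- function(tensor) {
  y <- tensor$values
  y[!tensor$mask] <- 0
  y
}

# expected squared residual over observed entries under the current posterior
.expected_sq_residual <- function(state, tensor) {
  y0 <- .zero_filled(tensor)
  S <- lapply(1:3, function(n) .smat(state$means[[n]], state$covs[[n]]))
  xhat <- .cp_compose(state$means, tensor$shape)
  t1 <- sum(y0^2)
  t2 <- sum(y0 * xhat)
  o1 <- .unfold(tensor$mask * 1, 1)
  t3 <- sum(S[[1]] * (o1 %*% .kr(S[[3]], S[[2]])))
  max(t1 - 2 * t2 + t3, 0)
}

# ---- state ------------------------------------------------------------------

#' Initialize the variational posterior state
#'
#' Factor means come from the mode-wise singular vectors of the
#' mask-zero-filled matricizations, scaled by the square roots of the
#' singular values; columns beyond a mode's numerical rank are filled with
#' small seeded Gaussian draws. Because per-mode singular vectors carry
#' arbitrary signs and scales, the third mode is then re-solved by masked
#' ridge least squares given the first two, which makes the initial triple
#' coherent (its composition actually approximates the data) -- without
#' this step the first sweep can start from a reconstruction worse than
#' predicting zero and drop into a degenerate optimum. Row covariances
#' start at 0.01 times the identity -- a deliberately small initial posterior uncertainty, since
#' unit covariances inflate the second-moment terms of the first factor
#' sweep, over-shrink the means, and can lock weak components into the
#' degenerate explained-as-noise optimum -- and the Gamma posteriors start
#' at their priors.
#'
#' @param tensor an [observed_tensor()].
#' @param config a [cp_prior_config()].
#' @return list of class `cp_state`: `means` (3 factor matrices), `covs`
#'   (per mode, an R x R x I_n array of row covariances), `lambda_shape`,
#'   `lambda_rate`, `tau_shape`, `tau_rate`, `rank`, `elbo_trace`,
#'   `converged`, `labels`.
#' @export
init_state <- function(tensor, config = cp_prior_config()) {
  stopifnot(inherits(tensor, "observed_tensor"))
  if (sum(tensor$mask) == 0L) stop("tensor has no observed entries")
  d <- tensor$shape
  R <- config$R_init %||% min(d[1], d[2])
  if (R > min(d))
    warning(sprintf("R_init = %d exceeds the smallest mode size %d; ",
                    R, min(d)),
            "starting overcomplete and relying on ARD pruning")
  y0 <- .zero_filled(tensor)
  means <- .with_seed(config$seed, {
    lapply(1:3, function(n) {
      Un <- .unfold(y0, n)
      sv <- svd(Un)
      k <- min(sum(sv$d > 1e-12 * max(sv$d, 1e-300)), R)
      An <- matrix(stats::rnorm(d[n] * R, sd = 0.1), d[n], R)
      if (k > 0)
        An[, seq_len(k)] <- sv$u[, seq_len(k), drop = FALSE] %*%
          diag(sqrt(sv$d[seq_len(k)]), k)
      An
    })
  })
  # coherence step: masked ridge LS for mode 3 given modes 1 and 2
  Km <- .kr(means[[2]], means[[1]])
  Y3 <- .unfold(y0, 3)
  O3 <- .unfold(tensor$mask * 1, 3)
  for (i in seq_len(d[3])) {
    G <- crossprod(Km, Km * O3[i, ]) + 1e-6 * diag(R)
    means[[3]][i, ] <- solve(G, crossprod(Km, Y3[i, ]))
  }
  covs <- lapply(1:3, function(n) array(0.01 * diag(R), c(R, R, d[n])))
  structure(list(means = means, covs = covs,
                 lambda_shape = rep(config$c0, length.out = R),
                 lambda_rate = rep(config$d0, length.out = R),
                 tau_shape = config$a0, tau_rate = config$b0,
                 rank = R, elbo_trace = numeric(0), converged = NA,
                 labels = tensor$labels),
            class = "cp_state")
}

#' @export
print.cp_state <- function(x, ...) {
  cat(sprintf("cp_state: rank %d, E[tau] = %.4g, %d recorded sweeps%s\n",
              x$rank, x$tau_shape / x$tau_rate, length(x$elbo_trace),
              if (isTRUE(x$converged)) " (converged)"
              else if (isFALSE(x$converged)) " (not converged)" else ""))
  invisible(x)
}

# ---- mean-field updates -----------------------------------------------------

#' Update one mode's factor posterior
#'
#' Replaces every row of the mode's factor posterior by its conjugate
#' Gaussian: precision `E[Lambda] + E[tau] * sum` over the row's observed
#' entries of the second moment of the element-wise product of the other
#' modes' factor rows, and mean solving the matching linear system against
#' the observed data. A row with no observed entries reverts to its prior
#' `N(0, E[Lambda]^-1)`.
#'
#' @param state a `cp_state`.
#' @param tensor the [observed_tensor()] being fitted.
#' @param mode mode index in 1..3.
#' @return updated `cp_state`.
#' @export
update_factor_mode <- function(state, tensor, mode) {
  stopifnot(mode %in% 1:3)
  R <- state$rank
  Elam <- state$lambda_shape / state$lambda_rate
  Etau <- state$tau_shape / state$tau_rate
  oth <- setdiff(1:3, mode)
  q <- min(oth); p <- max(oth)
  Sp <- .smat(state$means[[p]], state$covs[[p]])
  Sq <- .smat(state$means[[q]], state$covs[[q]])
  KS <- .kr(Sp, Sq)
  Km <- .kr(state$means[[p]], state$means[[q]])
  O <- .unfold(tensor$mask * 1, mode)
  Y <- .unfold(.zero_filled(tensor), mode)
  U <- O %*% KS
  Z <- Y %*% Km
  In <- tensor$shape[mode]
  M <- matrix(0, In, R)
  Varr <- array(0, c(R, R, In))
  for (i in seq_len(In)) {
    P <- diag(Elam, R) + Etau * matrix(U[i, ], R, R)
    P <- (P + t(P)) / 2
    diag(P) <- diag(P) + 1e-10
    if (any(!is.finite(P)) || any(!is.finite(Z[i, ])))
      stop(sprintf("non-finite values entering the linear solve for mode %d, row %d",
                   mode, i))
    ch <- chol(P)
    Vi <- chol2inv(ch)
    Varr[, , i] <- (Vi + t(Vi)) / 2
    M[i, ] <- Etau * drop(Vi %*% Z[i, ])
  }
  state$means[[mode]] <- M
  state$covs[[mode]] <- Varr
  state
}

# expected squared column norms summed over rows, per mode: Q[n, r]
.column_power <- function(state) {
  out <- matrix(0, 3, state$rank)
  for (n in 1:3) {
    dvar <- apply(state$covs[[n]], 3, diag)   # R x I_n (vector when R == 1)
    if (is.null(dim(dvar))) dvar <- matrix(dvar, nrow = 1)
    out[n, ] <- colSums(state$means[[n]]^2) + rowSums(dvar)
  }
  out
}

#' Update the component-precision (ARD) posteriors
#'
#' Conjugate Gamma update: shape `c0 + sum(I_n)/2`; rate `d0 +` half the
#' expected squared norm of component r's columns across all modes.
#'
#' @param state a `cp_state`.
#' @param config a [cp_prior_config()].
#' @return updated `cp_state`.
#' @export
update_lambda <- function(state, config = cp_prior_config()) {
  Qnr <- .column_power(state)   # 3 x R
  In <- vapply(state$means, nrow, integer(1))
  state$lambda_shape <- rep(config$c0, length.out = state$rank) + sum(In) / 2
  state$lambda_rate <- rep(config$d0, length.out = state$rank) +
    colSums(Qnr) / 2
  state
}

#' Update the noise-precision posterior
#'
#' Conjugate Gamma update: shape `a0 + (number of observed entries)/2`;
#' rate `b0 +` half the expected squared residual over observed entries.
#'
#' @param state a `cp_state`.
#' @param tensor the [observed_tensor()] being fitted.
#' @param config a [cp_prior_config()].
#' @return updated `cp_state`.
#' @export
update_tau <- function(state, tensor, config = cp_prior_config()) {
  state$tau_shape <- config$a0 + sum(tensor$mask) / 2
  state$tau_rate <- config$b0 + .expected_sq_residual(state, tensor) / 2
  state
}

#' Prune shrunk components (automatic rank determination)
#'
#' Removes components whose expected column power, summed over all modes,
#' falls below `prune_threshold` relative to the largest component. The
#' largest component is never pruned, so the rank never reaches 0.
#'
#' @param state a `cp_state`.
#' @param config a [cp_prior_config()].
#' @return updated `cp_state` with possibly reduced rank.
#' @export
prune_rank <- function(state, config = cp_prior_config()) {
  power <- colSums(.column_power(state))
  rel <- power / max(power)
  keep <- rel >= config$prune_threshold
  keep[which.max(power)] <- TRUE
  if (all(keep)) return(state)
  state$means <- lapply(state$means, function(M) M[, keep, drop = FALSE])
  state$covs <- lapply(state$covs, function(V) V[keep, keep, , drop = FALSE])
  state$lambda_shape <- state$lambda_shape[keep]
  state$lambda_rate <- state$lambda_rate[keep]
  state$rank <- sum(keep)
  state
}

#' Evidence lower bound of the current variational posterior
#'
#' Pure function of the state: expected complete-data log joint under q
#' plus the entropy of q, all log-Gamma/digamma terms evaluated in log
#' space. Non-decreasing along the mean-field updates.
#'
#' @param state a `cp_state`.
#' @param tensor the [observed_tensor()] being fitted.
#' @param config a [cp_prior_config()].
#' @return scalar lower-bound value.
#' @export
lower_bound <- function(state, tensor, config = cp_prior_config()) {
  R <- state$rank
  In <- vapply(state$means, nrow, integer(1))
  Mobs <- sum(tensor$mask)
  a <- state$tau_shape; b <- state$tau_rate
  cr <- state$lambda_shape; dr <- state$lambda_rate
  Etau <- a / b; Elntau <- digamma(a) - log(b)
  Elam <- cr / dr; Elnlam <- digamma(cr) - log(dr)
  eres <- .expected_sq_residual(state, tensor)
  lp_y <- 0.5 * Mobs * (Elntau - log(2 * pi)) - 0.5 * Etau * eres
  Qnr <- .column_power(state)
  lp_A <- sum(vapply(1:3, function(n) {
    -0.5 * In[n] * R * log(2 * pi) + 0.5 * In[n] * sum(Elnlam) -
      0.5 * sum(Elam * Qnr[n, ])
  }, numeric(1)))
  c0 <- rep(config$c0, length.out = R); d0 <- rep(config$d0, length.out = R)
  lp_lam <- sum(c0 * log(d0) - lgamma(c0) + (c0 - 1) * Elnlam - d0 * Elam)
  lp_tau <- config$a0 * log(config$b0) - lgamma(config$a0) +
    (config$a0 - 1) * Elntau - config$b0 * Etau
  h_A <- sum(vapply(1:3, function(n) {
    ld <- vapply(seq_len(In[n]), function(i) {
      V <- state$covs[[n]][, , i]
      if (R == 1) log(as.numeric(V))
      else as.numeric(determinant(V, logarithm = TRUE)$modulus)
    }, numeric(1))
    0.5 * sum(ld) + 0.5 * In[n] * R * (1 + log(2 * pi))
  }, numeric(1)))
  h_lam <- sum(cr - log(dr) + lgamma(cr) + (1 - cr) * digamma(cr))
  h_tau <- a - log(b) + lgamma(a) + (1 - a) * digamma(a)
  lp_y + lp_A + lp_lam + lp_tau + h_A + h_lam + h_tau
}

#' Fit the Bayesian CP factorization
#'
#' Cycles the mean-field updates -- factor modes 1, 2, 3, then the ARD
#' precisions, then the noise precision, then rank pruning -- until the
#' relative lower-bound change drops below `config$tol` or `config$max_iter`
#' sweeps are reached. The bound is recorded once per sweep in
#' `elbo_trace`. A run that hits `max_iter` returns normally with
#' `converged = FALSE`.
#'
#' @param tensor an [observed_tensor()].
#' @param config a [cp_prior_config()].
#' @return a converged (or flagged non-converged) `cp_state`.
#' Mean-field coordinate ascent can land in a poor local optimum from an
#' unlucky initialization; with `n_starts > 1` the fit is repeated from
#' `n_starts` seeded initializations (seeds `config$seed`, `config$seed +
#' 1`, ...) and the state with the highest final lower bound is returned.
#' This stays deterministic under `config$seed`.
#'
#' @param n_starts number of seeded restarts (default 1).
#' @seealso [reconstruct()], [predict.cp_state()], [fuse_network_mode()]
#' @export
bcpf <- function(tensor, config = cp_prior_config(), n_starts = 1L) {
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts) - 1L, function(k) {
      cfg <- config
      cfg$seed <- config$seed + k
      bcpf(tensor, cfg, n_starts = 1L)
    })
    best <- which.max(vapply(fits, function(f) utils::tail(f$elbo_trace, 1),
                             numeric(1)))
    return(fits[[best]])
  }
  state <- init_state(tensor, config)
  prev <- -Inf
  state$converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    for (n in 1:3) state <- update_factor_mode(state, tensor, n)
    state <- update_lambda(state, config)
    state <- update_tau(state, tensor, config)
    state <- prune_rank(state, config)
    lb <- lower_bound(state, tensor, config)
    state$elbo_trace <- c(state$elbo_trace, lb)
    if (is.finite(prev) && abs(lb - prev) <= config$tol * abs(prev)) {
      state$converged <- TRUE
      break
    }
    prev <- lb
  }
  state
}

#' Posterior-mean reconstruction of the latent tensor
#'
#' Sum over components of the outer products of the posterior mean factor
#' columns.
#'
#' @param state a `cp_state`.
#' @return 3-way numeric array.
#' @export
reconstruct <- function(state) {
  .cp_compose(state$means)
}

#' Predictive distribution of tensor entries
#'
#' For each requested index (i, j, k), the predictive mean is the
#' generalized inner product of the three posterior mean rows and the
#' variance propagates the factor-row covariances plus the posterior
#' expectation of the noise variance.
#'
#' @param object a `cp_state`.
#' @param indices integer matrix with 3 columns (one row per entry);
#'   default: all entries.
#' @param ... unused.
#' @return data frame with columns `i`, `j`, `k`, `mean`, `variance`.
#' @export
predict.cp_state <- function(object, indices = NULL, ...) {
  d <- vapply(object$means, nrow, integer(1))
  if (is.null(indices))
    indices <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                     k = seq_len(d[3])))
  indices <- as.matrix(indices)
  stopifnot(ncol(indices) == 3)
  a <- object$tau_shape; b <- object$tau_rate
  noise_var <- if (a > 1) b / (a - 1) else b / a
  S <- lapply(1:3, function(n) .smat(object$means[[n]], object$covs[[n]]))
  A <- object$means
  mu <- rowSums(A[[1]][indices[, 1], , drop = FALSE] *
                A[[2]][indices[, 2], , drop = FALSE] *
                A[[3]][indices[, 3], , drop = FALSE])
  ex2 <- rowSums(S[[1]][indices[, 1], , drop = FALSE] *
                 S[[2]][indices[, 2], , drop = FALSE] *
                 S[[3]][indices[, 3], , drop = FALSE])
  data.frame(i = indices[, 1], j = indices[, 2], k = indices[, 3],
             mean = mu, variance = pmax(ex2 - mu^2, 0) + noise_var)
}
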