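# Independent brute-force oracles used across tests. These deliberately
# re-derive each statistic by direct enumeration, never by calling the
# implementation under test.

# exhaustive placement-null overlap p-value
bf_overlap_pvalue <- function(qs, qe, ref, domain_length) {
  len <- qe - qs
  n_place <- domain_length - len + 1
  dist_one <- function(s, e) {
    min(vapply(seq_len(nrow(ref)), function(r) {
      rs <- ref$start[r]; re <- ref$end[r]
      if (s < re && rs < e) 0
      else if (e <= rs) rs - e
      else s - re
    }, numeric(1)))
  }
  d_obs <- dist_one(qs, qe)
  hits <- sum(vapply(0:(n_place - 1), function(p)
    dist_one(p, p + len) <= d_obs, logical(1)))
  hits / n_place
}

# triple-loop CP composition
bf_cp_compose <- function(A) {
  d <- vapply(A, nrow, integer(1))
  R <- ncol(A[[1]])
  x <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (r in seq_len(R))
      x[i, j, k] <- x[i, j, k] + A[[1]][i, r] * A[[2]][j, r] * A[[3]][k, r]
  x
}

# Mann-Whitney concordance AUC with ties counting 1/2
bf_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# plain alternating-least-squares CP at fixed rank, fully observed
bf_cp_als <- function(y, rank, iters = 200, seed = 1) {
  d <- dim(y)
  kr2 <- function(A, B)
    A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE] *
    B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE]
  unf <- function(x, m) switch(m, matrix(x, d[1]),
                               matrix(aperm(x, c(2, 1, 3)), d[2]),
                               matrix(aperm(x, c(3, 1, 2)), d[3]))
  A <- withr::with_seed(seed, lapply(d, function(I)
    matrix(stats::rnorm(I * rank), I, rank)))
  for (it in seq_len(iters)) {
    for (m in 1:3) {
      oth <- setdiff(1:3, m)
      K <- kr2(A[[max(oth)]], A[[min(oth)]])
      A[[m]] <- t(solve(crossprod(K) + 1e-12 * diag(rank),
                        t(unf(y, m) %*% K)))
    }
  }
  bf_cp_compose(A)
}

# edge keys "a|b" for every unordered pair within an index set
pairs_of <- function(idx, tfs) {
  cmb <- utils::combn(idx, 2)
  paste(pmin(tfs[cmb[1, ]], tfs[cmb[2, ]]),
        pmax(tfs[cmb[1, ]], tfs[cmb[2, ]]), sep = "|")
}

# small fitted state for tests that need a converged model
fit_small_state <- function(seed = 1, shape = c(12, 12, 3), rank = 2,
                            tau = 100, missing = 0.1, R_init = 4,
                            max_iter = 60) {
  g <- gen_cp_tensor(shape, rank, tau, missing, seed = seed)
  st <- suppressWarnings(bcpf(g$tensor,
                              cp_prior_config(R_init = R_init,
                                              max_iter = max_iter,
                                              seed = seed)))
  list(g = g, st = st)
}

elbo_monotone <- function(trace, tol = 1e-8) {
  all(diff(trace) >= -tol * abs(trace[-length(trace)]))
}
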