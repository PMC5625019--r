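# Weighted-network construction: symmetrization, correlation, methylation,
# co-occupancy Jaccard, percentile normalization and tensor stacking.

test_that("symmetrize averages the two directions", {
  m <- matrix(c(0, 0.4, 0.2, 0), 2, 2)   # asym[1,2]=0.2, asym[2,1]=0.4
  s <- symmetrize(m)
  expect_equal(s$weights[1, 2], 0.3)
  expect_equal(s$weights[2, 1], 0.3)

  # symmetric input is a fixed point; random input gives symmetric output
  w <- withr::with_seed(1, matrix(stats::runif(25), 5, 5))
  s2 <- symmetrize(w)
  expect_equal(s2$weights, t(s2$weights))
  sym_in <- (w + t(w)) / 2
  expect_equal(symmetrize(sym_in)$weights[upper.tri(w)], sym_in[upper.tri(w)])

  # one observed direction is kept as-is
  m2 <- matrix(c(0, NA, 0.6, 0), 2, 2)
  expect_equal(symmetrize(m2)$weights[1, 2], 0.6)
})

test_that("correlation network uses |PCC| and masks degenerate rows", {
  x <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 1,
             c = -c(1, 2, 3, 4), d = c(1, 3, 2, 4), e = c(2, 2, 2, 2))
  net <- correlation_network(x)
  expect_equal(net$weights["a", "b"], 1)
  expect_equal(net$weights["a", "c"], 1)          # anticorrelation -> |PCC|
  expect_equal(net$weights["a", "d"], 0.8)        # hand-computed PCC
  expect_false(net$mask["a", "e"])                # zero variance masked
  expect_false(net$mask["e", "d"])
  expect_error(correlation_network(x[, 1:2]), "3 samples")
})

test_that("promoter methylation averages betas in a closed +/-2kb window", {
  sites <- data.frame(position = c(900, 1100), beta = c(0.2, 0.4))
  expect_equal(promoter_methylation(sites, tss = 1000, window = 2000), 0.3)
  expect_true(is.na(promoter_methylation(
    data.frame(position = 10000, beta = 0.5), tss = 1000)))
  # boundary site at exactly tss + window is included
  expect_equal(promoter_methylation(
    data.frame(position = 3000, beta = 0.9), tss = 1000, window = 2000), 0.9)
})

test_that("co-occupancy Jaccard matches hand-enumerated sets", {
  edges <- data.frame(
    regulator = c(rep("TFi", 3), rep("TFj", 3)),
    target = c("g1", "g2", "g3", "g2", "g3", "g4"))
  net <- cooccupancy_jaccard(regulatory_network(
    edges, tf_universe = c("TFi", "TFj", "g1", "g2", "g3", "g4")))
  expect_equal(net$weights["TFi", "TFj"], 0.5)    # |{g2,g3}| / |{g1..g4}|
  # identical target sets -> 1; disjoint non-empty -> 0; empty union masked
  e2 <- data.frame(regulator = c("a", "a", "b", "b", "c"),
                   target = c("x", "y", "x", "y", "z"))
  n2 <- cooccupancy_jaccard(regulatory_network(
    e2, tf_universe = c("a", "b", "c", "d", "x", "y", "z")))
  expect_equal(n2$weights["a", "b"], 1)
  expect_equal(n2$weights["a", "c"], 0)
  expect_equal(n2$weights["a", "d"], 0)   # union {x,y} non-empty -> scored 0
  expect_false(n2$mask["d", "x"])         # neither occupies: masked, not 0
})

test_that("Jaccard network is symmetric and bounded (property)", {
  nets <- gen_regulatory_networks(12, c(L = 2L), shared_modules = list(1:3),
                                  edge_noise = 0.1, seed = 5,
                                  baseline_occupancy = 0.2,
                                  module_target_count = 4)
  net <- cooccupancy_jaccard(nets$L[[1]])
  expect_equal(net$weights, t(net$weights))
  obs <- net$weights[net$mask]
  expect_true(all(obs >= 0 & obs <= 1))
})

test_that("percentile normalization maps tails to exactly 0 and 1", {
  # 15 nodes -> 105 pairs; the first 100 observed with linearly spaced weights
  n <- 15
  w <- matrix(NA_real_, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)[1:100, ]
  vals <- seq(0, 1, length.out = 100)
  w[ut] <- vals
  w[ut[, 2:1]] <- vals
  net <- normalize_network(weighted_network(w))
  out <- net$weights[ut]
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(sum(out == 0), 5)                  # 5% lower tail truncated
  expect_equal(sum(out == 1), 5)
  # the median edge sits at ~0.5 after rescaling between p5 and p95
  expect_equal(out[50], (vals[50] - stats::quantile(vals, .05, names = FALSE)) /
                 diff(stats::quantile(vals, c(.05, .95), names = FALSE)))
  expect_lt(abs(out[50] - 0.5), 0.02)
  # idempotent once more than 5% of edges saturate each tail
  wsat <- matrix(NA_real_, n, n)
  vsat <- c(rep(0, 8), seq(0.1, 0.9, length.out = 84), rep(1, 8))
  wsat[ut] <- vsat
  wsat[ut[, 2:1]] <- vsat
  sat <- weighted_network(wsat)
  once <- normalize_network(sat)
  expect_equal(once$weights, sat$weights, tolerance = 1e-12)
  expect_equal(normalize_network(once)$weights, once$weights,
               tolerance = 1e-12)
})

test_that("constant network normalizes to zero with a warning", {
  w <- matrix(0.7, 4, 4)
  expect_warning(out <- normalize_network(weighted_network(w)), "constant")
  expect_true(all(out$weights[out$mask] == 0))
})

test_that("stack_tensor stacks slices, masks diagonals, rejects mismatches", {
  nets <- lapply(1:3, function(k) {
    w <- withr::with_seed(k, matrix(stats::runif(36), 6, 6))
    symmetrize(w, nodes = sprintf("TF%02d", 1:6))
  })
  tens <- stack_tensor(nets)
  expect_equal(tens$shape, c(6L, 6L, 3L))
  expect_equal(tens$values[1, 2, 2], nets[[2]]$weights[1, 2])
  expect_false(any(tens$mask[cbind(1:6, 1:6, rep(1:3, each = 6))]))

  # masked entry propagates into the tensor mask
  wm <- nets[[1]]$weights
  wm[2, 3] <- wm[3, 2] <- NA
  nets_m <- nets
  nets_m[[1]] <- weighted_network(wm, nodes = nets[[1]]$nodes)
  expect_false(stack_tensor(nets_m)$mask[2, 3, 1])

  # permuting slice order permutes tensor slices identically
  perm <- stack_tensor(nets[c(3, 1, 2)])
  expect_equal(perm$values[, , 1], tens$values[, , 3])

  other <- symmetrize(matrix(stats::runif(36), 6, 6),
                      nodes = sprintf("X%02d", 1:6))
  expect_error(stack_tensor(list(nets[[1]], other)), "symmetric difference")
})
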