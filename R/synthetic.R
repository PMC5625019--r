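# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the model assumes, so all stages are testable offline.

#' Generate a CP-structured noisy tensor with uniform missingness
#'
#' Draws factor matrices with i.i.d. standard-normal entries (the model's
#' own prior family with unit precision), composes the latent low-rank
#' tensor, adds i.i.d. Gaussian noise with the requested precision, and
#' masks a uniformly random subset of entries.
#'
#' @param shape integer vector of 3 mode sizes.
#' @param rank true CP rank of the latent tensor. Must not exceed, for any
#'   mode, the product of the other two mode sizes (the CP-rank feasibility
#'   bound); a rank larger than a single small mode size is allowed.
#' @param noise_precision precision (1/variance) of the additive Gaussian
#'   noise; `Inf` means noise-free.
#' @param missing_fraction fraction of entries masked out, in \[0, 1);
#'   exactly `round(missing_fraction * prod(shape))` entries are masked,
#'   placed uniformly at random.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return list with elements `tensor` (an [observed_tensor()]) and `truth`
#'   (class `cp_truth`: `latent_tensor`, `factor_matrices`, `true_rank`,
#'   `noise_precision`, `missing_fraction`, `seed`).
#' @export
gen_cp_tensor <- function(shape, rank, noise_precision = Inf,
                          missing_fraction = 0, seed = 1L) {
  if (length(shape) != 3L || any(shape < 1) || any(shape != round(shape)))
    stop("'shape' must be 3 positive integers")
  shape <- as.integer(shape)
  rank <- .stopifnot_count(rank, "rank")
  for (m in 1:3) {
    if (rank > prod(shape[-m]))
      stop(sprintf("rank %d is infeasible for mode %d: it exceeds the %d x %d product of the other modes",
                   rank, m, shape[-m][1], shape[-m][2]))
  }
  .stopifnot_fraction(missing_fraction, "missing_fraction")
  if (!(is.numeric(noise_precision) && length(noise_precision) == 1L &&
        noise_precision > 0))
    stop("'noise_precision' must be a positive real (Inf for no noise)")
  total <- prod(shape)
  n_missing <- round(missing_fraction * total)
  if (total - n_missing < rank * sum(shape))
    stop("missing_fraction leaves fewer observed entries than rank * sum(shape)")
  .with_seed(seed, {
    A <- lapply(shape, function(I) matrix(stats::rnorm(I * rank), I, rank))
    X <- .cp_compose(A, shape)
    Y <- if (is.finite(noise_precision))
      X + array(stats::rnorm(total, sd = 1 / sqrt(noise_precision)), shape)
    else X
    mask <- array(TRUE, shape)
    if (n_missing > 0) mask[sample.int(total, n_missing)] <- FALSE
  })
  labels <- list(sprintf("i%03d", seq_len(shape[1])),
                 sprintf("j%03d", seq_len(shape[2])),
                 sprintf("k%03d", seq_len(shape[3])))
  truth <- structure(list(latent_tensor = X, factor_matrices = A,
                          true_rank = rank, noise_precision = noise_precision,
                          missing_fraction = missing_fraction, seed = seed),
                     class = "cp_truth")
  list(tensor = observed_tensor(Y, mask, labels), truth = truth)
}

#' Generate toy peak sets with planted co-binding pairs
#'
#' Places fixed-length peaks on a finite linear domain ("chr1"). TFs in a
#' planted pair share peak centers up to an independent integer jitter of at
#' most `jitter`; all other TFs get independently uniform placements, so
#' non-planted pairs follow the uniform placement null.
#'
#' @param domain_length length of the linear domain.
#' @param n_tfs number of TFs.
#' @param planted_pairs list of length-2 integer vectors (1-based TF
#'   indices) that should co-bind.
#' @param peaks_per_tf number of peaks per TF.
#' @param jitter maximum absolute center offset between planted partners.
#' @param seed integer seed.
#' @param peak_length constant peak length (default 200); the constant
#'   geometry keeps the overlap null analytic.
#' @return named list of [interval_set()] objects, one per TF.
#' @export
gen_toy_peaks <- function(domain_length, n_tfs, planted_pairs = list(),
                          peaks_per_tf = 20, jitter = 0, seed = 1L,
                          peak_length = 200) {
  domain_length <- .stopifnot_count(domain_length, "domain_length")
  n_tfs <- .stopifnot_count(n_tfs, "n_tfs")
  peaks_per_tf <- .stopifnot_count(peaks_per_tf, "peaks_per_tf")
  if (jitter < 0 || jitter != round(jitter)) stop("'jitter' must be a non-negative integer")
  if (peak_length + 2 * jitter > domain_length)
    stop("peaks (plus jitter) cannot fit inside the domain")
  for (pr in planted_pairs) {
    if (length(pr) != 2L || any(pr < 1) || any(pr > n_tfs) || pr[1] == pr[2])
      stop("each planted pair must be two distinct TF indices in 1..n_tfs")
  }
  half <- floor(peak_length / 2)
  lo <- half + jitter
  hi <- domain_length - (peak_length - half) - jitter
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  .with_seed(seed, {
    centers <- vector("list", n_tfs)
    for (pr in planted_pairs) {
      i <- pr[1]; j <- pr[2]
      base <- centers[[i]] %||% centers[[j]] %||%
        round(stats::runif(peaks_per_tf, lo, hi))
      jit <- function() if (jitter > 0)
        sample.int(2L * jitter + 1L, peaks_per_tf, replace = TRUE) - jitter - 1L
      else rep(0L, peaks_per_tf)
      if (is.null(centers[[i]])) centers[[i]] <- base + jit()
      if (is.null(centers[[j]])) centers[[j]] <- base + jit()
    }
    out <- vector("list", n_tfs)
    for (t in seq_len(n_tfs)) {
      ct <- centers[[t]] %||% round(stats::runif(peaks_per_tf, half,
                                                 domain_length - (peak_length - half)))
      start <- pmax(0, ct - half)
      out[[t]] <- interval_set("chr1", start, start + peak_length,
                               round(stats::runif(peaks_per_tf, 10, 100), 1))
    }
  })
  names(out) <- tfs
  out
}

#' Generate TF profile matrices with planted correlated blocks
#'
#' TFs inside one block load on a common latent sample factor with loading
#' sqrt(rho), so the expected pairwise Pearson correlation within the block
#' is `within_block_correlation`; cross-block and background TFs are
#' independent (expected correlation 0).
#'
#' @param n_tfs number of TFs (rows).
#' @param n_samples number of samples (columns).
#' @param blocks list of disjoint integer index sets.
#' @param within_block_correlation expected within-block pairwise
#'   correlation, in (0, 1).
#' @param seed integer seed.
#' @return numeric matrix, TFs x samples, with TF row names and sample
#'   column names.
#' @export
gen_profiles <- function(n_tfs, n_samples, blocks = list(),
                         within_block_correlation = 0.8, seed = 1L) {
  n_tfs <- .stopifnot_count(n_tfs, "n_tfs")
  n_samples <- .stopifnot_count(n_samples, "n_samples")
  rho <- within_block_correlation
  if (!(rho > 0 && rho < 1)) stop("'within_block_correlation' must be in (0, 1)")
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) stop("blocks must be disjoint")
  if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > n_tfs))
    stop("block indices out of range")
  .with_seed(seed, {
    E <- matrix(stats::rnorm(n_tfs * n_samples), n_tfs, n_samples)
    for (b in blocks) {
      z <- stats::rnorm(n_samples)
      E[b, ] <- sqrt(rho) * matrix(z, length(b), n_samples, byrow = TRUE) +
        sqrt(1 - rho) * E[b, , drop = FALSE]
    }
  })
  dimnames(E) <- list(sprintf("TF%02d", seq_len(n_tfs)),
                      sprintf("S%03d", seq_len(n_samples)))
  E
}

#' Generate lineage-structured directed regulatory networks
#'
#' Emulates a panel of per-cell-type TF regulatory networks with planted
#' co-occupancy structure: TFs in a shared module occupy a common random
#' promoter set in every cell type; TFs in a lineage-specific module occupy
#' their module's promoter set only within that lineage's cell types. The
#' modules' promoter sets are drawn disjointly (a random partition of the
#' gene universe), so distinct planted modules stay identifiable: with the
#' small toy universe, independently drawn promoter sets would overlap
#' enough to blur the modules together. Every other (regulator, target)
#' edge is present independently with probability `baseline_occupancy`,
#' and each edge is independently flipped with probability `edge_noise`.
#'
#' @param n_tfs number of TFs; targets are the TF genes themselves.
#' @param lineages named integer vector: lineage name -> number of cell
#'   types.
#' @param shared_modules list of integer TF index sets active in all cell
#'   types.
#' @param specific_modules named list (lineage -> list of TF index sets)
#'   active only in that lineage.
#' @param edge_noise per-edge flip probability in \[0, 1\].
#' @param seed integer seed.
#' @param baseline_occupancy background occupancy probability per
#'   (regulator, target) pair.
#' @param module_target_count promoter-set size per module (default
#'   `max(4, round(0.25 * n_tfs))`).
#' @return nested named list: `result[[lineage]][[cell_type]]` is a
#'   [regulatory_network()].
#' @export
gen_regulatory_networks <- function(n_tfs, lineages, shared_modules = list(),
                                    specific_modules = list(),
                                    edge_noise = 0, seed = 1L,
                                    baseline_occupancy = 0.08,
                                    module_target_count = NULL) {
  n_tfs <- .stopifnot_count(n_tfs, "n_tfs")
  if (is.null(names(lineages)) || any(names(lineages) == ""))
    stop("'lineages' must be a named vector: lineage -> number of cell types")
  .stopifnot_fraction(edge_noise, "edge_noise", allow_one = TRUE)
  unknown <- setdiff(names(specific_modules), names(lineages))
  if (length(unknown))
    stop("specific_modules name lineages absent from 'lineages': ",
         paste(unknown, collapse = ", "))
  mtc <- module_target_count %||% max(4L, round(0.2 * n_tfs))
  n_modules <- length(shared_modules) + sum(lengths(specific_modules))
  if (n_modules * mtc > n_tfs)
    stop("module promoter sets are drawn disjointly: need ",
         "n_modules * module_target_count <= n_tfs")
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  .with_seed(seed, {
    pool <- sample.int(n_tfs)   # disjoint promoter sets for the modules
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    shared_targets <- lapply(shared_modules, function(m) take(mtc))
    specific_targets <- lapply(specific_modules, function(mods)
      lapply(mods, function(m) take(mtc)))
    out <- list()
    for (lin in names(lineages)) {
      cts <- list()
      for (ct in seq_len(lineages[[lin]])) {
        occ <- matrix(stats::runif(n_tfs * n_tfs) < baseline_occupancy,
                      n_tfs, n_tfs)
        for (s in seq_along(shared_modules))
          occ[shared_modules[[s]], shared_targets[[s]]] <- TRUE
        if (lin %in% names(specific_modules)) {
          mods <- specific_modules[[lin]]
          for (s in seq_along(mods))
            occ[mods[[s]], specific_targets[[lin]][[s]]] <- TRUE
        }
        if (edge_noise > 0) {
          flip <- matrix(stats::runif(n_tfs * n_tfs) < edge_noise, n_tfs, n_tfs)
          occ <- xor(occ, flip)
        }
        idx <- which(occ, arr.ind = TRUE)
        cts[[sprintf("%s_ct%d", lin, ct)]] <-
          regulatory_network(data.frame(regulator = tfs[idx[, 1]],
                                        target = tfs[idx[, 2]],
                                        stringsAsFactors = FALSE),
                             tf_universe = tfs)
      }
      out[[lin]] <- cts
    }
  })
  out
}
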