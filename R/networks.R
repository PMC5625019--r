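#' Symmetric weighted TF interaction network
#'
#' Container for a TF-by-TF weight matrix with an observation mask. The
#' diagonal is excluded from all statistics and is always masked. `NA`
#' weights are treated as unobserved; the mask distinguishes "no evidence"
#' from "evidence of no interaction" (weight 0).
#'
#' @param weights square numeric matrix; must be symmetric wherever both
#'   entries are observed.
#' @param mask logical matrix marking observed entries (default: non-`NA`
#'   weights). Made symmetric by conjunction with its transpose.
#' @param nodes TF labels (default: row names of `weights`).
#' @return An object of class `weighted_network` with elements
#'   `nodes`, `weights`, `mask`.
#' @export
weighted_network <- function(weights, mask = NULL, nodes = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("'weights' must be square")
  n <- nrow(weights)
  nodes <- nodes %||% rownames(weights) %||% sprintf("TF%02d", seq_len(n))
  if (length(nodes) != n) stop("'nodes' length must match the matrix size")
  if (is.null(mask)) mask <- !is.na(weights)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(weights))) stop("'mask' dimensions must match 'weights'")
  mask <- mask & t(mask)
  diag(mask) <- FALSE
  weights[!mask] <- NA_real_
  both <- mask & t(mask)
  if (any(abs(weights[both] - t(weights)[both]) > 1e-8, na.rm = TRUE))
    stop("'weights' must be symmetric where observed; use symmetrize() first")
  dimnames(weights) <- dimnames(mask) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, mask = mask),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d TFs, %d/%d observed pairs\n",
              length(x$nodes),
              sum(x$mask[upper.tri(x$mask)]),
              length(x$nodes) * (length(x$nodes) - 1) / 2))
  invisible(x)
}

#' Symmetrize an asymmetric interaction matrix
#'
#' Replaces each pair of off-diagonal entries by their average. If only one
#' direction is observed (the other is `NA`), the observed value is kept.
#'
#' @param asym square numeric matrix.
#' @param nodes optional TF labels.
#' @return A [weighted_network()].
#' @export
symmetrize <- function(asym, nodes = rownames(asym)) {
  asym <- as.matrix(asym)
  if (nrow(asym) != ncol(asym)) stop("'asym' must be square")
  b <- t(asym)
  s <- (asym + b) / 2
  only_a <- !is.na(asym) & is.na(b)
  only_b <- is.na(asym) & !is.na(b)
  s[only_a] <- asym[only_a]
  s[only_b] <- b[only_b]
  weighted_network(s, nodes = nodes)
}

#' Co-expression / co-methylation network from TF profiles
#'
#' Edge weight is the absolute Pearson correlation coefficient between two
#' TFs' profiles across samples. Rows with zero variance yield masked
#' (unobserved) entries rather than zero weights.
#'
#' @param profiles numeric matrix, TFs in rows, samples in columns
#'   (at least 3 samples).
#' @return A [weighted_network()].
#' @export
correlation_network <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3L)
    stop("at least 3 samples are required to form a correlation network")
  sds <- apply(profiles, 1, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  w <- abs(suppressWarnings(stats::cor(t(profiles))))
  mask <- outer(!degenerate, !degenerate, "&")
  weighted_network(w, mask = mask,
                   nodes = rownames(profiles) %||% sprintf("TF%02d", seq_len(nrow(profiles))))
}

#' Promoter methylation level of one gene
#'
#' Mean beta value over methylation sites within `window` bases of the
#' transcription start site (closed interval at both boundaries). Returns
#' `NA` when no site falls in the window, so the missingness propagates to
#' the network mask.
#'
#' @param sites data frame with columns `position` and `beta` (in \[0,1\]).
#' @param tss transcription start site position.
#' @param window half-width of the promoter window in bases (default 2000,
#'   i.e. TSS +/- 2 kb).
#' @return mean beta value, or `NA_real_`.
#' @export
promoter_methylation <- function(sites, tss, window = 2000) {
  sites <- as.data.frame(sites)
  sel <- abs(sites$position - tss) <= window
  if (!any(sel)) return(NA_real_)
  mean(sites$beta[sel])
}

#' Directed TF regulatory network for one cell type
#'
#' Directed regulator -> target occupancy edges over a fixed TF universe;
#' the input to the co-occupancy Jaccard score.
#'
#' @param edges data frame (or 2-column matrix) with columns
#'   `regulator`, `target`.
#' @param tf_universe ordered TF labels; every edge endpoint must belong to
#'   it. Default: the sorted union of edge endpoints.
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, tf_universe = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs two columns: regulator, target")
  names(edges)[1:2] <- c("regulator", "target")
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  tf_universe <- tf_universe %||% sort(unique(c(edges$regulator, edges$target)))
  bad <- setdiff(unique(c(edges$regulator, edges$target)), tf_universe)
  if (length(bad))
    stop("edge endpoints outside tf_universe: ", paste(bad, collapse = ", "))
  structure(list(edges = edges[, 1:2], tf_universe = tf_universe),
            class = "regulatory_network")
}

#' Co-occupancy network by Jaccard index
#'
#' For every TF pair, the interaction score is the Jaccard index of the two
#' TFs' occupied target sets: |Occupy(i) intersect Occupy(j)| /
#' |Occupy(i) union Occupy(j)|. Pairs whose union is empty (neither TF
#' occupies any promoter) are masked as unobserved, not scored 0.
#'
#' @param network a [regulatory_network()].
#' @return A [weighted_network()] over `network$tf_universe`.
#' @export
cooccupancy_jaccard <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  tfs <- network$tf_universe
  n <- length(tfs)
  inc <- matrix(FALSE, n, n, dimnames = list(tfs, tfs))
  if (nrow(network$edges) > 0)
    inc[cbind(match(network$edges$regulator, tfs),
              match(network$edges$target, tfs))] <- TRUE
  inter <- tcrossprod(inc * 1)
  sz <- rowSums(inc)
  un <- outer(sz, sz, "+") - inter
  w <- ifelse(un > 0, inter / un, NA_real_)
  weighted_network(w, mask = un > 0, nodes = tfs)
}

#' Percentile-truncated min-max normalization of a network
#'
#' Maps observed off-diagonal weights into \[0, 1\]: weights at or above the
#' upper percentile become 1, at or below the lower percentile become 0, and
#' the rest are linearly rescaled between the two percentiles. Percentiles
#' use linear interpolation between order statistics (`quantile` type 7) and
#' are computed over the observed upper-triangle weights. The mask is
#' unchanged.
#'
#' @param net a [weighted_network()].
#' @param lower_pct,upper_pct truncation percentiles (defaults 5 and 95).
#' @return A [weighted_network()] with observed weights in \[0, 1\].
#' @export
normalize_network <- function(net, lower_pct = 5, upper_pct = 95) {
  stopifnot(inherits(net, "weighted_network"))
  vals <- net$weights[upper.tri(net$weights) & net$mask]
  if (length(vals) == 0L) stop("network has no observed off-diagonal weights")
  qs <- stats::quantile(vals, c(lower_pct, upper_pct) / 100,
                        type = 7, names = FALSE)
  w <- net$weights
  if (qs[2] == qs[1]) {
    warning("constant network: upper and lower percentiles coincide; ",
            "all observed weights set to 0")
    w[net$mask] <- 0
  } else {
    scaled <- (w - qs[1]) / (qs[2] - qs[1])
    scaled <- pmin(pmax(scaled, 0), 1)
    w[net$mask] <- scaled[net$mask]
  }
  weighted_network(w, mask = net$mask, nodes = net$nodes)
}

#' Stack weighted networks into a 3-way observation tensor
#'
#' Slice k of the tensor holds network k's weight matrix; slice k of the
#' mask holds its observation mask. Diagonal entries are unobserved in every
#' slice. All networks must share the same node ordering.
#'
#' @param networks ordered list of [weighted_network()] objects.
#' @return An [observed_tensor()] of shape (nTF, nTF, nNetworks).
#' @export
stack_tensor <- function(networks) {
  stopifnot(length(networks) >= 1)
  nodes <- networks[[1]]$nodes
  for (k in seq_along(networks)) {
    nk <- networks[[k]]$nodes
    if (!identical(nk, nodes)) {
      diff <- union(setdiff(nodes, nk), setdiff(nk, nodes))
      stop("network ", k, " has a different node set/order; symmetric ",
           "difference: ", if (length(diff)) paste(diff, collapse = ", ")
           else "(same set, different order)")
    }
  }
  n <- length(nodes); K <- length(networks)
  vals <- array(NA_real_, c(n, n, K))
  mask <- array(FALSE, c(n, n, K))
  for (k in seq_len(K)) {
    vals[, , k] <- networks[[k]]$weights
    mask[, , k] <- networks[[k]]$mask
  }
  slice_names <- names(networks) %||% sprintf("net%d", seq_len(K))
  observed_tensor(vals, mask, labels = list(nodes, nodes, slice_names))
}

#' Observed pairs of a weighted network as an edge table
#'
#' @param net a [weighted_network()].
#' @return data frame with columns `tf_a`, `tf_b`, `weight`, one row per
#'   observed upper-triangle pair.
#' @export
network_pairs <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  idx <- which(upper.tri(net$weights) & net$mask, arr.ind = TRUE)
  data.frame(tf_a = net$nodes[idx[, 1]],
             tf_b = net$nodes[idx[, 2]],
             weight = net$weights[idx],
             stringsAsFactors = FALSE)
}
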