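# Fuse the factorization into one weighted TF network and call strong,
# hub, and lineage-specific/housekeeping interactions.

#' Configuration for strong-edge and hub calling
#'
#' @param alpha multiplier on the interquartile range above the 75th
#'   percentile (default 1.5).
#' @param hub_fraction fraction of TFs called hubs by strong-edge degree
#'   (default 0.05, i.e. the top 5 percent).
#' @return list of class `strong_edge_config`.
#' @export
strong_edge_config <- function(alpha = 1.5, hub_fraction = 0.05) {
  stopifnot(alpha > 0, hub_fraction > 0, hub_fraction < 1)
  structure(list(alpha = alpha, hub_fraction = hub_fraction),
            class = "strong_edge_config")
}

#' Fuse factors into one weighted TF interaction network
#'
#' Each rank-one TF x TF matrix is weighted by the mean of its
#' network-mode factor column (w_r = mean of column r of the network-mode
#' factor matrix) and the weighted sum is symmetrized. This is the unique
#' linear fusion that equals the slice-mean of the reconstructed tensor, so
#' it reduces to plain network averaging when the factorization is exact.
#' With `normalize = TRUE` the fused weights are min-max rescaled to
#' \[0, 1\] over the off-diagonal entries.
#'
#' @param state a fitted `cp_state` whose two TF modes have equal size.
#' @param network_mode index of the network (slice) mode, default 3.
#' @param normalize rescale fused weights to \[0, 1\]?
#' @return A [weighted_network()]; the unnormalized symmetric fused matrix
#'   is attached as attribute `"raw_weights"`.
#' @export
fuse_network_mode <- function(state, network_mode = 3, normalize = TRUE) {
  stopifnot(inherits(state, "cp_state"))
  if (!(network_mode %in% 1:3)) stop("'network_mode' must be in 1..3")
  tf_modes <- setdiff(1:3, network_mode)
  A <- state$means[[tf_modes[1]]]
  B <- state$means[[tf_modes[2]]]
  if (nrow(A) != nrow(B))
    stop("the two TF modes have different sizes; cannot fuse into one network")
  w <- colMeans(state$means[[network_mode]])
  f <- A %*% t(sweep(B, 2, w, "*"))
  raw <- (f + t(f)) / 2
  nodes <- if (!is.null(state$labels)) state$labels[[tf_modes[1]]]
           else sprintf("TF%02d", nrow(A))
  out <- raw
  diag(out) <- NA_real_
  if (normalize) {
    off <- out[upper.tri(out)]
    rng <- range(off)
    out[] <- if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else 0
    diag(out) <- NA_real_
  }
  net <- weighted_network(out, nodes = nodes)
  attr(net, "raw_weights") <- raw
  net
}

#' Call strongly relevant interactions per TF
#'
#' For each TF, an incident edge is strong when its weight exceeds
#' `Q3 + alpha * IQR` of that TF's observed incident edge weights (strict
#' inequality; quartiles by linear interpolation). The returned network is
#' the union over TFs of their strong edges: an edge strong for either
#' endpoint is kept. TFs with fewer than 4 observed incident edges
#' contribute no strong edges.
#'
#' @param net a [weighted_network()].
#' @param config a [strong_edge_config()].
#' @return data frame with columns `tf_a`, `tf_b`, `weight`, ordered by
#'   decreasing weight.
#' @export
strong_interactions <- function(net, config = strong_edge_config()) {
  stopifnot(inherits(net, "weighted_network"))
  n <- length(net$nodes)
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    obs <- which(net$mask[i, ])
    if (length(obs) < 4L) next
    ww <- net$weights[i, obs]
    q <- stats::quantile(ww, c(0.25, 0.75), type = 7, names = FALSE)
    thr <- q[2] + config$alpha * (q[2] - q[1])
    sel[i, obs[ww > thr]] <- TRUE
  }
  sel <- sel | t(sel)
  idx <- which(upper.tri(sel) & sel, arr.ind = TRUE)
  out <- data.frame(tf_a = net$nodes[idx[, 1]],
                    tf_b = net$nodes[idx[, 2]],
                    weight = net$weights[idx],
                    stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}

#' Hub TFs by strong-edge degree
#'
#' Degree is the number of strong edges incident to a TF. The top
#' `ceiling(hub_fraction * n)` TFs are returned, where n counts TFs with
#' degree > 0; ties at the boundary are all kept.
#'
#' @param strong_net strong-edge table from [strong_interactions()].
#' @param config a [strong_edge_config()].
#' @return character vector of hub TF labels, highest degree first.
#' @export
hub_tfs <- function(strong_net, config = strong_edge_config()) {
  if (nrow(strong_net) == 0L) return(character(0))
  deg <- table(c(strong_net$tf_a, strong_net$tf_b))
  deg <- sort(deg, decreasing = TRUE)
  k <- ceiling(config$hub_fraction * length(deg))
  thr <- deg[k]
  names(deg)[deg >= thr]
}

.edge_keys <- function(x) {
  if (is.character(x)) return(unique(x))
  a <- pmin(x$tf_a, x$tf_b); b <- pmax(x$tf_a, x$tf_b)
  unique(paste(a, b, sep = "|"))
}

#' Classify strong edges across cell lineages
#'
#' Each edge in the union of per-lineage strong-edge sets is labeled
#' `specific:<lineage>` when found in exactly one lineage, `housekeeping`
#' when found in every lineage, and `shared` otherwise.
#'
#' @param per_lineage_strong named list (lineage -> strong-edge table from
#'   [strong_interactions()], or character vector of `"a|b"` keys). At
#'   least 2 lineages.
#' @return list with `edges` (data frame: `edge`, `tf_a`, `tf_b`, `label`,
#'   `n_lineages`, `lineages`), `summary` (per-lineage counts and specific
#'   fractions) and `lineages`.
#' @export
classify_edges <- function(per_lineage_strong) {
  lineages <- names(per_lineage_strong)
  if (length(lineages) < 2L || is.null(lineages))
    stop("at least 2 named lineages are required; specific vs housekeeping ",
         "is undefined for a single lineage")
  keys <- lapply(per_lineage_strong, .edge_keys)
  all_edges <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) all_edges %in% k,
                   logical(length(all_edges)))
  if (length(all_edges) == 1L) member <- matrix(member, nrow = 1)
  nlin <- rowSums(member)
  lab <- ifelse(nlin == length(lineages), "housekeeping",
                ifelse(nlin == 1L,
                       paste0("specific:",
                              lineages[apply(member, 1, which.max)]),
                       "shared"))
  parts <- strsplit(all_edges, "|", fixed = TRUE)
  edges <- data.frame(
    edge = all_edges,
    tf_a = vapply(parts, `[`, "", 1),
    tf_b = vapply(parts, `[`, "", 2),
    label = lab,
    n_lineages = nlin,
    lineages = apply(member, 1, function(m) paste(lineages[m], collapse = ",")),
    stringsAsFactors = FALSE)
  summary <- data.frame(
    lineage = lineages,
    n_edges = colSums(member),
    n_specific = vapply(lineages, function(l)
      sum(edges$label == paste0("specific:", l)), integer(1)),
    stringsAsFactors = FALSE)
  summary$frac_specific <- ifelse(summary$n_edges > 0,
                                  summary$n_specific / summary$n_edges, NA)
  rownames(edges) <- rownames(summary) <- NULL
  list(edges = edges, summary = summary, lineages = lineages)
}

#' Strong-edge degree profile of TFs across lineages
#'
#' @param per_lineage_strong named list of strong-edge tables (or `"a|b"`
#'   key vectors), one per lineage.
#' @param tfs TF labels forming the rows.
#' @return integer matrix, TFs x lineages, of strong-edge degrees.
#' @export
degree_profile <- function(per_lineage_strong, tfs) {
  lineages <- names(per_lineage_strong)
  out <- matrix(0L, length(tfs), length(lineages),
                dimnames = list(tfs, lineages))
  for (l in lineages) {
    keys <- .edge_keys(per_lineage_strong[[l]])
    ends <- unlist(strsplit(keys, "|", fixed = TRUE))
    tab <- table(factor(ends, levels = tfs))
    out[, l] <- as.integer(tab)
  }
  out
}
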