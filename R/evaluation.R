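# Gold standards, averaged integrative networks, network completion, and
# ROC/AUC scoring.

.average_networks <- function(networks) {
  stopifnot(length(networks) >= 1)
  nodes <- networks[[1]]$nodes
  for (net in networks)
    if (!identical(net$nodes, nodes))
      stop("all networks must share the same node ordering")
  n <- length(nodes)
  total <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  for (net in networks) {
    w <- net$weights
    w[!net$mask] <- 0
    total <- total + w
    count <- count + net$mask
  }
  avg <- ifelse(count > 0, total / count, NA_real_)
  weighted_network(avg, mask = count > 0, nodes = nodes)
}

#' Network-averaging gold standard
#'
#' Per-pair mean of each TF pair's weight over the networks where the pair
#' is observed (missing entries excluded from the mean); pairs observed in
#' no network stay masked. The result is carried with the binarization
#' threshold used downstream.
#'
#' @param networks list of [weighted_network()] objects over the same nodes.
#' @param threshold default binarization threshold for [binarize_gold()].
#' @return object of class `gold_standard` with elements `network`,
#'   `threshold`.
#' @export
build_gold_standard_avg <- function(networks, threshold = 0.8) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(network = .average_networks(networks),
                 threshold = threshold),
            class = "gold_standard")
}

#' Averaged integrative network (AI-Net) of one lineage
#'
#' Per-pair mean of existing (observed) edges across one lineage's
#' cell-type networks -- the simple averaging baseline the factorization is
#' compared against.
#'
#' @param lineage_networks list of [weighted_network()] objects.
#' @return A [weighted_network()].
#' @export
ai_net <- function(lineage_networks) {
  .average_networks(lineage_networks)
}

#' Complete a cell-type network from its lineage AI-Net
#'
#' Masked entries of the cell-type network are filled with the AI-Net value
#' where the AI-Net observes the pair; entries masked in both stay masked.
#'
#' @param ct_net cell-type [weighted_network()].
#' @param ai_net_ lineage [ai_net()] over the same nodes.
#' @return completed [weighted_network()].
#' @export
complete_ct_net <- function(ct_net, ai_net_) {
  stopifnot(identical(ct_net$nodes, ai_net_$nodes))
  w <- ct_net$weights
  m <- ct_net$mask
  fill <- !m & ai_net_$mask
  w[fill] <- ai_net_$weights[fill]
  m[fill] <- TRUE
  weighted_network(w, mask = m, nodes = ct_net$nodes)
}

#' Binarize a gold standard at a threshold
#'
#' Label 1 when the gold weight is greater than or equal to the threshold;
#' masked pairs are excluded from evaluation entirely.
#'
#' @param gold a `gold_standard` from [build_gold_standard_avg()].
#' @param threshold binarization threshold (default: the one stored in
#'   `gold`).
#' @return data frame with columns `tf_a`, `tf_b`, `weight`, `label`.
#' @export
binarize_gold <- function(gold, threshold = gold$threshold) {
  stopifnot(inherits(gold, "gold_standard"))
  pairs <- network_pairs(gold$network)
  pairs$label <- as.integer(pairs$weight >= threshold)
  pairs
}

#' ROC curve and AUC of a score ranking against binary labels
#'
#' The ROC walks distinct score thresholds in decreasing order (tied scores
#' move as one block) and the AUC is the trapezoidal integral, which equals
#' the Mann-Whitney concordance probability with ties counting 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), same length; both classes
#'   must be present.
#' @return list with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute an ROC/AUC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- which(!duplicated(s, fromLast = TRUE))  # block boundaries
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}
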