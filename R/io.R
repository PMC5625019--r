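# Readers and writers for the supported plain-text formats. BED is read as
# 0-based half-open; "NA" encodes masked entries in matrix TSVs.

#' Read a BED file into an interval set
#'
#' Expects tab-separated columns chrom/start/end with optional name and
#' score columns; the score (column 5 when present) becomes the interval
#' score.
#'
#' @param path file path.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line(s) (need >= 3 fields): line ",
         paste(which(nf < 3L), collapse = ", "))
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start | start < 0)
  if (length(bad))
    stop("malformed BED coordinates at line ", paste(bad, collapse = ", "))
  score <- rep(NA_real_, length(parts))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(as.numeric(vapply(parts[has5], `[`, "", 5)))
  interval_set(vapply(parts, `[`, "", 1), start, end, score)
}

#' Write an interval set as BED
#'
#' @param x an [interval_set()].
#' @param path output path.
#' @param name feature-name prefix for column 4.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = "peak") {
  x <- as.data.frame(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), sprintf("%s_%d", name, seq_len(nrow(x))),
                   ifelse(is.na(x$score), ".", format(x$score, digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a weighted network as a labeled TSV matrix
#'
#' Masked entries (including the diagonal) are written as "NA".
#'
#' @param net a [weighted_network()] (or plain matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(net, path) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  utils::write.table(format(w, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labeled TSV matrix into a weighted network
#'
#' @param path file path ("NA" cells become masked entries).
#' @return A [weighted_network()].
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  weighted_network(m, nodes = rownames(m))
}

#' Read a two-column regulator/target edge list
#'
#' @param path TSV path: regulator TAB target, no header.
#' @param tf_universe optional fixed TF universe.
#' @return A [regulatory_network()].
#' @export
read_edge_list <- function(path, tf_universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed edge-list line(s): ", paste(bad, collapse = ", "))
  regulatory_network(data.frame(regulator = vapply(parts, `[`, "", 1),
                                target = vapply(parts, `[`, "", 2),
                                stringsAsFactors = FALSE),
                     tf_universe = tf_universe)
}

#' Write a regulatory network as a two-column edge list
#'
#' @param network a [regulatory_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  writeLines(sprintf("%s\t%s", network$edges$regulator,
                     network$edges$target), path)
  invisible(path)
}

#' Write an observed tensor as per-slice TSVs plus metadata
#'
#' Writes `slice_<k>.tsv` (values, "NA" for masked) and `mask_<k>.tsv`
#' per third-mode slice, plus `tensor.yaml` with shape and labels.
#'
#' @param tensor an [observed_tensor()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- tensor$shape
  labels <- tensor$labels %||% list(sprintf("i%03d", seq_len(d[1])),
                                    sprintf("j%03d", seq_len(d[2])),
                                    sprintf("k%03d", seq_len(d[3])))
  for (k in seq_len(d[3])) {
    v <- tensor$values[, , k]
    dimnames(v) <- labels[1:2]
    utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                       file.path(dir, sprintf("slice_%d.tsv", k)),
                       sep = "\t", quote = FALSE, col.names = NA)
    m <- tensor$mask[, , k] * 1L
    dimnames(m) <- labels[1:2]
    utils::write.table(m, file.path(dir, sprintf("mask_%d.tsv", k)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  yaml::write_yaml(list(shape = as.integer(d), labels = labels),
                   file.path(dir, "tensor.yaml"))
  invisible(dir)
}

#' Read a tensor written by [write_tensor()]
#'
#' @param dir directory containing `slice_*.tsv`, `mask_*.tsv`,
#'   `tensor.yaml`.
#' @return An [observed_tensor()].
#' @export
read_tensor <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "tensor.yaml"))
  d <- as.integer(meta$shape)
  vals <- array(NA_real_, d)
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    v <- as.matrix(utils::read.delim(file.path(dir, sprintf("slice_%d.tsv", k)),
                                     row.names = 1, check.names = FALSE))
    storage.mode(v) <- "double"
    m <- as.matrix(utils::read.delim(file.path(dir, sprintf("mask_%d.tsv", k)),
                                     row.names = 1, check.names = FALSE))
    vals[, , k] <- v
    mask[, , k] <- m == 1
  }
  observed_tensor(vals, mask, labels = lapply(meta$labels, as.character))
}
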