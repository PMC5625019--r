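#' Scored genomic intervals for one transcription factor
#'
#' A light container for a set of scored binding regions in the BED dialect:
#' 0-based, half-open coordinates on named sequences. This is the unit on
#' which peak merging and co-binding scoring operate.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer coordinates, 0-based half-open (`end > start`).
#' @param score numeric score per interval (e.g. mean summit height).
#' @return A data frame of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `score`.
#' @export
interval_set <- function(chrom, start, end, score = NA_real_) {
  n <- max(length(chrom), length(start))
  df <- data.frame(chrom = rep(as.character(chrom), length.out = n),
                   start = as.numeric(start),
                   end   = as.numeric(end),
                   score = rep(as.numeric(score), length.out = n),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
      stop("interval coordinates must be finite")
    if (any(df$start < 0))
      stop("negative coordinates are not allowed")
    if (any(df$end <= df$start))
      stop("every interval must satisfy end > start (0-based half-open)")
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Merge overlapping binding sites across conditions
#'
#' Collapses the union of one TF's peak sets from several conditions into
#' non-redundant binding regions: transitively overlapping intervals on the
#' same sequence are merged into one interval spanning them, and the merged
#' score is the arithmetic mean of the constituent peak scores. Abutting
#' half-open intervals (sharing only a boundary) are not merged.
#'
#' @param condition_sets a single [interval_set()] or a list of them.
#' @return An [interval_set()] whose entries are pairwise non-overlapping
#'   and sorted within each sequence.
#' @export
merge_peaks <- function(condition_sets) {
  if (inherits(condition_sets, "interval_set")) condition_sets <- list(condition_sets)
  all <- do.call(rbind, lapply(condition_sets, function(x) {
    stopifnot(is.data.frame(x))
    as.data.frame(x)[, c("chrom", "start", "end", "score")]
  }))
  if (any(all$start < 0)) stop("negative coordinates are not allowed")
  out <- lapply(split(all, all$chrom), function(sub) {
    ir <- IRanges::IRanges(start = as.integer(sub$start) + 1L,
                           end = as.integer(sub$end))
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(chrom = sub$chrom[1],
               start = IRanges::start(red) - 1L,
               end   = IRanges::end(red),
               score = vapply(revmap, function(i) mean(sub$score[i]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  interval_set(out$chrom, out$start, out$end, out$score)
}

#' Overlap p-value of one query peak against a reference peak set
#'
#' Distance-based placement null: a same-length interval is slid over every
#' valid start position in a linear domain of length `domain_length`, and the
#' p-value is the fraction of placements whose distance to the nearest
#' reference interval is at most the query's observed distance. Distance is
#' 0 for overlapping (or abutting) intervals and the gap length otherwise,
#' so an overlapping query attains the minimal possible p-value.
#'
#' When the query carries a sequence name, only reference intervals on that
#' sequence form the null (per-sequence computation is the default; the
#' domain is taken as the length of that sequence).
#'
#' @param query a single interval: a 1-row [interval_set()] or a numeric
#'   `c(start, end)` pair.
#' @param reference an [interval_set()]; must be non-empty (after restricting
#'   to the query's sequence).
#' @param domain_length length of the linear placement domain.
#' @return p-value in \[0, 1\].
#' @export
interval_overlap_pvalue <- function(query, reference, domain_length) {
  domain_length <- .stopifnot_count(domain_length, "domain_length")
  if (is.numeric(query) && length(query) == 2L) {
    qs <- query[1]; qe <- query[2]; qchrom <- NULL
  } else {
    query <- as.data.frame(query)
    if (nrow(query) != 1L) stop("'query' must be a single interval")
    qs <- query$start; qe <- query$end; qchrom <- query$chrom
  }
  if (qe <= qs) stop("query must satisfy end > start")
  ref <- as.data.frame(reference)
  if (!is.null(qchrom)) ref <- ref[ref$chrom == qchrom, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("reference interval set is empty on the query's sequence; ",
         "the overlap p-value is undefined (this is not p = 1)")
  len <- qe - qs
  if (len > domain_length) stop("query does not fit in the domain")
  n_place <- domain_length - len + 1
  # observed distance: 0 if overlapping/abutting, else gap length
  gaps <- pmax(ref$start - qe, qs - ref$end, 0)
  d_obs <- min(gaps)
  # placements p (query start) with distance <= d_obs form, per reference
  # interval [s, e), the integer range [s - len - d_obs, e + d_obs]
  lo <- pmax(0, ref$start - len - d_obs)
  hi <- pmin(n_place - 1, ref$end + d_obs)
  keep <- hi >= lo
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0L) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  count <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi + 1) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      count <- count + (cur_hi - cur_lo + 1)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  count <- count + (cur_hi - cur_lo + 1)
  count / n_place
}

#' Co-binding score between two TFs' peak sets
#'
#' Fraction of the query TF's peaks whose overlap p-value against the
#' reference TF's peak set falls below `significance` (default 0.05). The
#' score is asymmetric in (query, reference); see [symmetrize()] for the
#' network-level symmetrization. Query peaks on sequences where the
#' reference has no peaks count as non-significant.
#'
#' @param query_tf,reference_tf [interval_set()] objects.
#' @param domain_length placement-domain length passed to
#'   [interval_overlap_pvalue()].
#' @param significance p-value cut-off below which an overlap is called
#'   significant.
#' @return score in \[0, 1\].
#' @export
cobinding_score <- function(query_tf, reference_tf, domain_length,
                            significance = 0.05) {
  q <- as.data.frame(query_tf)
  if (nrow(q) == 0L) stop("query interval set is empty")
  r <- as.data.frame(reference_tf)
  sig <- vapply(seq_len(nrow(q)), function(i) {
    if (!any(r$chrom == q$chrom[i])) return(FALSE)
    interval_overlap_pvalue(q[i, , drop = FALSE], reference_tf,
                            domain_length) < significance
  }, logical(1))
  mean(sig)
}

#' Build a co-binding network from per-TF peak sets
#'
#' Computes the asymmetric co-binding score matrix over all ordered TF pairs
#' and symmetrizes it by averaging the two directions.
#'
#' @param peak_sets named list of [interval_set()] objects, one per TF.
#' @param domain_length placement-domain length.
#' @param significance per-peak overlap significance cut-off.
#' @return A [weighted_network()].
#' @export
cobinding_network <- function(peak_sets, domain_length, significance = 0.05) {
  n <- length(peak_sets)
  tfs <- names(peak_sets) %||% sprintf("TF%02d", seq_len(n))
  asym <- matrix(NA_real_, n, n, dimnames = list(tfs, tfs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    asym[i, j] <- cobinding_score(peak_sets[[i]], peak_sets[[j]],
                                  domain_length, significance)
  }
  symmetrize(asym, nodes = tfs)
}
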