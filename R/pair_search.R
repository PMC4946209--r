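# Lossless thresholded similarity join and pair bookkeeping.

#' All record pairs at or above a similarity threshold
#'
#' Finds exactly the record pairs whose cosine similarity on the requested
#' fields is `>= threshold` — the result provably equals exhaustive
#' enumeration of all n(n-1)/2 pairs. Comparisons are skipped only for
#' pairs sharing no positively weighted term (whose cosine is exactly 0),
#' via an inverted index over the corpus; everything else is computed.
#'
#' @param records records tibble from [consolidate_variants()].
#' @param indexes named list of `field_index` objects; see
#'   [build_field_index()].
#' @param threshold inclusive score threshold in `(0, 1]`. Pairs scoring
#'   exactly the threshold are included.
#' @param fields fields to score over; default `"title"`, the field with
#'   the best duplicate/non-duplicate discrimination.
#' @return tibble of class `scored_pairs` with columns `id_a`, `id_b`
#'   (record IDs, `id_a < id_b`) and `score`, sorted by `id_a`, `id_b`.
#' @export
all_pairs_above <- function(records, indexes, threshold = 0.5,
                            fields = "title") {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single value in (0, 1]", call. = FALSE)
  }
  trip <- corpus_triplets(records, indexes, fields = fields)
  n <- nrow(records)
  # L2-normalize rows on the triplet representation
  norms <- numeric(n)
  agg <- rowsum(trip$x^2, group = trip$i)
  norms[as.integer(rownames(agg))] <- sqrt(agg[, 1])
  x <- trip$x / norms[trip$i]
  n_terms <- trip$n_features
  # per-record feature lists in decreasing-weight order
  row_ord <- order(trip$i, -x)
  row_ptr <- c(0L, cumsum(tabulate(trip$i, nbins = n)))
  # per-term posting lists in increasing-record order
  col_ord <- order(trip$j, trip$i)
  col_ptr <- c(0L, cumsum(tabulate(trip$j, nbins = n_terms)))
  res <- pair_join_sorted(
    row_ptr, trip$j[row_ord] - 1L, x[row_ord],
    col_ptr, trip$i[col_ord] - 1L, x[col_ord],
    n, threshold
  )
  ids <- canonical_pairs(
    records$record_id[res$i],
    records$record_id[res$j]
  )
  out <- tibble(id_a = ids$id_a, id_b = ids$id_b, score = res$score)
  out <- out[order(out$id_a, out$id_b), ]
  class(out) <- c("scored_pairs", class(out))
  out
}

#' Total number of pairwise comparisons
#'
#' The exact number of unordered record pairs, n(n-1)/2, returned as a
#' double so that counts beyond the 32-bit integer range stay exact.
#'
#' @param n number of records (non-negative).
#' @return exact pair count.
#' @export
#' @examples
#' count_total_comparisons(285177)
count_total_comparisons <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Split scored pairs into known duplicates and candidates
#'
#' A pair is a *known* duplicate when both records fall in the same
#' duplicate group (they are linked, directly or transitively, by secondary
#' IDs); every other pair is a *candidate* — possibly a hidden duplicate.
#'
#' @param pairs `scored_pairs` tibble from [all_pairs_above()].
#' @param groups `duplicate_group_set` from [build_groups()].
#' @return the pairs tibble with an added logical column `known`.
#' @export
partition_known <- function(pairs, groups) {
  membership <- group_membership(groups)
  ga <- membership[pairs$id_a]
  gb <- membership[pairs$id_b]
  pairs$known <- !is.na(ga) & !is.na(gb) & ga == gb
  pairs
}

#' Score-range partition
#'
#' Builds contiguous half-open ranges `(lo, hi]` from a breaks vector, the
#' convention under which a score of exactly 0.8 falls in `(0.7, 0.8]`.
#'
#' @param breaks increasing numeric vector of range boundaries; default
#'   `seq(0.5, 1, 0.1)` giving the five ranges used throughout.
#' @return tibble with columns `lo` and `hi`, one row per range.
#' @export
score_ranges <- function(breaks = seq(0.5, 1, by = 0.1)) {
  if (length(breaks) < 2L || any(diff(breaks) <= 0)) {
    stop("`breaks` must be increasing with at least two values", call. = FALSE)
  }
  tibble(lo = breaks[-length(breaks)], hi = breaks[-1])
}

# Range index for each score under the (lo, hi] convention; errors when a
# score falls outside all ranges (threshold/range mismatch).
range_index <- function(score, ranges) {
  breaks <- c(ranges$lo[1], ranges$hi)
  idx <- findInterval(score, breaks, left.open = TRUE)
  bad <- idx < 1L | idx > nrow(ranges)
  if (any(bad)) {
    stop(
      "scores outside the range partition: e.g. ", signif(score[bad][1], 6),
      call. = FALSE
    )
  }
  idx
}

#' Histogram of pairs by score range
#'
#' Counts, for each range `(lo, hi]`, the total, known-duplicate and
#' candidate pairs. Totals are conserved: range totals sum to `nrow(pairs)`.
#'
#' @param pairs pairs tibble with a `known` column (see
#'   [partition_known()]).
#' @param ranges range partition from [score_ranges()]; must cover every
#'   score, else an error is raised.
#' @return tibble with columns `lo`, `hi`, `total`, `known`, `candidate`.
#' @export
range_histogram <- function(pairs, ranges = score_ranges()) {
  if (!"known" %in% names(pairs)) {
    stop("`pairs` must carry a `known` column; see partition_known()",
      call. = FALSE
    )
  }
  idx <- range_index(pairs$score, ranges)
  f <- factor(idx, levels = seq_len(nrow(ranges)))
  total <- as.integer(table(f))
  known <- as.integer(table(f[pairs$known]))
  tibble(
    lo = ranges$lo, hi = ranges$hi,
    total = total, known = known, candidate = total - known
  )
}
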