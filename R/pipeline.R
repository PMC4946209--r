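# Convenience driver chaining the full analysis.

#' Run the full hidden-duplicate analysis on a variants table
#'
#' Chains consolidation, secondary-ID linkage, title indexing, the
#' lossless similarity join at the threshold, known/candidate
#' partitioning, stratified candidate sampling rated by `rate_fun`, and
#' extrapolation to the overall hidden-duplicate percentage.
#'
#' @param variants variants tibble ([parse_corpus()] or
#'   [generate_corpus()]`$variants`).
#' @param rate_fun rating function for sampled candidate pairs; see
#'   [estimate_hidden()]. For synthetic corpora use [truth_oracle()], for
#'   real data a lookup into imported ratings, or [adjudicate_pairs()]
#'   wrapped in a closure.
#' @param threshold similarity threshold for the pair search.
#' @param ranges score-range partition; defaults to five ranges of width
#'   0.1 over (0.5, 1].
#' @param n_per_range sample size per range (capped at each pool).
#' @param seed integer seed governing all sampling.
#' @param conf confidence level.
#' @return list with `records`, `groups`, `pairs`, `trial_counts` (from
#'   [count_unique_trials()]), `histogram` and `estimate` (the
#'   [estimate_hidden()] result).
#' @export
run_hidden_duplicate_study <- function(variants, rate_fun, threshold = 0.5,
                                       ranges = score_ranges(),
                                       n_per_range = 100L, seed = 1L,
                                       conf = 0.95) {
  records <- consolidate_variants(variants)
  edges <- match_ids_to_records(records)
  groups <- build_groups(edges, records$record_id)
  counts <- count_unique_trials(groups)
  indexes <- list(title = build_field_index(records, "title"))
  pairs <- all_pairs_above(records, indexes, threshold = threshold)
  pairs <- partition_known(pairs, groups)
  kp <- known_pairs(groups)
  est <- estimate_hidden(
    pairs,
    total_known_pairs = nrow(kp),
    rate_fun = rate_fun,
    ranges = ranges,
    n_per_range = n_per_range,
    seed = seed,
    conf = conf,
    n_unique_trials = counts$n_trials
  )
  hist <- range_histogram(pairs[pairs$score > ranges$lo[1], ], ranges)
  list(
    records = records,
    groups = groups,
    pairs = pairs,
    trial_counts = counts,
    histogram = hist,
    estimate = est
  )
}

#' Observational summary figures for a registry snapshot
#'
#' Computes, for a supplied corpus, the descriptive figures usually quoted
#' for a full registry snapshot: record and known-duplicate-pair counts,
#' the number of pairs at or above the similarity threshold, the median
#' title score of known duplicates and the fraction of known duplicates
#' scoring above the threshold. These are observational (dataset-dependent)
#' quantities for comparison against an archived snapshot, not test
#' targets.
#'
#' @param records records tibble from [consolidate_variants()].
#' @param groups `duplicate_group_set` from [build_groups()].
#' @param pairs scored pairs from [all_pairs_above()].
#' @param threshold the threshold `pairs` was computed at.
#' @return tibble with columns `quantity` and `value`.
#' @export
snapshot_checks <- function(records, groups, pairs, threshold = 0.5) {
  kp <- known_pairs(groups)
  indexes <- list(title = build_field_index(records, "title"))
  m <- corpus_matrix(records, indexes, fields = "title")
  ia <- match(kp$id_a, records$record_id)
  ib <- match(kp$id_b, records$record_id)
  known_scores <- if (nrow(kp) > 0L) {
    Matrix::rowSums(m[ia, , drop = FALSE] * m[ib, , drop = FALSE])
  } else {
    numeric(0)
  }
  tibble(
    quantity = c(
      "n_records", "n_known_pairs", "n_pairs_at_or_above_threshold",
      "median_known_title_score", "fraction_known_above_threshold"
    ),
    value = c(
      nrow(records),
      nrow(kp),
      nrow(pairs),
      if (length(known_scores)) stats::median(known_scores) else NA_real_,
      if (length(known_scores)) mean(known_scores > threshold) else NA_real_
    )
  )
}
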