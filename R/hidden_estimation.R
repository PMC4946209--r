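# Estimation of hidden duplicates by stratified sampling of candidate
# pairs with exact binomial inference.
#
# For each similarity-score range, a without-replacement sample of
# candidate pairs (pairs not known to be duplicates) is manually rated;
# the binomial proportion of true duplicates, scaled by the candidate-pool
# size, estimates the number of hidden duplicates in the range. Exact
# Clopper-Pearson bounds for the proportion are pushed through the same
# formula, which is valid because the hidden percentage is strictly
# increasing in the proportion. Extrapolation beyond the examined ranges
# divides by the fraction of known-duplicate pairs the ranges cover,
# assuming a duplicate's probability of being hidden does not depend on
# its similarity score.

#' Sample candidate pairs from a score range
#'
#' Uniform without-replacement sample of candidate pairs whose score lies
#' in `(lo, hi]`, reproducible under a fixed seed.
#'
#' @param pairs pairs tibble with `known` column ([partition_known()]).
#' @param lo,hi range bounds, convention `lo < score <= hi`.
#' @param n sample size; must not exceed the candidate pool.
#' @param seed integer seed.
#' @return an object of class `range_sample`: list with `lo`, `hi`, `n`,
#'   `seed`, `pool` (pool size) and `pairs` (the sampled rows).
#' @export
sample_candidates <- function(pairs, lo, hi, n, seed) {
  pool <- pairs[!pairs$known & pairs$score > lo & pairs$score <= hi, ]
  if (n > nrow(pool)) {
    stop(
      "sample size ", n, " exceeds candidate pool (", nrow(pool),
      ") in range (", lo, ", ", hi, "]",
      call. = FALSE
    )
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  structure(
    list(lo = lo, hi = hi, n = n, seed = seed, pool = nrow(pool),
         pairs = pool[sort(idx), ]),
    class = "range_sample"
  )
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact (conservative) interval obtained by inverting binomial tail
#' probabilities, computed through the beta-quantile formulation. The lower
#' bound is exactly 0 when `x = 0` and the upper bound exactly 1 when
#' `x = n`.
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf confidence level in (0, 1); default 0.95.
#' @return numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' clopper_pearson(13, 100)
clopper_pearson <- function(x, n, conf = 0.95) {
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
    is.na(x) || is.na(n) || n < 1 || x < 0 || x > n ||
    x != floor(x) || n != floor(n)) {
    stop("need integer counts with 0 <= x <= n", call. = FALSE)
  }
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1) {
    stop("`conf` must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

# Percentage of duplicates hidden, given an estimated number of unknown
# duplicate pairs and the known pairs in the same range. Strictly
# increasing in `unknown`, so CI endpoints map through monotonically.
pct_hidden_formula <- function(unknown, known) {
  100 * unknown / (known + unknown)
}

#' Per-range hidden-duplicate estimate
#'
#' From `x` duplicates in a rated sample of `n` candidate pairs, with
#' `n_candidates` candidate pairs and `n_known` known-duplicate pairs in
#' the range: the estimated number of unknown duplicates is
#' `(x/n) * n_candidates`, and the percentage of duplicates hidden is
#' `100 * unknown / (known + unknown)`. Clopper-Pearson bounds on `x/n`
#' are mapped through the same formula.
#'
#' @param x duplicates found in the sample.
#' @param n sample size.
#' @param n_candidates candidate pairs in the range (> 0).
#' @param n_known known-duplicate pairs in the range.
#' @param conf confidence level; default 0.95.
#' @param lo,hi optional range bounds, carried through for reporting.
#' @return an object of class `range_estimate`: list with `lo`, `hi`, `x`,
#'   `n`, `p_hat`, `p_ci` (length-2), `n_candidates`, `n_known`,
#'   `unknown_est`, `unknown_ci`, `pct_hidden` and `pct_ci` (unrounded;
#'   round at reporting time with [round_half_up()]).
#' @export
#' @examples
#' est <- estimate_range(x = 13, n = 100, n_candidates = 17423, n_known = 3489)
#' round_half_up(est$pct_hidden)
#' round_half_up(est$pct_ci)
estimate_range <- function(x, n, n_candidates, n_known, conf = 0.95,
                           lo = NA_real_, hi = NA_real_) {
  if (n_candidates <= 0) {
    stop("`n_candidates` must be positive", call. = FALSE)
  }
  if (n_known < 0) {
    stop("`n_known` must be non-negative", call. = FALSE)
  }
  p_hat <- x / n
  p_ci <- clopper_pearson(x, n, conf)
  unknown_est <- p_hat * n_candidates
  unknown_ci <- p_ci * n_candidates
  if (n_known + unknown_est == 0) {
    stop("no known and no estimated unknown duplicates: percentage hidden undefined",
      call. = FALSE
    )
  }
  structure(
    list(
      lo = lo, hi = hi, x = x, n = n,
      p_hat = p_hat, p_ci = unname(p_ci),
      n_candidates = n_candidates, n_known = n_known,
      unknown_est = unknown_est, unknown_ci = unname(unknown_ci),
      pct_hidden = pct_hidden_formula(unknown_est, n_known),
      pct_ci = unname(pct_hidden_formula(unknown_ci, n_known))
    ),
    class = "range_estimate"
  )
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf(
    "<range_estimate> (%s, %s]: %d/%d duplicates, unknown ~ %.0f, %% hidden %.0f (%.0f-%.0f)\n",
    format(x$lo), format(x$hi), x$x, x$n, x$unknown_est,
    round_half_up(x$pct_hidden), round_half_up(x$pct_ci[1]),
    round_half_up(x$pct_ci[2])
  ))
  invisible(x)
}

#' Extrapolate range estimates to an overall hidden percentage
#'
#' Sums the estimated unknown duplicates over the examined ranges, divides
#' by the fraction of known-duplicate pairs those ranges cover (assuming
#' hiddenness is independent of similarity score), and converts to the
#' overall percentage of duplicates hidden. Confidence bounds are obtained
#' by carrying each range's Clopper-Pearson bounds through the same sum —
#' a conservative interval for the total. Optionally adjusts a
#' unique-trial count by subtracting one trial per estimated hidden pair
#' (an approximation ignoring overlaps of three or more records).
#'
#' @param range_estimates list of `range_estimate` objects.
#' @param coverage fraction (0, 1] of known-duplicate pairs inside the
#'   examined ranges.
#' @param total_known_pairs total known-duplicate pairs in the corpus.
#' @param n_unique_trials optional unique-trial count to adjust.
#' @return an object of class `overall_estimate`: list with `coverage`,
#'   `total_known_pairs`, `unknown_total_est`, `unknown_total_ci`,
#'   `pct_hidden_overall`, `pct_ci` and `unique_trials_adjusted` (NA when
#'   `n_unique_trials` is missing).
#' @export
extrapolate_overall <- function(range_estimates, coverage, total_known_pairs,
                                n_unique_trials = NULL) {
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
    coverage <= 0 || coverage > 1) {
    stop("`coverage` must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(range_estimates) > 0L)
  unknown <- sum(vapply(range_estimates, function(e) e$unknown_est, numeric(1)))
  unknown_lo <- sum(vapply(range_estimates, function(e) e$unknown_ci[1], numeric(1)))
  unknown_hi <- sum(vapply(range_estimates, function(e) e$unknown_ci[2], numeric(1)))
  total <- unknown / coverage
  total_ci <- c(unknown_lo, unknown_hi) / coverage
  structure(
    list(
      coverage = coverage,
      total_known_pairs = total_known_pairs,
      unknown_total_est = total,
      unknown_total_ci = total_ci,
      pct_hidden_overall = pct_hidden_formula(total, total_known_pairs),
      pct_ci = pct_hidden_formula(total_ci, total_known_pairs),
      unique_trials_adjusted = if (is.null(n_unique_trials)) {
        NA_real_
      } else {
        n_unique_trials - round_half_up(total)
      }
    ),
    class = "overall_estimate"
  )
}

#' @export
print.overall_estimate <- function(x, ...) {
  cat(sprintf(
    "<overall_estimate> %% hidden %.1f (%.1f-%.1f), unknown pairs ~ %.0f at coverage %.2f\n",
    x$pct_hidden_overall, x$pct_ci[1], x$pct_ci[2],
    x$unknown_total_est, x$coverage
  ))
  invisible(x)
}

#' Sample size needed to bound a proportion
#'
#' Smallest `n` such that, with the expected success count
#' `round_half_up(p_expected * n)`, the Clopper-Pearson interval lies
#' within `[lo_target, hi_target]`. Used to decide whether sampling the
#' next score range is affordable.
#'
#' @param p_expected expected proportion, strictly between the targets.
#' @param lo_target,hi_target bounds the interval must fall within.
#' @param conf confidence level; default 0.95.
#' @param n_max search ceiling; exceeded means the targets are
#'   unattainable and is an error.
#' @return smallest satisfying sample size (integer).
#' @export
required_sample_size <- function(p_expected, lo_target, hi_target,
                                 conf = 0.95, n_max = 100000L) {
  if (!(lo_target < p_expected && p_expected < hi_target)) {
    stop("need lo_target < p_expected < hi_target", call. = FALSE)
  }
  if (lo_target < 0 || hi_target > 1) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  for (n in seq_len(n_max)) {
    x <- round_half_up(p_expected * n)
    ci <- clopper_pearson(x, n, conf)
    if (ci[1] >= lo_target && ci[2] <= hi_target) {
      return(as.integer(n))
    }
  }
  stop("no sample size up to ", n_max, " attains the targets", call. = FALSE)
}

#' End-to-end hidden-duplicate estimation on scored pairs
#'
#' Runs the full sampling design: histogram the scored pairs over the
#' ranges, draw a candidate sample per range, rate it with `rate_fun`,
#' estimate each range, and extrapolate using the known-pair coverage of
#' the examined ranges.
#'
#' @param pairs pairs tibble with `known` column ([partition_known()]);
#'   pairs scoring at or below the lowest range bound are excluded.
#' @param total_known_pairs total known-duplicate pairs in the corpus
#'   (including those scoring below every range).
#' @param rate_fun function taking the sampled pairs tibble and returning a
#'   verdict per row, one of `"duplicate"`, `"non_duplicate"`, `"unknown"`
#'   (e.g. a lookup into imported human ratings, the [adjudicate_pairs()]
#'   rule engine, or a synthetic-truth oracle). Only `"duplicate"`
#'   verdicts count as successes.
#' @param ranges range partition from [score_ranges()].
#' @param n_per_range target sample size per range (capped at the pool).
#' @param seed integer seed for all sampling.
#' @param conf confidence level.
#' @param n_unique_trials optional unique-trial count to adjust.
#' @return list with `ranges` (tibble: one row per examined range with
#'   counts, estimates and CI bounds), `estimates` (list of
#'   `range_estimate`), `overall` (`overall_estimate`) and `coverage`.
#' @export
estimate_hidden <- function(pairs, total_known_pairs, rate_fun,
                            ranges = score_ranges(), n_per_range = 100L,
                            seed = 1L, conf = 0.95, n_unique_trials = NULL) {
  pairs <- pairs[pairs$score > ranges$lo[1], ]
  hist <- range_histogram(pairs, ranges)
  coverage <- if (total_known_pairs > 0) {
    sum(hist$known) / total_known_pairs
  } else {
    1
  }
  coverage <- min(coverage, 1)
  estimates <- list()
  rows <- list()
  for (k in seq_len(nrow(ranges))) {
    n_cand <- hist$candidate[k]
    n_known <- hist$known[k]
    if (n_cand == 0L) next
    n_take <- min(n_per_range, n_cand)
    smp <- sample_candidates(
      pairs, ranges$lo[k], ranges$hi[k], n_take,
      seed = seed + k
    )
    verdicts <- rate_fun(smp$pairs)
    x <- sum(verdicts == "duplicate")
    est <- estimate_range(
      x, n_take, n_cand, n_known, conf,
      lo = ranges$lo[k], hi = ranges$hi[k]
    )
    estimates[[length(estimates) + 1L]] <- est
    rows[[length(rows) + 1L]] <- tibble(
      lo = ranges$lo[k], hi = ranges$hi[k],
      n_known = n_known, n_candidates = n_cand,
      x = x, n = n_take,
      p_hat = est$p_hat,
      unknown_est = est$unknown_est,
      pct_hidden = est$pct_hidden,
      pct_lo = est$pct_ci[1], pct_hi = est$pct_ci[2]
    )
  }
  if (length(estimates) == 0L) {
    stop("no range contained candidate pairs", call. = FALSE)
  }
  if (coverage <= 0) {
    stop("no known pairs fall inside the examined ranges; coverage is zero",
      call. = FALSE
    )
  }
  overall <- extrapolate_overall(
    estimates, coverage, total_known_pairs,
    n_unique_trials
  )
  list(
    ranges = do.call(rbind, rows),
    estimates = estimates,
    overall = overall,
    coverage = coverage
  )
}
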