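# Shared fixtures and oracles, built in code.

# Minimal variants table from titles (+ optional extras), for corner-case
# corpora the generator would not produce.
variants_from_titles <- function(titles,
                                 ids = sprintf("NCT%08d", seq_along(titles)),
                                 registry = "ClinicalTrials.gov",
                                 secondary_ids = NULL,
                                 sponsors = NULL,
                                 dates = as.Date("2010-01-01") + seq_along(titles)) {
  n <- length(titles)
  tibble::tibble(
    registry_id = ids,
    registry = rep_len(registry, n),
    variant_suffix = rep("", n),
    public_title = titles,
    scientific_title = rep("", n),
    acronym = rep("", n),
    secondary_ids = secondary_ids %||% rep(list(character(0)), n),
    conditions = rep(list(character(0)), n),
    interventions = rep(list(character(0)), n),
    outcomes = rep(list(character(0)), n),
    inclusion_criteria = rep("", n),
    sponsors = sponsors %||% rep(list(character(0)), n),
    date_registered = dates,
    date_enrolment = as.Date(rep(NA, n)),
    countries = rep(list(character(0)), n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force all-pairs enumeration oracle: dense cosine on the normalized
# record-by-feature matrix, thresholded. Independent of the inverted-index
# join path.
brute_force_pairs <- function(records, indexes, threshold, fields = "title") {
  m <- trialdedup:::corpus_matrix(records, indexes, fields = fields)
  sims <- as.matrix(Matrix::tcrossprod(m))
  hit <- which(upper.tri(sims) & sims >= threshold - 1e-12, arr.ind = TRUE)
  a <- rownames(sims)[hit[, 1]]
  b <- colnames(sims)[hit[, 2]]
  out <- tibble::tibble(
    id_a = pmin(a, b), id_b = pmax(a, b),
    score = sims[hit]
  )
  out[order(out$id_a, out$id_b), ]
}

pair_keys <- function(pairs) paste(pairs$id_a, pairs$id_b)

# A consolidated synthetic corpus of moderate size, reused across tests.
small_study <- function(n_trials = 400, seed = 42, ...) {
  corp <- generate_corpus(generator_params(
    n_trials = n_trials, seed = seed, ...
  ))
  records <- consolidate_variants(corp$variants)
  list(corpus = corp, records = records, truth = corp$truth)
}
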