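test_that("US federal grant numbers are recognized and other IDs are not", {
  expect_true(is_grant_number("R01HL123456"))
  expect_true(is_grant_number("5R01HL123456-02"))
  expect_true(is_grant_number("U01AI069423"))
  expect_false(is_grant_number("2011-004388-62"))
  expect_false(is_grant_number("NCT01472939"))
  expect_false(is_grant_number("SP042-0137"))
  expect_false(is_grant_number(""))
})

test_that("contradictory titles require near-identity plus an antonym or extension marker", {
  expect_true(contradictory_titles(
    "Bioavailability of drug X under fed conditions",
    "Bioavailability of drug X under fasting conditions"
  ))
  expect_false(contradictory_titles(
    "Bioavailability of drug X under fed conditions",
    "Bioavailability of drug X under fed conditions"
  ))
  # antonyms present but titles otherwise dissimilar: rule does not fire
  expect_false(contradictory_titles(
    "Aspirin after fed state dosing",
    "Zinc supplementation fasting cohort outcomes"
  ))
  # extension marker on exactly one side of near-identical titles
  expect_true(contradictory_titles(
    "Drug X in rheumatoid arthritis",
    "Drug X in rheumatoid arthritis extension"
  ))
  expect_false(contradictory_titles(
    "Drug X in rheumatoid arthritis extension",
    "Drug X in rheumatoid arthritis extension"
  ))
})

pair_records <- function(title_a, title_b, ids_a, ids_b,
                         sponsor_a = "Sponsor A", sponsor_b = "Sponsor A",
                         dates = as.Date(c("2011-05-01", "2011-06-01"))) {
  v <- variants_from_titles(
    c(title_a, title_b),
    ids = c("NCT00000001", "ISRCTN00000002"),
    secondary_ids = list(ids_a, ids_b),
    sponsors = list(sponsor_a, sponsor_b),
    dates = dates
  )
  v$registry <- c("ClinicalTrials.gov", "ISRCTN")
  consolidate_variants(v)
}

test_that("rules fire in precedence order on planted pairs", {
  # rule 2: shared sponsor + shared strong secondary ID -> duplicate
  rec <- pair_records(
    "Drug X in asthma", "Study of drug X in asthmatic patients",
    "PROTO-991", "PROTO-991"
  )
  j <- adjudicate_pair(rec[1, ], rec[2, ])
  expect_equal(j$verdict, "duplicate")
  expect_equal(j$fired_rule, "shared_strong_id")

  # grant numbers never count as identifying IDs
  rec <- pair_records(
    "Drug X in asthma", "Completely different topic entirely",
    "R01HL123456", "R01HL123456"
  )
  expect_equal(adjudicate_pair(rec[1, ], rec[2, ])$verdict, "non_duplicate")

  # rule 3: shared sponsor + distinct same-format IDs -> non-duplicate
  rec <- pair_records(
    "Drug X in asthma", "Drug X in asthma second cohort",
    "ABC-0001", "ABC-0002"
  )
  j <- adjudicate_pair(rec[1, ], rec[2, ])
  expect_equal(j$verdict, "non_duplicate")
  expect_equal(j$fired_rule, "same_format_distinct_ids")

  # rule 1 precedes rule 2: contradiction wins over a shared ID
  rec <- pair_records(
    "Drug X dosing under fed conditions",
    "Drug X dosing under fasting conditions",
    "PROTO-991", "PROTO-991"
  )
  j <- adjudicate_pair(rec[1, ], rec[2, ])
  expect_equal(j$verdict, "non_duplicate")
  expect_equal(j$fired_rule, "contradictory_titles")

  # rule 4: similar titles, compatible dates and sponsors (IDs in
  # different formats, so rule 3 stays silent)
  rec <- pair_records(
    "Randomized trial of drug X in severe asthma",
    "Randomized trial of drug X in severe asthma patients",
    "IDAA-01", "ZX-99382"
  )
  j <- adjudicate_pair(rec[1, ], rec[2, ])
  expect_equal(j$verdict, "duplicate")
  expect_equal(j$fired_rule, "field_similarity")

  # rule 4 blocked by contradictory start dates -> doubt -> non-duplicate
  rec <- pair_records(
    "Randomized trial of drug X in severe asthma",
    "Randomized trial of drug X in severe asthma patients",
    "IDAA-01", "ZX-99382",
    dates = as.Date(c("2008-01-01", "2013-01-01"))
  )
  j <- adjudicate_pair(rec[1, ], rec[2, ])
  expect_equal(j$verdict, "non_duplicate")
  expect_equal(j$fired_rule, "default_doubt")

  # rule 5: mid similarity, no cues
  rec <- pair_records(
    "Drug X asthma study", "Drug X chronic sinusitis evaluation",
    "IDA-1", "IDB-2",
    sponsor_a = "Sponsor A", sponsor_b = "Sponsor B"
  )
  expect_equal(adjudicate_pair(rec[1, ], rec[2, ])$verdict, "non_duplicate")
})

test_that("verdicts are symmetric in the pair order", {
  s <- small_study(n_trials = 120, seed = 303)
  rec <- s$records
  set.seed(8)
  for (k in 1:25) {
    ij <- sample(nrow(rec), 2)
    ja <- adjudicate_pair(rec[ij[1], ], rec[ij[2], ])
    jb <- adjudicate_pair(rec[ij[2], ], rec[ij[1], ])
    expect_equal(ja$verdict, jb$verdict)
  }
})

test_that("the rule engine agrees with planted truth at low noise", {
  s <- small_study(n_trials = 400, seed = 505, title_perturbation = 0.03)
  rec <- s$records
  tp <- truth_pairs(s$truth)
  set.seed(31)
  neg_a <- sample(rec$record_id, 150)
  neg_b <- sample(rec$record_id, 150)
  trial_of <- setNames(s$truth$records$trial_id, s$truth$records$record_id)
  ok <- neg_a != neg_b & trial_of[neg_a] != trial_of[neg_b]
  eval_pairs <- tibble::tibble(
    id_a = c(tp$id_a, neg_a[ok]),
    id_b = c(tp$id_b, neg_b[ok]),
    truth = c(rep("duplicate", nrow(tp)), rep("non_duplicate", sum(ok)))
  )
  got <- adjudicate_pairs(eval_pairs, rec)
  agreement <- mean(got$verdict == eval_pairs$truth)
  expect_gt(agreement, 0.9)
})

test_that("ratings round-trip through TSV and invalid verdicts are rejected with a line number", {
  ratings <- tibble::tibble(
    id_a = sprintf("NCT%08d", 1:100),
    id_b = sprintf("ISRCTN%08d", 1:100),
    verdict = sample(c("duplicate", "non_duplicate", "unknown"), 100, replace = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratings(ratings, path)
  back <- read_ratings(path)
  expect_equal(back, ratings)

  bad <- ratings
  bad$verdict[42] <- "maybe"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c("id_a\tid_b\tverdict", paste(bad$id_a, bad$id_b, bad$verdict, sep = "\t")),
    path2
  )
  expect_error(read_ratings(path2), "line 43")
  expect_error(write_ratings(bad, path2), "row 42")

  # merging ratings with a sample counts duplicate verdicts as successes
  x <- sum(back$verdict == "duplicate")
  lookup <- setNames(back$verdict, paste(back$id_a, back$id_b))
  expect_equal(sum(lookup[paste(ratings$id_a, ratings$id_b)] == "duplicate"), x)
})
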