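test_that("secondary-ID strings split on whitespace and ,;. into tokens", {
  expect_equal(
    tokenize_secondary_ids("NCT01472939; 2011-004388-62")$token,
    c("NCT01472939", "2011-004388-62")
  )
  expect_equal(tokenize_secondary_ids("Version 1")$token, c("Version", "1"))
  expect_equal(nrow(tokenize_secondary_ids(character(0))), 0L)
  # "." is a separator, so dotted identifiers are split
  expect_equal(
    tokenize_secondary_ids("ABC.DEF,GHI")$token,
    c("ABC", "DEF", "GHI")
  )
  expect_equal(tokenize_secondary_ids(";;  ; ")$token, character(0))
})

euctr_nct_corpus <- function(nct_secondary) {
  v <- rbind(
    variants_from_titles("EU record",
      ids = "EUCTR2011-004388-62-BE", registry = "EUCTR"
    ),
    variants_from_titles("US record",
      ids = "NCT01472939",
      secondary_ids = list(nct_secondary)
    )
  )
  consolidate_variants(v)
}

test_that("tokens match registry IDs, with relaxed EUCTR prefix and country code", {
  for (tok in c(
    "2011-004388-62", # bare EudraCT number
    "EUCTR2011-004388-62", # stem
    "EUCTR2011-004388-62-BE", # full variant ID
    "2011-004388-62-CZ", # country code without prefix
    "euctr2011-004388-62" # case-insensitive
  )) {
    rec <- euctr_nct_corpus(tok)
    edges <- match_ids_to_records(rec)
    expect_equal(edges$id_a, "EUCTR2011-004388-62", info = tok)
    expect_equal(edges$id_b, "NCT01472939", info = tok)
  }
  # no such record, nonsense stop-list, short tokens: no edges
  for (tok in c("NCT99999999", "none", "123", "U234")) {
    rec <- euctr_nct_corpus(tok)
    expect_equal(nrow(match_ids_to_records(rec)), 0L, info = tok)
  }
  # self-references are discarded
  v <- variants_from_titles("self", ids = "NCT00000007",
    secondary_ids = list("NCT00000007")
  )
  expect_equal(nrow(match_ids_to_records(consolidate_variants(v))), 0L)
})

test_that("ID matching equals a brute-force scan over all (token, record) pairs", {
  s <- small_study(n_trials = 400, seed = 21)
  rec <- s$records
  got <- match_ids_to_records(rec)

  stop <- tolower(nonsense_id_stoplist())
  oracle <- list()
  for (r in seq_len(nrow(rec))) {
    toks <- tokenize_secondary_ids(rec$secondary_ids[[r]])$token
    toks <- trimws(toks)
    toks <- toks[nchar(toks) >= 4 & !(tolower(toks) %in% stop)]
    toks <- trialdedup:::canonicalize_id_token(toks)
    for (sdx in seq_len(nrow(rec))) {
      if (sdx == r) next
      if (toupper(rec$record_id[sdx]) %in% toks) {
        pr <- sort(c(rec$record_id[r], rec$record_id[sdx]))
        oracle[[paste(pr, collapse = " ")]] <- TRUE
      }
    }
  }
  expect_setequal(pair_keys(got), names(oracle))
  expect_gt(nrow(got), 0L)
})

test_that("groups are the transitive closure over edges, order-independent", {
  recs <- LETTERS[1:6]
  edges <- tibble::tibble(
    id_a = c("A", "B"), id_b = c("B", "C"), reason = "secondary_id"
  )
  g <- build_groups(edges, recs)
  m <- setNames(g$membership$group_id, g$membership$record_id)
  expect_equal(unname(m["A"]), unname(m["C"]))
  expect_equal(g$n_groups, 4L) # {A,B,C} + 3 singletons

  # no edges: all singletons
  g0 <- build_groups(edges[0, ], recs)
  expect_equal(g0$n_groups, 6L)

  # invariance to edge and record order
  g2 <- build_groups(edges[2:1, ], rev(recs))
  expect_equal(g$membership, g2$membership)

  # adding an edge never increases the group count
  g3 <- build_groups(rbind(edges, tibble::tibble(
    id_a = "D", id_b = "E", reason = "secondary_id"
  )), recs)
  expect_lte(g3$n_groups, g$n_groups)

  # conservation: n_groups + sum(size - 1) = n_records
  sizes <- table(g$membership$group_id)
  expect_equal(g$n_groups + sum(sizes - 1), length(recs))
})

test_that("unique-trial counts and known pairs follow group arithmetic", {
  recs <- sprintf("R%02d", 1:10)
  edges <- tibble::tibble(
    id_a = c("R01", "R01"), id_b = c("R02", "R03"), reason = "secondary_id"
  )
  g <- build_groups(edges, recs)
  counts <- count_unique_trials(g)
  expect_equal(counts$n_trials, 8L)
  expect_equal(counts$n_records_with_duplicates, 3L)
  expect_equal(nrow(known_pairs(g)), 3L) # C(3,2)

  # one group of 10
  full <- tibble::tibble(
    id_a = rep("R01", 9), id_b = recs[-1], reason = "secondary_id"
  )
  expect_equal(nrow(known_pairs(build_groups(full, recs))), 45L)
})

test_that("linkage on a planted corpus recovers exactly the known clusters", {
  s <- small_study(n_trials = 800, seed = 33)
  edges <- match_ids_to_records(s$records)
  g <- build_groups(edges, s$records$record_id)
  got <- known_pairs(g)
  want <- truth_pairs(s$truth)
  want <- want[want$known, ]
  expect_identical(pair_keys(got), pair_keys(want))

  # arithmetic identity against planted truth
  counts <- count_unique_trials(g)
  sizes <- table(g$membership$group_id)
  expect_equal(counts$n_trials, nrow(s$records) - sum(sizes - 1))
})

test_that("UTN tokens of the exact WHO shape link records", {
  v <- rbind(
    variants_from_titles("German record",
      ids = "DRKS00005274", registry = "JPRN",
      secondary_ids = list("U1111-1147-8393")
    ),
    variants_from_titles("US record",
      ids = "NCT02139163",
      secondary_ids = list("U1111-1147-8393")
    ),
    variants_from_titles("lone UTN",
      ids = "NCT00000002",
      secondary_ids = list("U1111-0000-0001")
    ),
    variants_from_titles("wrong shape",
      ids = "NCT00000003",
      secondary_ids = list(c("U1111-12-3", "U1111-1147-8393x"))
    )
  )
  rec <- consolidate_variants(v)
  edges <- match_by_utn(rec)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$id_a, "DRKS00005274")
  expect_equal(edges$id_b, "NCT02139163")
  expect_equal(edges$reason, "utn")
})

test_that("external ID lists match only under the sponsor filter, per a cross-join oracle", {
  s <- small_study(n_trials = 100, seed = 55, dup_rate = 0.2)
  rec <- s$records
  # plant: one sponsor's protocol IDs as the external list
  sponsor <- rec$sponsors[[1]][1]
  ids <- unique(unlist(lapply(seq_len(nrow(rec)), function(r) {
    if (sponsor %in% rec$sponsors[[r]]) {
      tokenize_secondary_ids(rec$secondary_ids[[r]])$token
    } else {
      character(0)
    }
  })))
  ids <- ids[grepl("^SP", ids)]
  res <- match_external_id_list(rec, ids, sponsor)

  # brute-force oracle over records x ids
  oracle_matches <- 0L
  holders <- list()
  for (r in seq_len(nrow(rec))) {
    if (!any(tolower(sponsor) == tolower(unlist(rec$sponsors[[r]])))) next
    toks <- toupper(tokenize_secondary_ids(rec$secondary_ids[[r]])$token)
    hit <- intersect(toks, toupper(ids))
    oracle_matches <- oracle_matches + length(hit)
    for (h in hit) holders[[h]] <- c(holders[[h]], rec$record_id[r])
  }
  oracle_edges <- sum(vapply(holders, function(v) choose(length(unique(v)), 2), numeric(1)))
  expect_equal(res$n_matched_ids, oracle_matches)
  expect_equal(nrow(res$edges), oracle_edges)
  expect_gt(res$n_matched_ids, 0L)

  # id present but sponsor absent: no match
  res2 <- match_external_id_list(rec, ids, "No Such Sponsor Ltd")
  expect_equal(res2$n_matched_ids, 0L)
  # empty id list: empty result
  expect_equal(match_external_id_list(rec, character(0), sponsor)$n_matched_ids, 0L)
})
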