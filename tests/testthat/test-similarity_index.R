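test_that("normalization folds case, strips accents and is idempotent", {
  expect_equal(normalize_text("Étude RANDOMISÉE"), "etude randomisee")
  expect_equal(normalize_text("abc123"), "abc123")
  expect_equal(normalize_text("Naïve Crohn’s"), normalize_text(normalize_text("Naïve Crohn’s")))
  set.seed(5)
  alphabet <- c(letters, LETTERS, 0:9, "é", "ü", "ß", "-", ".", ",", " ", "β", "阪")
  for (k in 1:40) {
    s <- paste(sample(alphabet, 20, replace = TRUE), collapse = "")
    once <- normalize_text(s)
    expect_equal(normalize_text(once), once, info = s)
    expect_false(grepl("[A-Z]", once))
  }
})

test_that("tokenization yields maximal alphanumeric runs, dropping punctuation", {
  expect_equal(tokenize_terms("aspirin vs. placebo"), c("aspirin", "vs", "placebo"))
  expect_equal(tokenize_terms(""), character(0))
  expect_equal(
    tokenize_terms("phase-ii, double-blind"),
    c("phase", "ii", "double", "blind")
  )
  # declared token regex oracle: maximal runs of [a-z0-9]
  s <- "a1b--c2;;d3 e"
  expect_equal(tokenize_terms(s), regmatches(s, gregexpr("[a-z0-9]+", s))[[1]])
})

test_that("field index weights equal ln(N/df), zero for stop terms and ubiquitous terms", {
  titles <- c(
    "aspirin heart", "aspirin stroke", "placebo stroke",
    "aspirin heart stroke", "zinc"
  )
  rec <- consolidate_variants(variants_from_titles(titles))
  idx <- build_field_index(rec, "title")
  expect_equal(idx$n_docs, 5L)
  want <- c(
    aspirin = log(5 / 3), heart = log(5 / 2), placebo = log(5),
    stroke = log(5 / 3), zinc = log(5)
  )
  expect_equal(idx$weight[names(want)], want)

  # a term present in every record weighs ln(1) = 0
  rec2 <- consolidate_variants(variants_from_titles(paste("trial", titles)))
  idx2 <- build_field_index(rec2, "title")
  expect_equal(unname(idx2$weight["trial"]), 0)
  # a term in exactly one of N records gets the maximal weight ln(N)
  expect_equal(unname(idx2$weight["zinc"]), log(5))

  # stop words are forced to zero whatever their frequency
  rec3 <- consolidate_variants(variants_from_titles(c("the aspirin", "the zinc")))
  idx3 <- build_field_index(rec3, "title")
  expect_equal(unname(idx3$weight["the"]), 0)

  expect_error(build_field_index(rec[0, ], "title"), "empty")
})

test_that("feature vectors are binary, field-tagged, and empty for redacted records", {
  v <- variants_from_titles(c("aspirin aspirin trial", "other words"))
  v$conditions <- list("aspirin", "unrelated")
  rec <- consolidate_variants(v)
  idx <- list(
    title = build_field_index(rec, "title"),
    condition = build_field_index(rec, "condition")
  )
  fv <- vectorize(rec[1, ], idx)
  # binary presence: "aspirin" contributes once per field
  expect_setequal(
    names(fv),
    c("title:aspirin", "title:trial", "condition:aspirin")
  )
  # the same word in two fields is two distinct features
  expect_equal(sum(grepl(":aspirin$", names(fv))), 2L)
  expect_equal(attr(fv, "norm"), sqrt(sum(unclass(fv)^2)))

  v2 <- variants_from_titles(c("N/A", "real title words"))
  rec2 <- consolidate_variants(v2)
  idx2 <- list(title = build_field_index(rec2, "title"))
  fv2 <- vectorize(rec2[rec2$redacted, ], idx2)
  expect_length(unclass(fv2), 0L)
  expect_equal(attr(fv2, "norm"), 0)
  expect_equal(cosine_similarity(fv2, vectorize(rec2[!rec2$redacted, ], idx2)), 0)
})

unit_index <- function(terms) {
  structure(
    list(
      field = "title", n_docs = 2L,
      df = setNames(rep(1L, length(terms)), terms),
      weight = setNames(rep(1, length(terms)), terms),
      stop_terms = character(0)
    ),
    class = "field_index"
  )
}

test_that("cosine similarity matches hand computations and its invariants", {
  idx <- list(title = unit_index(c("a", "b", "c", "d")))
  rec <- consolidate_variants(variants_from_titles(c("a b c", "a b d")))
  va <- vectorize(rec[1, ], idx)
  vb <- vectorize(rec[2, ], idx)
  expect_equal(cosine_similarity(va, vb), 2 / 3)
  expect_equal(cosine_similarity(va, va), 1)
  vd <- vectorize(
    consolidate_variants(variants_from_titles(c("d", "x")))[1, ], idx
  )
  expect_equal(cosine_similarity(va, vd), 0)

  # removing a shared term never increases the cosine (3-term toys)
  for (shared in 1:3) {
    t_a <- paste(c(letters[1:shared], "x", "y")[1:3], collapse = " ")
    t_b <- paste(c(letters[1:shared], "p", "q")[1:3], collapse = " ")
    t_b_less <- paste(c(letters[seq_len(shared - 1)], "p", "q", "r")[1:3], collapse = " ")
    idx2 <- list(title = unit_index(c(letters[1:3], "x", "y", "p", "q", "r")))
    r3 <- consolidate_variants(variants_from_titles(c(t_a, t_b, t_b_less)))
    s_with <- cosine_similarity(vectorize(r3[1, ], idx2), vectorize(r3[2, ], idx2))
    s_less <- cosine_similarity(vectorize(r3[1, ], idx2), vectorize(r3[3, ], idx2))
    expect_gte(s_with, s_less)
  }
})

test_that("cosine is symmetric and bounded on corpus-built vectors", {
  s <- small_study(n_trials = 120, seed = 9)
  idx <- list(title = build_field_index(s$records, "title"))
  set.seed(17)
  for (k in 1:40) {
    ij <- sample(nrow(s$records), 2)
    va <- vectorize(s$records[ij[1], ], idx)
    vb <- vectorize(s$records[ij[2], ], idx)
    ab <- cosine_similarity(va, vb)
    expect_equal(ab, cosine_similarity(vb, va), tolerance = 1e-12)
    expect_gte(ab, 0)
    expect_lte(ab, 1 + 1e-12)
  }
})

test_that("planted duplicates separate from non-duplicates on the title field", {
  s <- small_study(n_trials = 500, seed = 77)
  rec <- s$records
  idx <- list(title = build_field_index(rec, "title"))
  tp <- truth_pairs(s$truth)
  pos <- match(tp$id_a, rec$record_id)
  qos <- match(tp$id_b, rec$record_id)
  m <- trialdedup:::corpus_matrix(rec, idx, fields = "title")
  dup_scores <- Matrix::rowSums(m[pos, , drop = FALSE] * m[qos, , drop = FALSE])

  set.seed(3)
  ra <- sample(nrow(rec), 4000, replace = TRUE)
  rb <- sample(nrow(rec), 4000, replace = TRUE)
  keep <- ra != rb
  trial_of <- setNames(s$truth$records$trial_id, s$truth$records$record_id)
  same_trial <- trial_of[rec$record_id[ra]] == trial_of[rec$record_id[rb]]
  keep <- keep & !same_trial
  non_scores <- Matrix::rowSums(m[ra[keep], , drop = FALSE] * m[rb[keep], , drop = FALSE])

  expect_gt(
    median(dup_scores),
    quantile(non_scores, 0.99)
  )
})
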