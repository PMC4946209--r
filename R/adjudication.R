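# Rule engine encoding manual duplicate-judgment criteria.
#
# Summary protocol information is rarely detailed enough to prove that two
# records describe the same trial, so judgments rest on an ordered set of
# signals; the first rule that fires decides, and doubt defaults to
# non-duplicate. Separately registered extension studies are treated as
# new trials.

VERDICTS <- c("duplicate", "non_duplicate", "unknown")

#' Adjudication rule configuration
#'
#' @param antonym_pairs list of length-2 character vectors of contradictory
#'   phrases: titles that are near-identical except for swapping one such
#'   pair are judged non-duplicates.
#' @param extension_markers phrases whose presence in exactly one of two
#'   near-identical titles marks a separately registered extension study
#'   (a new trial).
#' @param grant_patterns regular expressions recognizing US federal grant
#'   numbers, which never count as identifying secondary IDs. The shipped
#'   default encodes the NIH shape: optional application-type digit,
#'   activity code (letter + two digits), institute code (two letters),
#'   serial number.
#' @param min_strong_id_len a shared secondary ID must be longer than this
#'   many characters to count as identifying; default 5.
#' @param field_similarity_floor unit-weight title cosine above which two
#'   records count as textually similar for the fallback rule; default 0.5.
#' @param title_identity_floor unit-weight cosine above which titles count
#'   as near-identical for the contradiction rule; default 0.85.
#' @param date_window_days start dates further apart than this count as
#'   contradictory; default 365.
#' @return list of class `rule_config`.
#' @export
rule_config <- function(antonym_pairs = list(
                          c("fed", "fasting"),
                          c("fed", "fasted"),
                          c("open", "blind"),
                          c("adults", "children")
                        ),
                        extension_markers = c("extension", "followup", "follow"),
                        grant_patterns = c("^[0-9]?[A-Z][0-9]{2}[A-Z]{2}[0-9]{5,6}([A-Z0-9-]*)?$"),
                        min_strong_id_len = 5,
                        field_similarity_floor = 0.5,
                        title_identity_floor = 0.85,
                        date_window_days = 365) {
  stopifnot(min_strong_id_len >= 1)
  for (p in grant_patterns) regexpr(p, "") # patterns must compile
  structure(
    list(
      antonym_pairs = antonym_pairs,
      extension_markers = extension_markers,
      grant_patterns = grant_patterns,
      min_strong_id_len = min_strong_id_len,
      field_similarity_floor = field_similarity_floor,
      title_identity_floor = title_identity_floor,
      date_window_days = date_window_days
    ),
    class = "rule_config"
  )
}

#' Is a token a US federal grant number?
#'
#' Grant numbers often apply to many different trials (the same grant can
#' fund dozens), so they never count as identifying secondary IDs.
#'
#' @param token character vector of cleaned ID tokens.
#' @param config `rule_config`.
#' @return logical vector.
#' @export
#' @examples
#' is_grant_number(c("R01HL123456", "2011-004388-62"))
is_grant_number <- function(token, config = rule_config()) {
  token <- toupper(trimws(as.character(token)))
  out <- rep(FALSE, length(token))
  for (p in config$grant_patterns) {
    out <- out | grepl(p, token)
  }
  out & nzchar(token)
}

# Unit-weight cosine of two token sets (binary presence, all weights 1).
unit_cosine <- function(ta, tb) {
  ta <- unique(ta)
  tb <- unique(tb)
  if (length(ta) == 0L || length(tb) == 0L) {
    return(0)
  }
  length(intersect(ta, tb)) / sqrt(length(ta) * length(tb))
}

#' Do two titles contradict each other?
#'
#' TRUE when the titles are near-identical (unit-weight cosine at or above
#' the configured identity floor after removing the marker words) but one
#' contains a phrase and the other its configured antonym — or exactly one
#' carries an extension-study marker. Dissimilar titles never fire this
#' rule, whatever words they contain.
#'
#' @param title_a,title_b raw titles (normalized internally).
#' @param config `rule_config`.
#' @return single logical.
#' @export
#' @examples
#' contradictory_titles(
#'   "Drug X under fed conditions",
#'   "Drug X under fasting conditions"
#' )
contradictory_titles <- function(title_a, title_b, config = rule_config()) {
  ta <- unique(tokenize_terms(normalize_text(title_a)))
  tb <- unique(tokenize_terms(normalize_text(title_b)))
  marker_words <- unique(c(unlist(config$antonym_pairs), config$extension_markers))
  rest_sim <- unit_cosine(setdiff(ta, marker_words), setdiff(tb, marker_words))
  if (rest_sim < config$title_identity_floor) {
    return(FALSE)
  }
  for (pair in config$antonym_pairs) {
    p <- pair[1]
    q <- pair[2]
    if ((p %in% ta && q %in% tb && !(q %in% ta) && !(p %in% tb)) ||
      (q %in% ta && p %in% tb && !(p %in% ta) && !(q %in% tb))) {
      return(TRUE)
    }
  }
  for (m in config$extension_markers) {
    if (xor(m %in% ta, m %in% tb)) {
      return(TRUE)
    }
  }
  FALSE
}

# Character-class skeleton: letters -> A, digits -> 9; punctuation kept.
# Two distinct IDs with equal skeleton are "the same format".
id_skeleton <- function(id) {
  id <- toupper(id)
  id <- gsub("[A-Z]", "A", id)
  gsub("[0-9]", "9", id)
}

shared_sponsor <- function(a, b) {
  sa <- tolower(squish(unlist(a$sponsors)))
  sb <- tolower(squish(unlist(b$sponsors)))
  sa <- sa[nzchar(sa)]
  sb <- sb[nzchar(sb)]
  length(intersect(sa, sb)) > 0L
}

record_tokens_clean <- function(rec) {
  toupper(trimws(tokenize_secondary_ids(unlist(rec$secondary_ids))$token))
}

start_date <- function(rec) {
  d <- rec$date_enrolment
  if (length(d) == 0L || is.na(d)) d <- rec$date_registered
  d
}

#' Adjudicate one candidate pair
#'
#' Applies the judgment rules in fixed precedence order; the first firing
#' rule decides:
#'
#' 1. near-identical titles with a contradictory phrase (or an
#'    extension-study marker on one side only) — non-duplicate;
#' 2. shared sponsor and a shared secondary ID that is not a grant number
#'    and is longer than `min_strong_id_len` characters — duplicate;
#' 3. shared sponsor and distinct secondary IDs in the same format —
#'    non-duplicate;
#' 4. title similarity at or above the floor with no contradictory start
#'    dates or sponsors — duplicate;
#' 5. otherwise (doubt) — non-duplicate.
#'
#' @param a,b one-row records tibbles.
#' @param config `rule_config`.
#' @param title_score optional precomputed title similarity used for rule
#'   4 in place of the unit-weight cosine (e.g. the IDF-weighted score).
#' @return list of class `judgment`: `verdict`, `fired_rule`, `rationale`.
#' @export
adjudicate_pair <- function(a, b, config = rule_config(), title_score = NULL) {
  judgment <- function(verdict, rule, why) {
    structure(list(verdict = verdict, fired_rule = rule, rationale = why),
      class = "judgment"
    )
  }
  # rule 1: contradictory near-identical titles
  if (contradictory_titles(a$concatenated_title, b$concatenated_title, config)) {
    return(judgment(
      "non_duplicate", "contradictory_titles",
      "near-identical titles with a contradictory phrase or extension marker"
    ))
  }
  sponsor_shared <- shared_sponsor(a, b)
  tok_a <- record_tokens_clean(a)
  tok_b <- record_tokens_clean(b)
  strong <- function(t) {
    nchar(t) > config$min_strong_id_len & !is_grant_number(t, config)
  }
  # rule 2: shared sponsor + shared strong secondary ID
  shared_ids <- intersect(tok_a[strong(tok_a)], tok_b[strong(tok_b)])
  if (sponsor_shared && length(shared_ids) > 0L) {
    return(judgment(
      "duplicate", "shared_strong_id",
      paste0("shared sponsor and shared secondary ID ", shared_ids[1])
    ))
  }
  # rule 3: shared sponsor + distinct same-format IDs
  if (sponsor_shared && length(tok_a) > 0L && length(tok_b) > 0L) {
    sk_a <- split(tok_a, id_skeleton(tok_a))
    sk_b <- split(tok_b, id_skeleton(tok_b))
    for (sk in intersect(names(sk_a), names(sk_b))) {
      if (length(setdiff(sk_a[[sk]], sk_b[[sk]])) > 0L &&
        length(setdiff(sk_b[[sk]], sk_a[[sk]])) > 0L) {
        return(judgment(
          "non_duplicate", "same_format_distinct_ids",
          paste0("shared sponsor but distinct IDs of format ", sk)
        ))
      }
    }
  }
  # rule 4: similar fields, no contradictions
  sim <- title_score %||% unit_cosine(
    tokenize_terms(normalize_text(a$concatenated_title)),
    tokenize_terms(normalize_text(b$concatenated_title))
  )
  if (sim >= config$field_similarity_floor) {
    da <- start_date(a)
    db <- start_date(b)
    dates_ok <- is.na(da) || is.na(db) ||
      abs(as.numeric(da - db)) <= config$date_window_days
    sa <- tolower(squish(unlist(a$sponsors)))
    sb <- tolower(squish(unlist(b$sponsors)))
    sponsors_ok <- sponsor_shared || length(sa) == 0L || length(sb) == 0L
    if (dates_ok && sponsors_ok) {
      return(judgment(
        "duplicate", "field_similarity",
        sprintf("title similarity %.2f with no contradictory dates or sponsors", sim)
      ))
    }
  }
  judgment("non_duplicate", "default_doubt", "no decisive signal; doubt")
}

#' @export
print.judgment <- function(x, ...) {
  cat("<judgment> ", x$verdict, " [", x$fired_rule, "]: ", x$rationale, "\n",
    sep = ""
  )
  invisible(x)
}

#' Adjudicate many pairs
#'
#' Vectorized driver for [adjudicate_pair()] over a pairs tibble.
#'
#' @param pairs tibble with columns `id_a`, `id_b` and optionally `score`
#'   (passed as `title_score` when scored on the title field).
#' @param records records tibble containing all referenced IDs.
#' @param config `rule_config`.
#' @param use_score pass `pairs$score` to rule 4; default TRUE when a
#'   `score` column is present.
#' @return tibble `id_a`, `id_b`, `verdict`, `fired_rule`.
#' @export
adjudicate_pairs <- function(pairs, records, config = rule_config(),
                             use_score = "score" %in% names(pairs)) {
  idx <- setNames(seq_len(nrow(records)), records$record_id)
  verdict <- character(nrow(pairs))
  rule <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- records[idx[[pairs$id_a[k]]], ]
    b <- records[idx[[pairs$id_b[k]]], ]
    j <- adjudicate_pair(
      a, b, config,
      title_score = if (use_score) pairs$score[k] else NULL
    )
    verdict[k] <- j$verdict
    rule[k] <- j$fired_rule
  }
  tibble(
    id_a = pairs$id_a, id_b = pairs$id_b,
    verdict = verdict, fired_rule = rule
  )
}

#' Read and write pair ratings
#'
#' Ratings are stored as TSV with columns `id_a`, `id_b`, `verdict`
#' (`duplicate`, `non_duplicate` or `unknown`); the round trip is stable
#' and `unknown` verdicts are preserved. Replaces interactive rating with
#' a file-based workflow.
#'
#' @param path TSV file path.
#' @return `read_ratings()`: tibble `id_a`, `id_b`, `verdict`.
#' @export
read_ratings <- function(path) {
  df <- read.delim(path,
    sep = "\t", quote = "", colClasses = "character",
    stringsAsFactors = FALSE, na.strings = NULL
  )
  needed <- c("id_a", "id_b", "verdict")
  if (!all(needed %in% names(df))) {
    stop("ratings file must have columns id_a, id_b, verdict", call. = FALSE)
  }
  bad <- which(!(df$verdict %in% VERDICTS))
  if (length(bad) > 0L) {
    stop(
      "invalid verdict ", dQuote(df$verdict[bad[1]]), " at line ",
      bad[1] + 1L, " of ", path,
      call. = FALSE
    )
  }
  tibble(id_a = df$id_a, id_b = df$id_b, verdict = df$verdict)
}

#' @rdname read_ratings
#' @param ratings tibble with columns `id_a`, `id_b`, `verdict`.
#' @return `write_ratings()`: `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  bad <- which(!(ratings$verdict %in% VERDICTS))
  if (length(bad) > 0L) {
    stop("invalid verdict ", dQuote(ratings$verdict[bad[1]]), " in row ", bad[1],
      call. = FALSE
    )
  }
  write.table(
    as.data.frame(ratings[c("id_a", "id_b", "verdict")]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
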