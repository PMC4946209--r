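# Known-duplicate grouping by secondary-ID linkage.
#
# The portal-style grouping: a secondary-ID token on one record that equals
# the registry ID of another links the two; groups are the connected
# components of those links. For EUCTR, tokens may omit the EUCTR prefix
# and/or the member-state code (a bare EudraCT number still identifies the
# record).

EUDRACT_RE <- "^\\d{4}-\\d{6}-\\d{2}$"
UTN_RE <- "^U1111-\\d{4}-\\d{4}$"

#' Default nonsense secondary-ID stop list
#'
#' Free-text values commonly entered in the secondary-ID field that can
#' never identify a trial. Tokens on this list (case-insensitive), and
#' tokens shorter than `min_len` characters, never produce linkage edges.
#'
#' @return lowercase character vector.
#' @export
nonsense_id_stoplist <- function() {
  c("nil", "none", "known", "nil known", "n/a", "na", "pending", "version",
    "unknown", "not", "applicable")
}

#' Tokenize raw secondary-ID strings
#'
#' Splits each raw secondary-ID value into tokens on whitespace and the
#' characters `,`, `;`, `.` — a single field frequently carries several
#' IDs. Note that `.` is a separator, so identifiers with internal dots are
#' split.
#'
#' @param raw_ids character vector of raw secondary-ID values.
#' @param source_record optional record ID(s) the values came from (either
#'   length 1 or one per value); carried through to the output.
#' @return tibble with columns `token` and `source_record`; empty tokens
#'   are dropped.
#' @export
#' @examples
#' tokenize_secondary_ids("NCT01472939; 2011-004388-62")
tokenize_secondary_ids <- function(raw_ids, source_record = NA_character_) {
  if (length(raw_ids) == 0L) {
    return(tibble(token = character(0), source_record = character(0)))
  }
  source_record <- rep_len(source_record, length(raw_ids))
  pieces <- strsplit(as.character(raw_ids), "[[:space:],;.]+")
  lens <- lengths(pieces)
  out <- tibble(
    token = unlist(pieces) %||% character(0),
    source_record = rep.int(source_record, lens)
  )
  out[nzchar(out$token), ]
}

# All secondary-ID tokens of a consolidated corpus, one row per
# (token, record).
corpus_id_tokens <- function(records) {
  lens <- lengths(records$secondary_ids)
  tokenize_secondary_ids(
    unlist(records$secondary_ids) %||% character(0),
    rep.int(records$record_id, lens)
  )
}

# Canonical form a token must take to name a record: EudraCT-shaped tokens
# (with the EUCTR prefix and/or a member-state suffix possibly absent) are
# rewritten to the EUCTR record stem; all other tokens are matched verbatim
# (case-insensitively).
canonicalize_id_token <- function(token) {
  tok <- toupper(trimws(token))
  eu <- grepl("^(EUCTR)?\\d{4}-\\d{6}-\\d{2}(-[A-Z]{2,3})?$", tok)
  tok[eu] <- paste0(
    "EUCTR",
    sub("^(EUCTR)?(\\d{4}-\\d{6}-\\d{2})(-[A-Z]{2,3})?$", "\\2", tok[eu])
  )
  tok
}

#' Match secondary-ID tokens to registry IDs
#'
#' Produces one linkage edge for every token equal (case-insensitively,
#' after trimming) to another record's registry ID. For EUCTR records the
#' EUCTR prefix and the member-state suffix may be absent from the token.
#' Tokens shorter than `min_len` characters or on the nonsense stop list
#' never match. Self-matches are discarded; edges are deduplicated and
#' canonicalized with the lexicographically smaller ID first.
#'
#' @param records records tibble (consolidated corpus).
#' @param tokens optional pre-tokenized tibble (`token`, `source_record`);
#'   defaults to all secondary-ID tokens in `records`.
#' @param min_len minimum token length eligible for matching.
#' @param stoplist nonsense-token stop list, see [nonsense_id_stoplist()].
#' @return tibble of edges with columns `id_a`, `id_b` (`id_a < id_b`) and
#'   `reason` (`"secondary_id"`).
#' @export
match_ids_to_records <- function(records, tokens = NULL,
                                 min_len = 4, stoplist = nonsense_id_stoplist()) {
  if (is.null(tokens)) tokens <- corpus_id_tokens(records)
  tok <- trimws(tokens$token)
  src <- tokens$source_record
  ok <- nchar(tok) >= min_len & !(tolower(tok) %in% tolower(stoplist))
  tok <- canonicalize_id_token(tok[ok])
  src <- src[ok]
  lookup <- setNames(records$record_id, toupper(records$record_id))
  target <- unname(lookup[tok])
  hit <- !is.na(target) & target != src
  edges_tibble(src[hit], target[hit], "secondary_id")
}

edges_tibble <- function(a, b, reason) {
  ids <- canonical_pairs(a, b)
  out <- tibble(id_a = ids$id_a, id_b = ids$id_b, reason = reason)
  out <- out[!duplicated(out[c("id_a", "id_b")]), ]
  out[order(out$id_a, out$id_b), ]
}

#' Build duplicate groups from linkage edges
#'
#' Groups are the connected components of the edge set over all records:
#' every record in a group is considered a known duplicate of every other
#' record in the group. Unmatched records form singleton groups. Group IDs
#' are the lexicographically smallest member ID, so the grouping is
#' invariant to edge and record order.
#'
#' @param edges edge tibble (`id_a`, `id_b`, optionally `reason`).
#' @param record_ids character vector of all record IDs to cover.
#' @return an object of class `duplicate_group_set`: a list with
#'   `membership` (tibble `record_id`, `group_id`), `edges` (the input
#'   edges) and `n_groups`.
#' @export
build_groups <- function(edges, record_ids) {
  record_ids <- sort(unique(record_ids))
  unknown <- setdiff(c(edges$id_a, edges$id_b), record_ids)
  if (length(unknown) > 0L) {
    stop("edges mention unknown records: ", paste(head(unknown, 3), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      edges[c("id_a", "id_b")],
      directed = FALSE, vertices = record_ids
    )
    comp <- igraph::components(g)$membership
  } else {
    comp <- setNames(seq_along(record_ids), record_ids)
  }
  # stable group labels: smallest member id
  smallest <- tapply(names(comp), comp, min)
  membership <- tibble(
    record_id = names(comp),
    group_id = unname(smallest[as.character(comp)])
  )
  membership <- membership[order(membership$record_id), ]
  structure(
    list(
      membership = membership,
      edges = edges,
      n_groups = length(smallest)
    ),
    class = "duplicate_group_set"
  )
}

group_membership <- function(groups) {
  stopifnot(inherits(groups, "duplicate_group_set"))
  setNames(groups$membership$group_id, groups$membership$record_id)
}

#' @export
print.duplicate_group_set <- function(x, ...) {
  n <- nrow(x$membership)
  cat(
    "<duplicate_group_set> ", n, " records in ", x$n_groups, " groups (",
    nrow(x$edges), " edges)\n",
    sep = ""
  )
  invisible(x)
}

#' Count unique trials implied by a grouping
#'
#' The number of unique trials equals the number of groups. Also reports
#' how many records have at least one known duplicate and the group-size
#' histogram.
#'
#' @param groups `duplicate_group_set` from [build_groups()].
#' @return list with `n_trials`, `n_records`, `n_records_with_duplicates`
#'   and `size_histogram` (named integer vector: group size -> count).
#' @export
count_unique_trials <- function(groups) {
  sizes <- table(group_membership(groups))
  hist <- table(as.integer(sizes))
  list(
    n_trials = length(sizes),
    n_records = nrow(groups$membership),
    n_records_with_duplicates = sum(sizes[sizes > 1]),
    size_histogram = setNames(as.integer(hist), names(hist))
  )
}

#' All within-group record pairs
#'
#' Every unordered pair of records sharing a group — the known-duplicate
#' pairs, `sum(choose(size, 2))` in total.
#'
#' @param groups `duplicate_group_set`.
#' @return tibble with columns `id_a`, `id_b` (`id_a < id_b`).
#' @export
known_pairs <- function(groups) {
  membership <- groups$membership
  sizes <- table(membership$group_id)
  multi <- names(sizes)[sizes > 1]
  if (length(multi) == 0L) {
    return(tibble(id_a = character(0), id_b = character(0)))
  }
  m <- membership[membership$group_id %in% multi, ]
  by_group <- split(m$record_id, m$group_id)
  pairs <- lapply(by_group, function(ids) {
    ids <- sort(ids)
    k <- length(ids)
    i <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    j <- unlist(lapply(seq_len(k - 1L), function(p) (p + 1L):k))
    cbind(ids[i], ids[j])
  })
  mat <- do.call(rbind, pairs)
  out <- tibble(id_a = mat[, 1], id_b = mat[, 2])
  out[order(out$id_a, out$id_b), ]
}

#' Link records sharing a Universal Trial Number
#'
#' Secondary-ID tokens matching the WHO UTN format `U1111-dddd-dddd` link
#' all records carrying the same UTN, a grouping the portal itself does not
#' perform.
#'
#' @param records records tibble.
#' @return edge tibble (`id_a`, `id_b`, `reason = "utn"`).
#' @export
match_by_utn <- function(records) {
  tokens <- corpus_id_tokens(records)
  utn <- tokens[grepl(UTN_RE, toupper(trimws(tokens$token))), ]
  if (nrow(utn) == 0L) {
    return(edges_tibble(character(0), character(0), "utn"))
  }
  utn$token <- toupper(trimws(utn$token))
  utn <- utn[!duplicated(utn[c("token", "source_record")]), ]
  by_utn <- split(utn$source_record, utn$token)
  a <- character(0)
  b <- character(0)
  for (ids in by_utn) {
    ids <- sort(unique(ids))
    k <- length(ids)
    if (k < 2L) next
    i <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    j <- unlist(lapply(seq_len(k - 1L), function(p) (p + 1L):k))
    a <- c(a, ids[i])
    b <- c(b, ids[j])
  }
  edges_tibble(a, b, "utn")
}

#' Match an external sponsor identifier list
#'
#' Matches an externally harvested list of trial identifiers (e.g. from a
#' sponsor's own study register) against secondary-ID tokens, restricted
#' to records listing one of the given sponsor name variants
#' (case-insensitive substring match after whitespace normalization).
#' Records sharing a matched external ID are linked.
#'
#' @param records records tibble.
#' @param ids character vector of external identifiers.
#' @param sponsor_names character vector of sponsor name variants.
#' @return list with `n_matched_ids` (count of matched (record, ID)
#'   occurrences), `matched_ids` (tibble `token`, `record_id`) and `edges`
#'   (edge tibble, `reason = "external_list"`).
#' @export
match_external_id_list <- function(records, ids, sponsor_names) {
  empty <- list(
    n_matched_ids = 0L,
    matched_ids = tibble(token = character(0), record_id = character(0)),
    edges = edges_tibble(character(0), character(0), "external_list")
  )
  if (length(ids) == 0L) {
    return(empty)
  }
  sponsor_text <- vapply(
    records$sponsors,
    function(s) tolower(squish(paste(s, collapse = " ; "))), character(1)
  )
  pat <- tolower(squish(sponsor_names))
  has_sponsor <- rep(FALSE, nrow(records))
  for (p in pat[nzchar(pat)]) {
    has_sponsor <- has_sponsor | grepl(p, sponsor_text, fixed = TRUE)
  }
  sub <- records[has_sponsor, ]
  if (nrow(sub) == 0L) {
    return(empty)
  }
  tokens <- corpus_id_tokens(sub)
  tokens$token <- toupper(trimws(tokens$token))
  tokens <- tokens[!duplicated(tokens[c("token", "source_record")]), ]
  hit <- tokens[tokens$token %in% toupper(trimws(ids)), ]
  by_id <- split(hit$source_record, hit$token)
  a <- character(0)
  b <- character(0)
  for (recs in by_id) {
    recs <- sort(unique(recs))
    k <- length(recs)
    if (k < 2L) next
    i <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    j <- unlist(lapply(seq_len(k - 1L), function(p) (p + 1L):k))
    a <- c(a, recs[i])
    b <- c(b, recs[j])
  }
  list(
    n_matched_ids = nrow(hit),
    matched_ids = tibble(token = hit$token, record_id = hit$source_record),
    edges = edges_tibble(a, b, "external_list")
  )
}
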