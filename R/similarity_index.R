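# Field-tagged, IDF-weighted binary cosine similarity.
#
# Each scored field (title = concatenated title, condition, intervention,
# outcome, inclusion) gets its own index: document frequencies are counted
# once per record (binary presence), and a term's weight is ln(N / df),
# with stop words forced to zero. A record's feature vector is the union of
# its field-tagged terms; the same word in two fields is two distinct
# features. Term multiplicity within a field is ignored.

SCORED_FIELDS <- c("title", "condition", "intervention", "outcome", "inclusion")

# Record column holding the text of each scored field.
field_column <- function(field) {
  switch(field,
    title = "concatenated_title",
    condition = "condition",
    intervention = "intervention",
    outcome = "outcome",
    inclusion = "inclusion",
    stop("unknown field: ", field, call. = FALSE)
  )
}

#' Normalize registry text for similarity scoring
#'
#' Case-folds, transliterates accented Latin letters to their base letters,
#' and removes characters that are not lowercase Latin letters, digits,
#' punctuation or spaces. Idempotent.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_text("Étude RANDOMISÉE")
normalize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  # explicit accent folding (iconv transliteration is libc-dependent)
  from <- "àáâãäåçèéêëìíîïñòóôõöøùúûüýÿāąćčēęğīłńőřśşšūźżž"
  to <- "aaaaaaceeeeiiiinoooooouuuuyyaacceesilnorsssuzzz"
  x <- chartr(from, to, x)
  latin <- iconv(x, from = "UTF-8", to = "ASCII", sub = " ")
  latin[is.na(latin)] <- ""
  latin <- gsub("[^a-z0-9[:punct:] ]", " ", latin)
  squish(latin)
}

#' Tokenize normalized text into terms
#'
#' Terms are maximal runs of `[a-z0-9]`; every other character is a
#' boundary, so punctuation-only tokens never appear.
#'
#' @param x normalized text (see [normalize_text()]); a character vector.
#' @return for a single string, a character vector of terms; for a longer
#'   vector, a list of such vectors.
#' @export
#' @examples
#' tokenize_terms("aspirin vs. placebo")
tokenize_terms <- function(x) {
  pieces <- strsplit(x, "[^a-z0-9]+")
  pieces <- lapply(pieces, function(v) v[nzchar(v)])
  if (length(pieces) == 1L) pieces[[1]] else pieces
}

# Unique terms per record for one scored field (normalize + tokenize +
# binary presence). Redacted records yield no terms.
record_terms <- function(records, field) {
  text <- records[[field_column(field)]]
  text[records$redacted] <- ""
  toks <- strsplit(normalize_text(text), "[^a-z0-9]+")
  lapply(toks, function(v) unique(v[nzchar(v)]))
}

#' Build an IDF index for one field
#'
#' Counts, for every term, the number of records whose field contains it
#' (binary per record) and assigns weight `ln(N / df)` — rare terms get
#' high weight, ubiquitous terms weight zero. Stop words are forced to
#' weight zero.
#'
#' @param records records tibble from [consolidate_variants()].
#' @param field one of `"title"`, `"condition"`, `"intervention"`,
#'   `"outcome"`, `"inclusion"`; `"title"` scores the concatenated title.
#' @param stop_terms terms with forced zero weight.
#' @return an object of class `field_index`: a list with elements `field`,
#'   `n_docs`, `df` (named integer vector) and `weight` (named numeric
#'   vector).
#' @export
build_field_index <- function(records, field = "title",
                              stop_terms = stopwords_en()) {
  field <- match.arg(field, SCORED_FIELDS)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot index an empty corpus", call. = FALSE)
  }
  terms <- record_terms(records, field)
  all_terms <- unlist(terms)
  df <- table(all_terms)
  df <- setNames(as.integer(df), names(df))
  n <- nrow(records)
  weight <- log(n / df)
  weight[names(weight) %in% stop_terms] <- 0
  structure(
    list(field = field, n_docs = n, df = df, weight = weight,
         stop_terms = stop_terms),
    class = "field_index"
  )
}

#' @export
print.field_index <- function(x, ...) {
  cat(
    "<field_index> field=", x$field, ", N=", x$n_docs,
    ", terms=", length(x$df), "\n",
    sep = ""
  )
  invisible(x)
}

#' Build a record's feature vector
#'
#' Binary, field-tagged, IDF-weighted term features. The same word in two
#' fields yields two distinct features (named `"field:term"`). Redacted
#' records yield an empty vector, so their similarity with anything is 0.
#'
#' @param record one-row records tibble.
#' @param indexes named list of `field_index` objects (names = fields).
#' @param fields fields to include; defaults to all indexed fields.
#' @return an object of class `feature_vector`: a named numeric vector of
#'   weights with a `norm` attribute (Euclidean length).
#' @export
vectorize <- function(record, indexes, fields = names(indexes)) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  entries <- numeric(0)
  for (f in fields) {
    idx <- indexes[[f]]
    if (is.null(idx)) stop("no index for field: ", f, call. = FALSE)
    terms <- record_terms(record, f)[[1]]
    w <- idx$weight[terms]
    w[is.na(w)] <- 0 # terms unseen by the index carry no weight
    keep <- w > 0
    if (any(keep)) {
      entries <- c(entries, setNames(w[keep], paste0(f, ":", terms[keep])))
    }
  }
  structure(entries,
    norm = sqrt(sum(entries^2)),
    class = "feature_vector"
  )
}

#' Cosine similarity of two feature vectors
#'
#' Dot product over shared features divided by the product of Euclidean
#' norms; 0 when either vector is empty. A score of 1 means identical term
#' sets in the same fields; 0 means no shared weighted term.
#'
#' @param a,b `feature_vector` objects from [vectorize()] built against the
#'   same indexes.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- attr(a, "norm")
  nb <- attr(b, "norm")
  if (na == 0 || nb == 0) {
    return(0)
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    return(0)
  }
  sum(unclass(a)[shared] * unclass(b)[shared]) / (na * nb)
}

# Triplet (record, feature, weight) representation of the corpus over a
# set of fields; features are field-tagged, zero-weight entries dropped.
# The workhorse behind the similarity join.
corpus_triplets <- function(records, indexes, fields = names(indexes)) {
  i_all <- integer(0)
  j_all <- integer(0)
  x_all <- numeric(0)
  feat_names <- character(0)
  offset <- 0L
  for (f in fields) {
    idx <- indexes[[f]]
    if (is.null(idx)) stop("no index for field: ", f, call. = FALSE)
    terms <- record_terms(records, f)
    lens <- lengths(terms)
    row_i <- rep.int(seq_along(terms), lens)
    term_v <- unlist(terms)
    w <- idx$weight[term_v]
    w[is.na(w)] <- 0
    keep <- w > 0
    row_i <- row_i[keep]
    term_v <- term_v[keep]
    w <- w[keep]
    fterms <- sort(unique(term_v))
    j <- match(term_v, fterms) + offset
    i_all <- c(i_all, row_i)
    j_all <- c(j_all, j)
    x_all <- c(x_all, unname(w))
    feat_names <- c(feat_names, paste0(f, ":", fterms))
    offset <- offset + length(fterms)
  }
  list(
    i = i_all, j = j_all, x = x_all,
    n_features = offset, feature_names = feat_names
  )
}

# Sparse record-by-feature matrix (rows L2-normalized when requested);
# used by the brute-force enumeration oracle and index serialization.
corpus_matrix <- function(records, indexes, fields = names(indexes),
                          normalize = TRUE) {
  trip <- corpus_triplets(records, indexes, fields)
  m <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = trip$x,
    dims = c(nrow(records), trip$n_features),
    dimnames = list(records$record_id, trip$feature_names)
  )
  if (normalize) {
    norms <- sqrt(Matrix::rowSums(m^2))
    inv <- ifelse(norms > 0, 1 / norms, 0)
    m <- Matrix::Diagonal(x = inv) %*% m
    m <- as(m, "CsparseMatrix")
    dimnames(m) <- list(records$record_id, trip$feature_names)
  }
  m
}
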