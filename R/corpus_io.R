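# Ingestion and consolidation of registry records.
#
# A *variant* is one registration as published (EUCTR publishes one variant
# per EU member state); a *record* is the consolidated per-registration unit
# used everywhere downstream. Variants are held as a tibble with one row per
# variant; multi-valued WHO fields (secondary IDs, conditions, interventions,
# outcomes, sponsors, countries) are list-columns of character vectors.

VARIANT_SCALAR_COLS <- c(
  "registry_id", "registry", "variant_suffix",
  "public_title", "scientific_title", "acronym",
  "inclusion_criteria", "date_registered", "date_enrolment"
)
VARIANT_LIST_COLS <- c(
  "secondary_ids", "conditions", "interventions", "outcomes",
  "sponsors", "countries"
)

#' Default redaction markers
#'
#' Public titles used by registries in place of withheld protocol
#' information. A record whose public title equals one of these markers
#' (case-insensitively, after trimming) is treated as redacted and always
#' scores zero similarity against every other record.
#'
#' @return character vector of marker strings.
#' @export
redaction_markers <- function() {
  c(
    "N/A",
    "[Trial of device that is not approved or cleared by the U.S. FDA]"
  )
}

#' Strip HTML markup from registry text
#'
#' Removes markup tags, decodes character entities and collapses whitespace
#' to single spaces. Registry exports frequently embed HTML in free-text
#' fields; all text is cleaned at ingestion. Parsing is delegated to
#' libxml2's lenient HTML parser (via xml2), with a fast path for strings
#' containing no markup.
#'
#' @param x character vector (NA treated as empty).
#' @return character vector of cleaned text.
#' @export
#' @examples
#' strip_html("<b>Aspirin</b> trial")
#' strip_html("a&amp;b  c")
strip_html <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl("[<>&]", x)
  x[!needs] <- squish(x[!needs])
  x[needs] <- vapply(x[needs], strip_html_one, character(1), USE.NAMES = FALSE)
  x
}

strip_html_one <- function(s) {
  # a space before each tag keeps adjacent words from gluing together when
  # the tag is dropped ("...</p><p>..." stays two words)
  spaced <- gsub("<", " <", s, fixed = TRUE)
  txt <- tryCatch(
    xml2::xml_text(xml2::read_html(paste0("<div>", spaced, "</div>"))),
    error = function(e) gsub("<[^>]*>", " ", s)
  )
  squish(txt)
}

#' Read a registry corpus from XML or a delimited table
#'
#' Parses an ICTRP-style export into a variants table, cleaning every text
#' field with [strip_html()]. Two dialects are supported:
#'
#' * `"xml"`: a root element containing one `<trial>` element per variant,
#'   with child elements named after the variant fields and multi-valued
#'   fields as repeated children (`<secondary_id>`, `<condition>`,
#'   `<intervention>`, `<outcome>`, `<sponsor>`, `<country>`).
#' * `"tsv"`: tab-separated with a mandatory header row; multi-valued
#'   fields joined by `"|"`.
#'
#' @param path file path.
#' @param format `"xml"` or `"tsv"`.
#' @return tibble of variants, one row per variant. Columns: `registry_id`,
#'   `registry`, `variant_suffix`, `public_title`, `scientific_title`,
#'   `acronym`, `inclusion_criteria` (character), `date_registered`,
#'   `date_enrolment` (`Date`), and list-columns `secondary_ids`,
#'   `conditions`, `interventions`, `outcomes`, `sponsors`, `countries`.
#' @seealso [write_corpus()], [consolidate_variants()]
#' @export
parse_corpus <- function(path, format = c("xml", "tsv")) {
  format <- match.arg(format)
  out <- switch(format,
    xml = parse_corpus_xml(path),
    tsv = parse_corpus_tsv(path)
  )
  dup <- duplicated(out$registry_id)
  if (any(dup)) {
    stop(
      "duplicate registry_id in input: ",
      paste(unique(out$registry_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

parse_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  trials <- xml2::xml_find_all(doc, ".//trial")
  if (length(trials) == 0L) {
    return(empty_variants())
  }
  field_xml <- function(node, name) {
    child <- xml2::xml_find_first(node, name)
    if (inherits(child, "xml_missing")) "" else xml2::xml_text(child)
  }
  multi_xml <- function(node, name) {
    xml2::xml_text(xml2::xml_find_all(node, name))
  }
  rows <- lapply(seq_along(trials), function(i) {
    node <- trials[[i]]
    rid <- field_xml(node, "registry_id")
    if (!nzchar(rid)) {
      stop("trial element ", i, " has no <registry_id>", call. = FALSE)
    }
    list(
      registry_id = rid,
      registry = field_xml(node, "registry"),
      variant_suffix = field_xml(node, "variant_suffix"),
      public_title = field_xml(node, "public_title"),
      scientific_title = field_xml(node, "scientific_title"),
      acronym = field_xml(node, "acronym"),
      inclusion_criteria = field_xml(node, "inclusion_criteria"),
      date_registered = field_xml(node, "date_registered"),
      date_enrolment = field_xml(node, "date_enrolment"),
      secondary_ids = multi_xml(node, "secondary_id"),
      conditions = multi_xml(node, "condition"),
      interventions = multi_xml(node, "intervention"),
      outcomes = multi_xml(node, "outcome"),
      sponsors = multi_xml(node, "sponsor"),
      countries = multi_xml(node, "country")
    )
  })
  assemble_variants(rows)
}

parse_corpus_tsv <- function(path) {
  df <- read.delim(path,
    sep = "\t", quote = "", colClasses = "character",
    stringsAsFactors = FALSE, na.strings = NULL, check.names = FALSE
  )
  needed <- c(VARIANT_SCALAR_COLS, VARIANT_LIST_COLS)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("tsv corpus missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) {
    return(empty_variants())
  }
  bad <- which(!nzchar(df$registry_id))
  if (length(bad) > 0L) {
    stop("empty registry_id at data line ", bad[1], call. = FALSE)
  }
  split_multi <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    c(
      as.list(df[i, VARIANT_SCALAR_COLS]),
      lapply(
        setNames(df[i, VARIANT_LIST_COLS], VARIANT_LIST_COLS),
        function(x) split_multi(x)[[1]]
      )
    )
  })
  assemble_variants(rows)
}

assemble_variants <- function(rows) {
  getc <- function(name) vapply(rows, function(r) r[[name]], character(1))
  getl <- function(name) {
    lapply(rows, function(r) {
      v <- strip_html(r[[name]])
      v[nzchar(v)]
    })
  }
  parse_date <- function(x) {
    x[!nzchar(x)] <- NA_character_
    as.Date(x, format = "%Y-%m-%d")
  }
  tibble(
    registry_id = squish(getc("registry_id")),
    registry = strip_html(getc("registry")),
    variant_suffix = squish(getc("variant_suffix")),
    public_title = strip_html(getc("public_title")),
    scientific_title = strip_html(getc("scientific_title")),
    acronym = strip_html(getc("acronym")),
    secondary_ids = getl("secondary_ids"),
    conditions = getl("conditions"),
    interventions = getl("interventions"),
    outcomes = getl("outcomes"),
    inclusion_criteria = strip_html(getc("inclusion_criteria")),
    sponsors = getl("sponsors"),
    date_registered = parse_date(getc("date_registered")),
    date_enrolment = parse_date(getc("date_enrolment")),
    countries = getl("countries")
  )
}

empty_variants <- function() {
  assemble_variants(list())[0, ]
}

#' Write a variants table to XML or TSV
#'
#' Inverse of [parse_corpus()]: both dialects round-trip all fields.
#' Values must not contain tab, newline or `"|"` characters in the TSV
#' dialect.
#'
#' @param variants tibble as returned by [parse_corpus()] or
#'   [generate_corpus()].
#' @param path output file path.
#' @param format `"xml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(variants, path, format = c("xml", "tsv")) {
  format <- match.arg(format)
  switch(format,
    xml = write_corpus_xml(variants, path),
    tsv = write_corpus_tsv(variants, path)
  )
  invisible(path)
}

write_corpus_xml <- function(variants, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  scalar_tag <- function(tag, value) {
    ifelse(nzchar(value),
      paste0("  <", tag, ">", esc(value), "</", tag, ">"),
      paste0("  <", tag, "/>")
    )
  }
  multi_tag <- function(tag, values) {
    vapply(values, function(v) {
      if (length(v) == 0L) {
        return("")
      }
      paste0("  <", tag, ">", esc(v), "</", tag, ">", collapse = "\n")
    }, character(1))
  }
  body <- paste(
    "<trial>",
    scalar_tag("registry_id", variants$registry_id),
    scalar_tag("registry", variants$registry),
    scalar_tag("variant_suffix", variants$variant_suffix),
    scalar_tag("public_title", variants$public_title),
    scalar_tag("scientific_title", variants$scientific_title),
    scalar_tag("acronym", variants$acronym),
    multi_tag("secondary_id", variants$secondary_ids),
    multi_tag("condition", variants$conditions),
    multi_tag("intervention", variants$interventions),
    multi_tag("outcome", variants$outcomes),
    scalar_tag("inclusion_criteria", variants$inclusion_criteria),
    multi_tag("sponsor", variants$sponsors),
    scalar_tag("date_registered", fmt_date(variants$date_registered)),
    scalar_tag("date_enrolment", fmt_date(variants$date_enrolment)),
    multi_tag("country", variants$countries),
    "</trial>",
    sep = "\n"
  )
  body <- gsub("\n\n+", "\n", body)
  writeLines(
    c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<trials>", body, "</trials>"),
    path, useBytes = TRUE
  )
}

write_corpus_tsv <- function(variants, path) {
  join_multi <- function(col) {
    vapply(col, paste, character(1), collapse = "|")
  }
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  df <- data.frame(
    registry_id = variants$registry_id,
    registry = variants$registry,
    variant_suffix = variants$variant_suffix,
    public_title = variants$public_title,
    scientific_title = variants$scientific_title,
    acronym = variants$acronym,
    inclusion_criteria = variants$inclusion_criteria,
    date_registered = fmt_date(variants$date_registered),
    date_enrolment = fmt_date(variants$date_enrolment),
    secondary_ids = join_multi(variants$secondary_ids),
    conditions = join_multi(variants$conditions),
    interventions = join_multi(variants$interventions),
    outcomes = join_multi(variants$outcomes),
    sponsors = join_multi(variants$sponsors),
    countries = join_multi(variants$countries),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
}

#' EUCTR record stem
#'
#' Strips the two-letter member-state suffix from an EUCTR variant ID
#' (`EUCTR2011-004388-62-BE` becomes `EUCTR2011-004388-62`); IDs from all
#' other registries are returned unchanged.
#'
#' @param registry_id character vector of variant IDs.
#' @return character vector of record IDs.
#' @export
euctr_stem <- function(registry_id) {
  sub("^(EUCTR\\d{4}-\\d{6}-\\d{2})-[A-Z]{2,3}$", "\\1", registry_id)
}

#' Detect redacted records
#'
#' A record is redacted when its public title equals one of the configured
#' markers, compared case-insensitively after trimming. Redacted records
#' take part in ID linkage but always score zero similarity.
#'
#' @param public_title character vector.
#' @param markers marker strings; defaults to [redaction_markers()].
#' @return logical vector.
#' @export
detect_redaction <- function(public_title, markers = redaction_markers()) {
  tolower(trimws(public_title)) %in% tolower(trimws(markers))
}

#' Consolidate variants into records
#'
#' Collapses variants to one record per record stem (for EUCTR, the ID with
#' the member-state suffix removed; for other registries the registry ID
#' itself). For multi-variant records the variant registered first is
#' chosen; ties on date, and variants without a date (sorted last), are
#' broken by lexicographic variant suffix. Secondary IDs of *all* variants
#' are pooled on the record so that ID linkage sees every variant, and a
#' concatenated title (public title, scientific title, acronym joined by
#' single spaces) is built for similarity scoring. Multi-valued text fields
#' of the chosen variant are concatenated with single spaces.
#'
#' @param variants tibble from [parse_corpus()] or [generate_corpus()].
#' @param markers redaction markers, see [detect_redaction()].
#' @return tibble of records with columns `record_id`, `registry`,
#'   `public_title`, `scientific_title`, `acronym`, `concatenated_title`,
#'   `condition`, `intervention`, `outcome`, `inclusion` (character),
#'   `secondary_ids`, `sponsors` (list), `date_registered`,
#'   `date_enrolment`, `n_variants` (integer) and `redacted` (logical).
#' @export
consolidate_variants <- function(variants, markers = redaction_markers()) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    stop("cannot consolidate an empty variants table", call. = FALSE)
  }
  stem <- euctr_stem(variants$registry_id)
  # Choose the earliest-registered variant per stem; NA dates sort last,
  # ties broken by variant suffix, then registry_id for full determinism.
  date_key <- as.numeric(variants$date_registered)
  date_key[is.na(date_key)] <- Inf
  ord <- order(stem, date_key, variants$variant_suffix, variants$registry_id)
  first_idx <- ord[!duplicated(stem[ord])]
  chosen <- variants[first_idx, ]
  chosen_stem <- stem[first_idx]

  pooled_ids <- split(
    rep(variants$secondary_ids, 1L),
    factor(stem, levels = chosen_stem)
  )
  pooled_ids <- lapply(pooled_ids, function(lst) unique(unlist(lst)) %||% character(0))

  n_var <- as.integer(table(factor(stem, levels = chosen_stem)))

  cat_multi <- function(col) {
    vapply(col, function(v) squish(paste(v, collapse = " ")), character(1))
  }
  records <- tibble(
    record_id = chosen_stem,
    registry = chosen$registry,
    public_title = chosen$public_title,
    scientific_title = chosen$scientific_title,
    acronym = chosen$acronym,
    concatenated_title = paste_fields(
      chosen$public_title, chosen$scientific_title, chosen$acronym
    ),
    condition = cat_multi(chosen$conditions),
    intervention = cat_multi(chosen$interventions),
    outcome = cat_multi(chosen$outcomes),
    inclusion = chosen$inclusion_criteria,
    secondary_ids = unname(pooled_ids),
    sponsors = chosen$sponsors,
    date_registered = chosen$date_registered,
    date_enrolment = chosen$date_enrolment,
    n_variants = n_var,
    redacted = detect_redaction(chosen$public_title, markers)
  )
  records[order(records$record_id), ]
}
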