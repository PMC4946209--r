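# Synthetic multi-registry corpora with planted duplicate ground truth.
#
# The generator emulates the statistical structure the analysis relies on,
# not registry prose: titles drawn from a Zipf vocabulary plus
# trial-specific rare tokens (so IDF weighting is informative), per-registry
# field dialects, duplicate clusters that are either linked by secondary
# IDs ("known") or unlinked ("hidden"), redacted records, nonsense and
# grant-number secondary IDs, and near-duplicate confounder trials
# (contradictory-phrase twins and post-hoc extension studies) that populate
# the high-similarity non-duplicate region.

#' Generator parameters
#'
#' Defaults are the "ictrp-like" preset: 9% of trials registered more than
#' once and 55% of duplicate clusters carrying secondary-ID links, echoing
#' the registry-scale corpus the analysis is designed for.
#'
#' @param n_trials number of underlying trials (>= 1).
#' @param n_registries number of registries (2-5 use realistic ID formats).
#' @param dup_rate fraction of trials registered two or more times.
#' @param known_link_fraction fraction of duplicate clusters whose records
#'   are linked by secondary IDs (recoverable by ID linkage); the rest are
#'   hidden.
#' @param title_perturbation per-word probability that a title word is
#'   perturbed in a given record (half deletions, half substitutions).
#' @param vocab_size size of the shared Zipf vocabulary.
#' @param zipf_exponent exponent of the Zipf rank-frequency law.
#' @param redaction_rate fraction of records with a redacted public title.
#' @param nonsense_id_rate fraction of records carrying a nonsense
#'   secondary ID ("Version 1" and the like).
#' @param grant_id_rate fraction of records carrying a US federal grant
#'   number shared across many unrelated trials.
#' @param confounder_rate fraction of trials that spawn a high-similarity
#'   non-duplicate twin (contradictory phrase or extension study).
#' @param seed integer seed; the corpus is byte-identical under a fixed
#'   seed.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(n_trials = 20000L,
                             n_registries = 5L,
                             dup_rate = 0.09,
                             known_link_fraction = 0.55,
                             title_perturbation = 0.08,
                             vocab_size = 2000L,
                             zipf_exponent = 1.07,
                             redaction_rate = 0.003,
                             nonsense_id_rate = 0.05,
                             grant_id_rate = 0.02,
                             confounder_rate = 0.02,
                             seed = 1L) {
  p <- list(
    n_trials = as.integer(n_trials), n_registries = as.integer(n_registries),
    dup_rate = dup_rate, known_link_fraction = known_link_fraction,
    title_perturbation = title_perturbation,
    vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
    redaction_rate = redaction_rate, nonsense_id_rate = nonsense_id_rate,
    grant_id_rate = grant_id_rate, confounder_rate = confounder_rate,
    seed = as.integer(seed)
  )
  fracs <- c(
    "dup_rate", "known_link_fraction", "title_perturbation",
    "redaction_rate", "nonsense_id_rate", "grant_id_rate", "confounder_rate"
  )
  for (f in fracs) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop("`", f, "` must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  if (p$n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (p$n_registries < 2L) stop("`n_registries` must be >= 2", call. = FALSE)
  if (p$vocab_size < 50L) stop("`vocab_size` must be >= 50", call. = FALSE)
  if (p$dup_rate == 0 && p$known_link_fraction > 0) {
    warning("dup_rate is 0: known_link_fraction has no effect", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

# Deterministic pronounceable pseudo-vocabulary.
make_vocab <- function(v) {
  syl <- c(
    "ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
    "ka", "ke", "ki", "ko", "ku", "la", "le", "li", "lo", "lu",
    "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
    "ra", "re", "ri", "ro", "ru", "sa", "se", "si", "so", "su",
    "ta", "te", "ti", "to", "tu", "va", "ve", "vi", "vo", "vu"
  )
  two <- as.vector(outer(syl, syl, paste0))
  if (v <= length(two)) {
    return(two[seq_len(v)])
  }
  three <- as.vector(outer(two, syl, paste0))
  c(two, three)[seq_len(v)]
}

METHOD_WORDS <- c(
  "randomized", "controlled", "placebo", "double", "blind", "phase",
  "study", "trial", "safety", "efficacy", "multicenter", "openlabel",
  "crossover", "parallel", "pilot", "prospective", "observational",
  "cohort", "healthy", "volunteers", "patients", "evaluation",
  "comparison", "assessment", "treatment", "tolerability"
)

EU_STATES <- c("BE", "CZ", "DE", "ES", "FR", "HU", "IT", "LV", "NL", "PL")

NONSENSE_IDS <- c("Version 1", "Nil known", "None", "N/A")
GRANT_IDS <- c("R01HL048744", "R01CA060553", "U01AI069423")

registry_table <- function(k) {
  base <- tibble(
    registry = c(
      "ClinicalTrials.gov", "EUCTR", "ISRCTN", "JPRN", "ANZCTR"
    )[seq_len(min(k, 5L))]
  )
  if (k > 5L) {
    base <- rbind(base, tibble(registry = sprintf("REG%02d", 6:k)))
  }
  base
}

registry_record_id <- function(registry, serial) {
  out <- character(length(registry))
  out[registry == "ClinicalTrials.gov"] <-
    sprintf("NCT%08d", 10000000L + serial[registry == "ClinicalTrials.gov"])
  eu <- registry == "EUCTR"
  out[eu] <- sprintf(
    "EUCTR%04d-%06d-%02d",
    2004L + serial[eu] %% 11L, serial[eu], serial[eu] %% 97L
  )
  out[registry == "ISRCTN"] <-
    sprintf("ISRCTN%08d", 10000000L + serial[registry == "ISRCTN"])
  out[registry == "JPRN"] <-
    sprintf("JPRN-UMIN%09d", serial[registry == "JPRN"])
  out[registry == "ANZCTR"] <-
    sprintf("ACTRN126%08d", 10000000L + serial[registry == "ANZCTR"])
  other <- !nzchar(out)
  out[other] <- sprintf("%s-%07d", registry[other], serial[other])
  out
}

#' Generate a synthetic registry corpus with ground truth
#'
#' @param params `generator_params` object.
#' @return list of class `synthetic_corpus` with elements:
#'   * `variants`: tibble in the [parse_corpus()] layout (one row per
#'     variant; EUCTR records may carry several member-state variants);
#'   * `truth`: list of class `registry_truth` with `records` (tibble
#'     `record_id`, `trial_id`), `trials` (tibble `trial_id`, `n_records`,
#'     `known_link`, `confounder_of`) and `params`.
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, generate_corpus_impl(params))
}

generate_corpus_impl <- function(params) {
  n <- params$n_trials
  v <- params$vocab_size
  vocab <- make_vocab(v)
  zipf_p <- (seq_len(v))^(-params$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)
  zipf_sample <- function(k) vocab[sample.int(v, k, replace = TRUE, prob = zipf_p)]

  # ---- trials ------------------------------------------------------------
  title_mat <- matrix(zipf_sample(n * 8L), nrow = n)
  agent_tok <- sprintf("agent%05d", seq_len(n))
  focus_tok <- sprintf("proto%05d", seq_len(n))
  title_words <- lapply(seq_len(n), function(i) {
    c(title_mat[i, ], agent_tok[i], focus_tok[i])
  })
  method_idx <- matrix(
    sample.int(length(METHOD_WORDS), n * 3L, replace = TRUE),
    nrow = n
  )
  method_words <- lapply(seq_len(n), function(i) METHOD_WORDS[method_idx[i, ]])

  disease_tok <- sprintf("disease%03d", sample.int(300L, n, replace = TRUE))
  cond_mat <- matrix(zipf_sample(n * 3L), nrow = n)
  out_mat <- matrix(zipf_sample(n * 4L), nrow = n)
  incl_mat <- matrix(zipf_sample(n * 6L), nrow = n)
  ivn_mat <- matrix(zipf_sample(n * 2L), nrow = n)

  n_sponsors <- max(20L, ceiling(n / 25))
  sponsor_idx <- sample.int(n_sponsors, n, replace = TRUE)
  sponsor_name <- sprintf("Sponsor %03d Inc", sponsor_idx)
  protocol_id <- sprintf("SP%03d-%04d", sponsor_idx, seq_len(n))

  is_dup <- runif(n) < params$dup_rate
  extra <- ifelse(is_dup, 1L + (runif(n) < 0.11), 0L)
  # plant the known fraction exactly, stratified by cluster size, so that
  # the corpus realizes the requested hidden fraction up to rounding (the
  # planted fraction is the estimand recovery studies are judged against)
  known_link <- rep(FALSE, n)
  for (sz in unique(extra[is_dup])) {
    stratum <- which(is_dup & extra == sz)
    n_known <- round_half_up(params$known_link_fraction * length(stratum))
    if (n_known > 0L) {
      known_link[stratum[sample.int(length(stratum), n_known)]] <- TRUE
    }
  }

  trials <- tibble(
    trial_id = seq_len(n),
    n_records = 1L + extra,
    known_link = known_link,
    confounder_of = NA_integer_,
    sponsor = sponsor_name,
    protocol_id = protocol_id
  )

  # ---- confounder twins: separate trials, near-identical titles ---------
  conf_parent <- which(runif(n) < params$confounder_rate)
  twin_words <- title_words
  if (length(conf_parent) > 0L) {
    twin_kind <- sample(c("antonym", "extension"), length(conf_parent),
      replace = TRUE
    )
    twin_ids <- n + seq_along(conf_parent)
    for (k in seq_along(conf_parent)) {
      p_id <- conf_parent[k]
      if (twin_kind[k] == "antonym") {
        title_words[[p_id]] <- c(title_words[[p_id]], "fed")
        twin_words[[length(twin_words) + 1L]] <-
          c(twin_words[[p_id]], "fasting")
      } else {
        twin_words[[length(twin_words) + 1L]] <-
          c(twin_words[[p_id]], "extension")
      }
    }
    title_words <- c(title_words, twin_words[n + seq_along(conf_parent)])
    trials <- rbind(trials, tibble(
      trial_id = twin_ids,
      n_records = 1L,
      known_link = FALSE,
      confounder_of = conf_parent,
      sponsor = sponsor_name[conf_parent],
      # same sponsor, same ID format, different serial (rule-3 material)
      protocol_id = sprintf("SP%03d-%04d", sponsor_idx[conf_parent],
        conf_parent + 5000L
      )
    ))
    pr <- conf_parent
    method_words <- c(method_words, method_words[pr])
    disease_tok <- c(disease_tok, disease_tok[pr])
    cond_mat <- rbind(cond_mat, cond_mat[pr, , drop = FALSE])
    out_mat <- rbind(out_mat, out_mat[pr, , drop = FALSE])
    incl_mat <- rbind(incl_mat, incl_mat[pr, , drop = FALSE])
    ivn_mat <- rbind(ivn_mat, ivn_mat[pr, , drop = FALSE])
    agent_tok <- c(agent_tok, agent_tok[pr])
  }
  nt <- nrow(trials)

  # ---- records -----------------------------------------------------------
  reg_tab <- registry_table(params$n_registries)
  rec_trial <- rep.int(trials$trial_id, trials$n_records)
  rec_copy <- unlist(lapply(trials$n_records, seq_len))
  n_rec <- length(rec_trial)
  # distinct registries within a cluster (duplicates live across registries)
  rec_registry <- character(n_rec)
  pos <- 1L
  for (t in seq_len(nt)) {
    k <- trials$n_records[t]
    rec_registry[pos:(pos + k - 1L)] <-
      reg_tab$registry[sample.int(nrow(reg_tab), k)]
    pos <- pos + k
  }
  rec_id <- registry_record_id(rec_registry, seq_len(n_rec))

  # perturbed per-record title words
  perturb <- function(words) {
    hit <- runif(length(words)) < params$title_perturbation
    if (!any(hit)) {
      return(words)
    }
    drop <- hit & runif(length(words)) < 0.5
    subst <- hit & !drop
    words[subst] <- zipf_sample(sum(subst))
    words[!drop]
  }
  rec_title_words <- lapply(seq_len(n_rec), function(r) {
    perturb(title_words[[rec_trial[r]]])
  })
  public_title <- vapply(rec_title_words, paste, character(1), collapse = " ")
  scientific_title <- vapply(seq_len(n_rec), function(r) {
    paste(c(method_words[[rec_trial[r]]], rec_title_words[[r]]), collapse = " ")
  }, character(1))
  has_acro <- runif(n_rec) < 0.2
  acronym <- ifelse(has_acro, sprintf("ACRO%05d", rec_trial), "")

  # registry dialects: richer outcomes on ClinicalTrials.gov, richer
  # interventions on EUCTR
  t_of <- rec_trial
  conditions <- lapply(seq_len(n_rec), function(r) {
    c(disease_tok[t_of[r]], cond_mat[t_of[r], ])
  })
  interventions <- lapply(seq_len(n_rec), function(r) {
    base <- c(agent_tok[t_of[r]], ivn_mat[t_of[r], ])
    if (rec_registry[r] == "EUCTR") c(base, zipf_sample(2L)) else base
  })
  outcomes <- lapply(seq_len(n_rec), function(r) {
    base <- out_mat[t_of[r], ]
    if (rec_registry[r] == "ClinicalTrials.gov") c(base, zipf_sample(3L)) else base
  })
  inclusion <- vapply(seq_len(n_rec), function(r) {
    paste(incl_mat[t_of[r], ], collapse = " ")
  }, character(1))

  date_registered <- as.Date("2005-01-01") +
    sample.int(3700L, n_rec, replace = TRUE)
  has_enrol <- runif(n_rec) < 0.8
  date_enrolment <- date_registered + sample.int(300L, n_rec, replace = TRUE)
  date_enrolment[!has_enrol] <- NA

  # ---- secondary IDs -----------------------------------------------------
  # every record carries its trial's protocol ID; later records of a known
  # cluster reference the first record's registry ID (sometimes as a bare
  # EudraCT number, sometimes packed into one field with the protocol ID)
  first_rec <- rec_id[match(rec_trial, rec_trial)]
  known_of_rec <- trials$known_link[match(rec_trial, trials$trial_id)]
  link_target <- ifelse(rec_copy > 1L & known_of_rec, first_rec, NA_character_)
  bare_ok <- !is.na(link_target) & grepl("^EUCTR", link_target) & runif(n_rec) < 0.5
  link_target[bare_ok] <- sub("^EUCTR", "", link_target[bare_ok])

  proto_of_rec <- trials$protocol_id[match(rec_trial, trials$trial_id)]
  pack <- runif(n_rec) < 0.25
  nonsense <- runif(n_rec) < params$nonsense_id_rate
  grant <- runif(n_rec) < params$grant_id_rate
  nonsense_val <- sample(NONSENSE_IDS, n_rec, replace = TRUE)
  grant_val <- sample(GRANT_IDS, n_rec, replace = TRUE)
  secondary_ids <- lapply(seq_len(n_rec), function(r) {
    ids <- character(0)
    if (!is.na(link_target[r]) && pack[r]) {
      ids <- c(ids, paste0(proto_of_rec[r], "; ", link_target[r]))
    } else {
      ids <- c(ids, proto_of_rec[r])
      if (!is.na(link_target[r])) ids <- c(ids, link_target[r])
    }
    if (nonsense[r]) ids <- c(ids, nonsense_val[r])
    if (grant[r]) ids <- c(ids, grant_val[r])
    ids
  })

  # ---- redaction ---------------------------------------------------------
  redact <- runif(n_rec) < params$redaction_rate
  public_title[redact] <- ifelse(
    rec_registry[redact] == "EUCTR",
    "N/A",
    "[Trial of device that is not approved or cleared by the U.S. FDA]"
  )
  scientific_title[redact] <- ""
  acronym[redact] <- ""

  sponsors <- as.list(trials$sponsor[match(rec_trial, trials$trial_id)])
  country_pool <- c(
    "United States", "Germany", "France", "Japan", "Australia",
    "Netherlands", "Canada", "United Kingdom"
  )
  countries <- lapply(
    sample.int(length(country_pool), n_rec, replace = TRUE),
    function(i) country_pool[i]
  )

  # ---- expand EUCTR records into member-state variants -------------------
  is_eu <- rec_registry == "EUCTR"
  n_var_of <- ifelse(is_eu, 1L + (runif(n_rec) < 0.5), 1L)
  var_rec <- rep.int(seq_len(n_rec), n_var_of)
  var_copy <- unlist(lapply(n_var_of, seq_len))
  suffix <- character(length(var_rec))
  var_id <- rec_id[var_rec]
  eu_rows <- is_eu[var_rec]
  if (any(eu_rows)) {
    states <- unlist(lapply(n_var_of[is_eu], function(k) {
      sample(EU_STATES, k)
    }))
    suffix[eu_rows] <- states
    var_id[eu_rows] <- paste0(rec_id[var_rec[eu_rows]], "-", states)
  }
  var_date <- date_registered[var_rec] + ifelse(var_copy > 1L,
    sample.int(90L, length(var_rec), replace = TRUE), 0L
  )

  variants <- tibble(
    registry_id = var_id,
    registry = rec_registry[var_rec],
    variant_suffix = suffix,
    public_title = public_title[var_rec],
    scientific_title = scientific_title[var_rec],
    acronym = acronym[var_rec],
    secondary_ids = secondary_ids[var_rec],
    conditions = conditions[var_rec],
    interventions = interventions[var_rec],
    outcomes = outcomes[var_rec],
    inclusion_criteria = inclusion[var_rec],
    sponsors = sponsors[var_rec],
    date_registered = var_date,
    date_enrolment = date_enrolment[var_rec],
    countries = countries[var_rec]
  )

  truth <- structure(
    list(
      records = tibble(record_id = rec_id, trial_id = rec_trial),
      trials = trials[c("trial_id", "n_records", "known_link", "confounder_of")],
      params = params
    ),
    class = "registry_truth"
  )
  structure(list(variants = variants, truth = truth),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  s <- truth_summary(x$truth)
  cat(
    "<synthetic_corpus> ", nrow(x$variants), " variants, ", s$n_records,
    " records, ", s$n_trials, " trials (", s$n_known_pairs, " known / ",
    s$n_hidden_pairs, " hidden duplicate pairs)\n",
    sep = ""
  )
  invisible(x)
}

#' Summarize planted ground truth
#'
#' Exact counts from the record-to-trial map: trials, records, known and
#' hidden duplicate pairs (within-trial pairs of linked and unlinked
#' clusters respectively) and the hidden fraction
#' `hidden / (known + hidden)`.
#'
#' @param truth `registry_truth` from [generate_corpus()].
#' @return list with `n_trials`, `n_records`, `n_known_pairs`,
#'   `n_hidden_pairs`, `hidden_fraction`.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "registry_truth"))
  sizes <- table(truth$records$trial_id)
  sizes <- sizes[sizes >= 1]
  pairs <- choose(as.integer(sizes), 2)
  known <- truth$trials$known_link[
    match(as.integer(names(sizes)), truth$trials$trial_id)
  ]
  n_known <- sum(pairs[known])
  n_hidden <- sum(pairs[!known])
  list(
    n_trials = length(sizes),
    n_records = nrow(truth$records),
    n_known_pairs = n_known,
    n_hidden_pairs = n_hidden,
    hidden_fraction = if (n_known + n_hidden > 0) {
      n_hidden / (n_known + n_hidden)
    } else {
      NA_real_
    }
  )
}

#' True duplicate pairs from planted truth
#'
#' All within-trial record pairs with their known/hidden label.
#'
#' @param truth `registry_truth`.
#' @return tibble `id_a`, `id_b`, `known` (TRUE for linked clusters).
#' @export
truth_pairs <- function(truth) {
  stopifnot(inherits(truth, "registry_truth"))
  by_trial <- split(truth$records$record_id, truth$records$trial_id)
  by_trial <- by_trial[lengths(by_trial) > 1L]
  if (length(by_trial) == 0L) {
    return(tibble(id_a = character(0), id_b = character(0), known = logical(0)))
  }
  known_of <- setNames(truth$trials$known_link, truth$trials$trial_id)
  out <- lapply(names(by_trial), function(t) {
    ids <- sort(by_trial[[t]])
    k <- length(ids)
    i <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    j <- unlist(lapply(seq_len(k - 1L), function(p) (p + 1L):k))
    tibble(id_a = ids[i], id_b = ids[j], known = unname(known_of[t]))
  })
  res <- do.call(rbind, out)
  res[order(res$id_a, res$id_b), ]
}

#' Truth-oracle rating function
#'
#' Returns a rating function suitable for [estimate_hidden()]'s `rate_fun`:
#' a sampled pair is rated `"duplicate"` exactly when both records belong
#' to the same planted trial.
#'
#' @param truth `registry_truth`.
#' @return function mapping a pairs tibble to a verdict vector.
#' @export
truth_oracle <- function(truth) {
  trial_of <- setNames(truth$records$trial_id, truth$records$record_id)
  function(pairs) {
    same <- trial_of[pairs$id_a] == trial_of[pairs$id_b]
    ifelse(!is.na(same) & same, "duplicate", "non_duplicate")
  }
}
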