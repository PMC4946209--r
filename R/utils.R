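# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state (the generator and samplers must not leak global state).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so `round_half_up(0.5) == 1`), the convention used when reporting
#' integer percentages. Base R's `round()` rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 47.145))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Collapse repeated whitespace and trim; keeps single spaces between words.
squish <- function(x) {
  trimws(gsub("[ \t\r\n]+", " ", x))
}

# Paste non-empty pieces with a single space.
paste_fields <- function(...) {
  pieces <- list(...)
  n <- max(lengths(pieces))
  pieces <- lapply(pieces, function(p) {
    p <- as.character(p)
    p[is.na(p)] <- ""
    rep_len(p, n)
  })
  out <- do.call(paste, c(pieces, sep = " "))
  squish(out)
}

# Canonical unordered pair order: id_a < id_b lexicographically.
canonical_pairs <- function(id_a, id_b) {
  swap <- id_a > id_b
  tmp <- id_a[swap]
  id_a[swap] <- id_b[swap]
  id_b[swap] <- tmp
  list(id_a = id_a, id_b = id_b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
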