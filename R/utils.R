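# Month keys, classed conditions, RNG scoping.

#' Classed error helpers
#'
#' All user-facing failures in the package are signalled as classed
#' conditions so callers (and the command-line wrapper) can map them to
#' exit codes: validation errors, I/O errors and degenerate-data errors.
#' @name hpu-conditions
#' @keywords internal
NULL

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("hpu_validation_error", "hpu_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("hpu_io_error", "hpu_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("hpu_degenerate_error", "hpu_error")))
}

#' Year-month keys
#'
#' Months are the only time resolution in the package and are serialized as
#' `"YYYY-MM"` throughout.  `ym()` builds a key from year and month,
#' `ym_parse()` splits keys back into year/month integers, and `ym_seq()`
#' enumerates the inclusive range between two keys.
#'
#' @param year,month integer vectors (month in 1..12).
#' @param x character vector of `"YYYY-MM"` keys (a single `"YYYY-M"` digit
#'   is tolerated on input and canonicalized).
#' @param from,to `"YYYY-MM"` keys, `from <= to`.
#' @return `ym()` and `ym_seq()` return character keys; `ym_parse()` a
#'   data.frame with columns `year` and `month`.
#' @examples
#' ym(2003, 1)
#' ym_seq("2005-11", "2006-02")
#' @export
ym <- function(year, month) {
  year <- as.integer(year)
  month <- as.integer(month)
  bad <- is.na(year) | is.na(month) | month < 1L | month > 12L |
    year < 1900L | year > 2100L
  if (any(bad)) {
    stop_validation("invalid year-month: year must be in 1900..2100 and month in 1..12")
  }
  sprintf("%04d-%02d", year, month)
}

#' @rdname ym
#' @export
ym_parse <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]{4}-[0-9]{1,2}$", x)
  if (!all(ok)) {
    stop_validation("malformed month key (expected \"YYYY-MM\"): ",
                    paste(utils::head(x[!ok], 3L), collapse = ", "))
  }
  year <- as.integer(substr(x, 1L, 4L))
  month <- as.integer(sub("^[0-9]{4}-", "", x))
  if (any(month < 1L | month > 12L)) {
    stop_validation("month key outside 1..12: ",
                    paste(utils::head(x[month < 1L | month > 12L], 3L), collapse = ", "))
  }
  data.frame(year = year, month = month)
}

#' @rdname ym
#' @export
ym_seq <- function(from, to) {
  a <- ym_parse(from)
  b <- ym_parse(to)
  ia <- a$year * 12L + (a$month - 1L)
  ib <- b$year * 12L + (b$month - 1L)
  if (ia > ib) stop_validation("month range start ", from, " is after end ", to)
  idx <- ia:ib
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

# Canonicalize a vector of "YYYY-M"/"YYYY-MM" keys to "YYYY-MM".
ym_canon <- function(x) {
  p <- ym_parse(x)
  ym(p$year, p$month)
}

# Evaluate `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop_validation("seed must be a finite integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic 31-bit hash of a string, for hierarchical seed derivation.
hash31 <- function(s) {
  v <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (cp in v) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a parent seed and string/integer components.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (part in list(...)) {
    hp <- if (is.character(part)) hash31(part) else as.numeric(part) %% 2147483647
    h <- (h * 48271 + hp + 1) %% 2147483647
  }
  as.integer(h)
}
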