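# Newspapers x months count panels and coverage masks.

#' Count panels
#'
#' A `count_panel` is a newspapers-by-months matrix of nonnegative integer
#' counts; `NA` marks a cell in a declared coverage gap (distinct from a
#' legitimate zero-article month).  Rows are newspapers, columns are
#' strictly increasing `"YYYY-MM"` keys.
#'
#' @param counts numeric matrix, rows named by newspaper, columns by month.
#' @return the validated matrix with class `count_panel`.
#' @keywords internal
#' @export
count_panel <- function(counts) {
  if (!is.matrix(counts)) stop_validation("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("count panel must have newspaper rownames and month colnames")
  }
  months <- ym_canon(colnames(counts))
  if (is.unsorted(months, strictly = TRUE)) {
    stop_validation("panel months must be strictly increasing with no duplicates")
  }
  colnames(counts) <- months
  vals <- counts[!is.na(counts)]
  if (any(vals < 0)) stop_validation("panel counts must be nonnegative")
  structure(counts, class = c("count_panel", class(counts)))
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf("<count_panel> %d newspapers x %d months, %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(unclass(x), ...)
  invisible(x)
}

#' Expand and validate coverage-gap declarations
#'
#' Gaps are declared metadata, not inferred from zeros: a covered month with
#' zero articles is a legitimate zero.  Declarations map newspaper ids to
#' `"YYYY-MM"` keys or bare `"YYYY"` years (each year expands to its 12
#' months).
#'
#' @param gaps a named list mapping newspaper id to a character vector of
#'   month keys and/or years, or a path to a YAML/JSON file holding such a
#'   map, or `NULL` (no gaps).
#' @param roster character vector of known newspaper ids; a gap declared for
#'   an unknown newspaper is a validation error.
#' @return a named list mapping newspaper id to sorted `"YYYY-MM"` keys.
#' @examples
#' expand_gaps(list(q = "2006"), roster = c("p", "q"))$q
#' @export
expand_gaps <- function(gaps, roster) {
  if (is.null(gaps) || length(gaps) == 0L) return(list())
  if (is.character(gaps) && length(gaps) == 1L && file.exists(gaps)) {
    gaps <- if (grepl("\\.ya?ml$", gaps)) yaml::read_yaml(gaps) else jsonlite::fromJSON(gaps)
  }
  if (!is.list(gaps) || is.null(names(gaps)) || any(!nzchar(names(gaps)))) {
    stop_validation("gap declarations must be a named list (newspaper -> months)")
  }
  unknown <- setdiff(names(gaps), roster)
  if (length(unknown)) {
    stop_validation("gap declared for unknown newspaper(s): ",
                    paste(unknown, collapse = ", "))
  }
  out <- lapply(gaps, function(v) {
    v <- as.character(unlist(v, use.names = FALSE))
    keys <- unlist(lapply(v, function(s) {
      if (grepl("^[0-9]{4}$", s)) ym(rep(as.integer(s), 12L), 1:12) else ym_canon(s)
    }), use.names = FALSE)
    sort(unique(keys))
  })
  out[lengths(out) > 0L]
}

#' Coverage mask for a corpus
#'
#' TRUE where a newspaper-month is covered (not inside a declared gap);
#' zero-article covered months stay covered.
#'
#' @param corpus an [hpu_corpus()].
#' @param declared_gaps gap declarations, see [expand_gaps()].
#' @return a logical newspapers-by-months matrix over the corpus roster and
#'   month range.
#' @export
coverage_mask <- function(corpus, declared_gaps = NULL) {
  stopifnot(inherits(corpus, "hpu_corpus"))
  months <- ym_seq(corpus$month_range[1L], corpus$month_range[2L])
  gaps <- expand_gaps(declared_gaps, corpus$newspapers)
  mask <- matrix(TRUE, nrow = length(corpus$newspapers), ncol = length(months),
                 dimnames = list(corpus$newspapers, months))
  for (np in names(gaps)) {
    hit <- intersect(gaps[[np]], months)
    mask[np, hit] <- FALSE
  }
  mask
}

#' Monthly total-article panel
#'
#' Tabulates the total number of articles per newspaper per month over the
#' corpus month range.  Months with no articles are 0 when covered and `NA`
#' when inside a declared coverage gap.
#'
#' @inheritParams coverage_mask
#' @return a [count_panel()] of total article counts.
#' @export
monthly_totals <- function(corpus, declared_gaps = NULL) {
  stopifnot(inherits(corpus, "hpu_corpus"))
  months <- ym_seq(corpus$month_range[1L], corpus$month_range[2L])
  a <- corpus$articles
  tab <- table(factor(a$newspaper, levels = corpus$newspapers),
               factor(a$month_key, levels = months))
  counts <- matrix(as.numeric(tab), nrow = length(corpus$newspapers),
                   dimnames = list(corpus$newspapers, months))
  mask <- coverage_mask(corpus, declared_gaps)
  if (any(counts[!mask] > 0)) {
    bad <- which(!mask & counts > 0, arr.ind = TRUE)[1L, ]
    stop_validation("articles present in declared gap: ",
                    rownames(counts)[bad[1L]], " ", colnames(counts)[bad[2L]])
  }
  counts[!mask] <- NA_real_
  count_panel(counts)
}
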