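# Newspaper corpora: construction, validation, JSONL/CSV round-trip.

#' Newspaper corpus objects
#'
#' An `hpu_corpus` holds an ordered collection of newspaper articles
#' together with the newspaper roster and the inclusive month range of the
#' study window.  Each article carries a newspaper identifier, a publication
#' year and month, a corpus-unique article id, and its full text.
#'
#' @param articles a data.frame with columns `newspaper`, `year`, `month`,
#'   `text` and optionally `article_id` (assigned sequentially as
#'   `"a000001"`, ... when absent).
#' @param newspapers optional roster of newspaper ids; defaults to the
#'   distinct newspapers observed, in order of first appearance.  Every
#'   article's newspaper must be on the roster.
#' @param month_range optional length-2 character vector of `"YYYY-MM"`
#'   keys; defaults to the span of observed months.  Every article must fall
#'   inside it.
#' @return an object of class `hpu_corpus`: a list with elements
#'   `articles` (data.frame with a `month_key` column added), `newspapers`
#'   and `month_range`.
#' @examples
#' co <- hpu_corpus(data.frame(
#'   newspaper = "renmin", year = 2003, month = 1, text = "some text"))
#' co$month_range
#' @seealso [read_corpus()], [monthly_totals()]
#' @export
hpu_corpus <- function(articles, newspapers = NULL, month_range = NULL) {
  if (!is.data.frame(articles)) stop_validation("articles must be a data.frame")
  need <- c("newspaper", "year", "month", "text")
  missing_cols <- setdiff(need, names(articles))
  if (length(missing_cols)) {
    stop_validation("articles is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(articles) == 0L) stop_validation("empty corpus: no articles")
  articles$newspaper <- as.character(articles$newspaper)
  articles$year <- as.integer(articles$year)
  articles$month <- as.integer(articles$month)
  articles$text <- enc2utf8(as.character(articles$text))
  if (is.null(articles$article_id)) {
    articles$article_id <- sprintf("a%06d", seq_len(nrow(articles)))
  }
  articles$article_id <- as.character(articles$article_id)

  bad_month <- which(is.na(articles$month) | articles$month < 1L | articles$month > 12L)
  if (length(bad_month)) {
    stop_validation("article ", articles$article_id[bad_month[1L]],
                    ": month must be in 1..12 (got ", articles$month[bad_month[1L]], ")")
  }
  bad_year <- which(is.na(articles$year) | articles$year < 1900L | articles$year > 2100L)
  if (length(bad_year)) {
    stop_validation("article ", articles$article_id[bad_year[1L]],
                    ": year must be in 1900..2100")
  }
  if (any(!nzchar(trimws(articles$text)))) {
    stop_validation("article text must be non-empty after whitespace stripping")
  }
  if (anyDuplicated(articles$article_id)) {
    dup <- articles$article_id[duplicated(articles$article_id)][1L]
    stop_validation("duplicate article_id: ", dup)
  }

  articles$month_key <- ym(articles$year, articles$month)

  if (is.null(newspapers)) {
    newspapers <- unique(articles$newspaper)
  } else {
    newspapers <- as.character(newspapers)
    if (anyDuplicated(newspapers)) stop_validation("duplicate newspaper id in roster")
    off <- setdiff(articles$newspaper, newspapers)
    if (length(off)) {
      stop_validation("article newspaper(s) not on roster: ", paste(off, collapse = ", "))
    }
  }
  if (is.null(month_range)) {
    month_range <- range(articles$month_key)
  } else {
    if (length(month_range) != 2L) stop_validation("month_range must have length 2")
    month_range <- ym_canon(month_range)
    span <- ym_seq(month_range[1L], month_range[2L])
    off <- setdiff(articles$month_key, span)
    if (length(off)) {
      stop_validation("article month(s) outside month_range: ", paste(off, collapse = ", "))
    }
  }

  articles <- articles[, c("newspaper", "year", "month", "article_id",
                           "text", "month_key")]
  rownames(articles) <- NULL
  structure(
    list(articles = articles, newspapers = newspapers, month_range = month_range),
    class = "hpu_corpus"
  )
}

#' @export
print.hpu_corpus <- function(x, ...) {
  cat(sprintf("<hpu_corpus> %d articles, %d newspapers, %s .. %s\n",
              nrow(x$articles), length(x$newspapers),
              x$month_range[1L], x$month_range[2L]))
  invisible(x)
}

#' Number of articles in a corpus
#' @param corpus an [hpu_corpus()].
#' @return integer article count.
#' @export
n_articles <- function(corpus) {
  stopifnot(inherits(corpus, "hpu_corpus"))
  nrow(corpus$articles)
}

#' Read a newspaper corpus from disk
#'
#' Reads a line-delimited JSON (one object per line with keys `newspaper`,
#' `year`, `month`, `text`, optional `id`) or CSV (same columns, header row)
#' corpus file.  Input must be UTF-8; records that fail to parse are a hard
#' error naming the line, never silently skipped, since dropped records
#' would bias the downstream count panels.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`.
#' @param newspapers,month_range optional roster / window overrides passed
#'   to [hpu_corpus()].
#' @return an [hpu_corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"),
                        newspapers = NULL, month_range = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("corpus file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop_validation("empty corpus file: ", path)
    recs <- vector("list", length(lines))
    for (k in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[k]]),
                      error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) {
        stop_validation("malformed JSONL record at line ", k, " of ", path)
      }
      need <- c("newspaper", "year", "month", "text")
      if (!all(need %in% names(rec))) {
        stop_validation("record at line ", k, " lacks required key(s): ",
                        paste(setdiff(need, names(rec)), collapse = ", "))
      }
      recs[[k]] <- data.frame(
        newspaper = as.character(rec$newspaper),
        year = as.integer(rec$year),
        month = as.integer(rec$month),
        text = as.character(rec$text),
        article_id = if (!is.null(rec$id)) as.character(rec$id) else NA_character_,
        stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, recs)
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
      error = function(e) stop_validation("malformed CSV corpus file ", path, ": ",
                                          conditionMessage(e))
    )
    if (nrow(df) == 0L) stop_validation("empty corpus file: ", path)
    if ("id" %in% names(df) && !"article_id" %in% names(df)) {
      names(df)[names(df) == "id"] <- "article_id"
    }
  }
  if (!is.null(df$article_id) && all(is.na(df$article_id))) df$article_id <- NULL
  hpu_corpus(df, newspapers = newspapers, month_range = month_range)
}

#' Write a newspaper corpus to disk
#'
#' Inverse of [read_corpus()]: the written file re-reads into an equal
#' corpus, article order preserved.
#'
#' @param corpus an [hpu_corpus()].
#' @inheritParams read_corpus
#' @return the path, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "hpu_corpus"))
  if (!dir.exists(dirname(path))) stop_io("directory does not exist: ", dirname(path))
  a <- corpus$articles
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(a)), function(k) {
      jsonlite::toJSON(
        list(newspaper = a$newspaper[k], year = a$year[k], month = a$month[k],
             text = a$text[k], id = a$article_id[k]),
        auto_unbox = TRUE
      )
    }, character(1L))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    df <- a[, c("newspaper", "year", "month", "article_id", "text")]
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
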