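# Three-category screening of article texts.

# Fixed-pattern detection matrix: rows = texts, one column per term.
# Texts and terms are both NFKC-normalized before comparison.
.detect_terms <- function(texts, terms) {
  texts <- stringi::stri_trans_nfkc(enc2utf8(texts))
  vapply(terms,
         function(term) stringi::stri_detect_fixed(texts, term),
         logical(length(texts)))
}

.category_hit <- function(texts, terms) {
  m <- .detect_terms(texts, terms)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  rowSums(m) > 0L
}

#' Screen one article against a lexicon
#'
#' An article is a target article when its text contains at least one term
#' from each of the three lexicon categories, by plain substring containment
#' on the NFKC-normalized text (no word segmentation).  The per-category hit
#' lists are returned for audit transparency.
#'
#' @param article an article row of an [hpu_corpus()] (any list/data.frame
#'   with a `text` field), or a plain character string.
#' @param lexicon an [hpu_lexicon()].
#' @return a list with `match` (logical) and `hits`, a list of the matched
#'   terms per category.
#' @examples
#' lex <- load_lexicon()
#' article_matches("卫生政府不确定", lex)$match
#' @export
article_matches <- function(article, lexicon) {
  stopifnot(inherits(lexicon, "hpu_lexicon"))
  text <- if (is.character(article)) article else article$text
  if (length(text) != 1L) stop_validation("article_matches screens one article at a time")
  text <- stringi::stri_trans_nfkc(enc2utf8(text))
  hits <- lapply(lexicon[c("health", "policy", "uncertainty")], function(terms) {
    terms[stringi::stri_detect_fixed(text, terms)]
  })
  list(match = all(lengths(hits) > 0L), hits = hits)
}

# Vectorized screening of many texts; returns a logical vector.
screen_texts <- function(texts, lexicon) {
  if (!length(texts)) return(logical(0L))
  .category_hit(texts, lexicon$health) &
    .category_hit(texts, lexicon$policy) &
    .category_hit(texts, lexicon$uncertainty)
}

#' Monthly target-article panel
#'
#' Counts, per newspaper-month cell, the articles satisfying the
#' three-category criterion.  Cells in declared coverage gaps are `NA`; each
#' article counts at most once regardless of how many terms hit.  The result
#' is cell-wise bounded by [monthly_totals()].
#'
#' @inheritParams coverage_mask
#' @param lexicon an [hpu_lexicon()].
#' @return a [count_panel()] of target-article counts.
#' @export
count_matches <- function(corpus, lexicon, declared_gaps = NULL) {
  stopifnot(inherits(corpus, "hpu_corpus"), inherits(lexicon, "hpu_lexicon"))
  months <- ym_seq(corpus$month_range[1L], corpus$month_range[2L])
  a <- corpus$articles
  is_target <- screen_texts(a$text, lexicon)
  tab <- table(factor(a$newspaper[is_target], levels = corpus$newspapers),
               factor(a$month_key[is_target], levels = months))
  counts <- matrix(as.numeric(tab), nrow = length(corpus$newspapers),
                   dimnames = list(corpus$newspapers, months))
  mask <- coverage_mask(corpus, declared_gaps)
  counts[!mask] <- NA_real_
  count_panel(counts)
}

#' Target-article ids per newspaper
#'
#' Lists, for each newspaper, the ids of its articles that satisfy the
#' screening criterion — the sampling frame for [sample_for_audit()].
#'
#' @inheritParams count_matches
#' @return named list mapping newspaper id to a character vector of
#'   article ids.
#' @export
target_article_ids <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "hpu_corpus"), inherits(lexicon, "hpu_lexicon"))
  a <- corpus$articles
  hit <- a[screen_texts(a$text, lexicon), , drop = FALSE]
  out <- split(hit$article_id, factor(hit$newspaper, levels = corpus$newspapers))
  lapply(out, as.character)
}
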