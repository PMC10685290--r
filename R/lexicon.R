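# Three-category keyword lexicons.

# Chinese term sets for the builtin "hpu-china-2003" lexicon.  The English
# glosses: health = health care/medicine; policy = policy/measures,
# government/authority, country leaders, regulation, health care reform;
# uncertainty = uncertain/unclear, volatile, unstable, unpredictable,
# plunge/surge.
.builtin_lexicons <- list(
  "hpu-china-2003" = list(
    health = c("卫生", "医药"),
    policy = c(
      "制度", "体制", "战略", "措施",
      "条例",
      "政府", "国务院", "人大",
      "人民代表大会",
      "主席", "总书记", "总理",
      "整治", "监管", "规章",
      "医改", "医疗改革", "医保"
    ),
    uncertainty = c(
      "不确定", "不明确",
      "波动", "不稳",
      "不明朗", "未明",
      "难料", "难以预计", "难以预测",
      "难以估计", "难以预料",
      "流失", "亏损", "骤跌", "衰退",
      "激增", "滞后"
    )
  )
)

#' Keyword lexicons for article screening
#'
#' A lexicon carries three named term sets — health, policy and uncertainty
#' — and an article is a target article when its text contains at least one
#' term from each set.  Terms are NFKC-normalized and deduplicated at
#' construction so that full-width/half-width variants match uniformly.
#'
#' @param health,policy,uncertainty non-empty character vectors of literal
#'   terms (no empty strings).
#' @param name label for the lexicon.
#' @return an object of class `hpu_lexicon`: a list with elements `health`,
#'   `policy`, `uncertainty`, `name`.
#' @seealso [load_lexicon()] for the builtin Chinese lexicon and file input.
#' @export
hpu_lexicon <- function(health, policy, uncertainty, name = "custom") {
  norm_set <- function(terms, label) {
    terms <- as.character(unlist(terms, use.names = FALSE))
    if (!length(terms)) stop_validation("lexicon category '", label, "' is empty")
    terms <- stringi::stri_trans_nfkc(enc2utf8(terms))
    if (any(!nzchar(terms))) {
      stop_validation("lexicon category '", label, "' contains an empty term")
    }
    unique(terms)
  }
  structure(
    list(health = norm_set(health, "health"),
         policy = norm_set(policy, "policy"),
         uncertainty = norm_set(uncertainty, "uncertainty"),
         name = as.character(name)),
    class = "hpu_lexicon"
  )
}

#' @export
print.hpu_lexicon <- function(x, ...) {
  cat(sprintf("<hpu_lexicon> \"%s\": %d health, %d policy, %d uncertainty terms\n",
              x$name, length(x$health), length(x$policy), length(x$uncertainty)))
  invisible(x)
}

#' Load a keyword lexicon
#'
#' With the default name `"hpu-china-2003"` returns the builtin Chinese
#' lexicon (health-care/medicine; policy, government, leaders, regulation,
#' health-reform; uncertainty/volatility terms).  Otherwise `path` is read
#' as a YAML or JSON file with keys `health`, `policy`, `uncertainty`, each
#' a list of strings; a missing or empty category is a validation error.
#'
#' @param path builtin lexicon name or file path.
#' @return an [hpu_lexicon()].
#' @examples
#' lex <- load_lexicon()
#' length(lex$policy)
#' @export
load_lexicon <- function(path = "hpu-china-2003") {
  if (path %in% names(.builtin_lexicons)) {
    b <- .builtin_lexicons[[path]]
    return(hpu_lexicon(b$health, b$policy, b$uncertainty, name = path))
  }
  if (!file.exists(path)) stop_io("lexicon file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else yaml::read_yaml(path)
  need <- c("health", "policy", "uncertainty")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_validation("lexicon file missing categor",
                    if (length(miss) > 1L) "ies: " else "y: ",
                    paste(miss, collapse = ", "))
  }
  hpu_lexicon(raw$health, raw$policy, raw$uncertainty,
              name = if (!is.null(raw$name)) raw$name else basename(path))
}
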