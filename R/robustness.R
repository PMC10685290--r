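# Robustness battery: pairwise correlations, subgroup report, audit
# sampling, pass rates, external-series comparison.

#' Pearson correlation between two monthly index series
#'
#' Aligns the two series on their overlapping months and computes the
#' product-moment correlation with a two-sided p-value from the t transform
#' on n-2 degrees of freedom.  Requires at least 3 overlapping months and
#' both series non-constant on the overlap.
#'
#' @param a,b [hpu_index()] objects (or named numeric vectors keyed by
#'   month).
#' @param months optional restriction of the overlap to these months.
#' @return a list of class `hpu_cor` with elements `r`, `p_value`, `n`.
#' @examples
#' x <- hpu_index(c("2020-01" = 1, "2020-02" = 2, "2020-03" = 4))
#' y <- hpu_index(c("2020-01" = 1, "2020-02" = 3, "2020-03" = 5))
#' pearson(x, y)$r
#' @export
pearson <- function(a, b, months = NULL) {
  va <- if (inherits(a, "hpu_index")) index_values(a) else a
  vb <- if (inherits(b, "hpu_index")) index_values(b) else b
  if (is.null(names(va)) || is.null(names(vb))) {
    stop_validation("series must be named by month")
  }
  overlap <- intersect(names(va), names(vb))
  if (!is.null(months)) overlap <- intersect(overlap, ym_canon(months))
  if (length(overlap) < 3L) {
    stop_validation("insufficient overlap: ", length(overlap),
                    " common month(s), need at least 3")
  }
  x <- as.numeric(va[overlap])
  y <- as.numeric(vb[overlap])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_degenerate("correlation undefined: a series is constant on the overlap")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(overlap)),
            class = "hpu_cor")
}

#' @export
print.hpu_cor <- function(x, ...) {
  p_txt <- if (x$p_value < 0.001) "<.001" else sprintf("%.3f", x$p_value)
  cat(sprintf("r = %.3f, P %s%s, n = %d\n", x$r,
              if (x$p_value < 0.001) "" else "= ", p_txt, x$n))
  invisible(x)
}

#' Newspaper group presets
#'
#' The default subgroup axes of the robustness tests over the 11-newspaper
#' study roster: ALL (all 11), NNI (the 9 national papers, excluding the
#' two local Beijing papers), PNI (the 2 party newspapers) and MNI (the 9
#' metropolitan papers).
#'
#' @param roster character vector of the 11 newspaper ids, in the order:
#'   People's Daily, Guangming Daily, Southern Metropolis Daily, Yangcheng
#'   Evening News, New Express Daily, Xinmin Evening News, Morning News,
#'   Nanfang Daily, Morning Post, Beijing Evening News, Beijing Daily.
#' @return a named list of character vectors (group name -> members).
#' @export
newspaper_groups <- function(roster = default_newspapers()) {
  if (length(roster) != 11L) {
    stop_validation("group presets require the 11-newspaper roster, got ",
                    length(roster))
  }
  list(
    ALL = roster,
    NNI = roster[1:9],
    PNI = roster[1:2],
    MNI = roster[3:11]
  )
}

#' Default study newspaper identifiers
#'
#' Romanized ids for the 11 study newspapers, in roster order (party papers
#' first, then metropolitan papers, then the two local Beijing papers).
#'
#' @return character vector of length 11.
#' @export
default_newspapers <- function() {
  c("peoples_daily", "guangming_daily",
    "southern_metropolis_daily", "yangcheng_evening_news",
    "new_express_daily", "xinmin_evening_news", "morning_news",
    "nanfang_daily", "morning_post",
    "beijing_evening_news", "beijing_daily")
}

#' Subgroup robustness report
#'
#' Builds one index per newspaper group and computes all pairwise Pearson
#' correlations, flagging each pair against the robustness criterion
#' (default r >= 0.74).  A group whose index cannot be built is reported as
#' failed without aborting the remaining pairs.
#'
#' @inheritParams build_index
#' @param groups named list of newspaper-id vectors (see
#'   [newspaper_groups()]); at least 2 groups.
#' @param threshold pass criterion on r (default 0.74).
#' @return an object of class `hpu_robustness`: list with `r`, `p`, `n`
#'   (group x group matrices), `pass` (logical matrix, `r >= threshold`
#'   off-diagonal), `threshold`, `indexes` (the per-group [hpu_index()]s),
#'   and `errors` (per-group build failures, if any).
#' @export
robustness_report <- function(corpus, lexicon = load_lexicon(),
                              groups = newspaper_groups(corpus$newspapers),
                              threshold = 0.74, months = NULL,
                              declared_gaps = NULL) {
  if (length(groups) < 2L) stop_validation("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_validation("groups must be named")
  }
  if (threshold <= 0 || threshold > 1) stop_validation("threshold must be in (0, 1]")
  idx <- list()
  errors <- list()
  for (g in names(groups)) {
    res <- tryCatch(
      build_index(corpus, lexicon, newspapers = groups[[g]], months = months,
                  declared_gaps = declared_gaps, label = g),
      error = function(e) e
    )
    if (inherits(res, "error")) errors[[g]] <- conditionMessage(res)
    else idx[[g]] <- res
  }
  gn <- names(groups)
  k <- length(gn)
  r_mat <- matrix(NA_real_, k, k, dimnames = list(gn, gn))
  p_mat <- r_mat
  n_mat <- matrix(NA_integer_, k, k, dimnames = list(gn, gn))
  diag(r_mat) <- 1
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (is.null(idx[[gn[i]]]) || is.null(idx[[gn[j]]])) next
    ct <- tryCatch(pearson(idx[[gn[i]]], idx[[gn[j]]]), error = function(e) NULL)
    if (is.null(ct)) next
    r_mat[i, j] <- r_mat[j, i] <- ct$r
    p_mat[i, j] <- p_mat[j, i] <- ct$p_value
    n_mat[i, j] <- n_mat[j, i] <- ct$n
  }
  pass <- r_mat >= threshold
  structure(list(r = r_mat, p = p_mat, n = n_mat, pass = pass,
                 threshold = threshold, indexes = idx, errors = errors),
            class = "hpu_robustness")
}

#' @export
print.hpu_robustness <- function(x, ...) {
  cat(sprintf("Subgroup robustness (criterion r >= %.2f)\n", x$threshold))
  gn <- rownames(x$r)
  fmt_p <- function(p) {
    ifelse(is.na(p), "-", ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
  }
  for (g in gn) {
    cat(sprintf("%s\n", g))
    cat("  r:      ", paste(sprintf("%6s", ifelse(is.na(x$r[g, ]), "-",
                                                  sprintf("%.3f", x$r[g, ]))), collapse = " "), "\n")
    pv <- fmt_p(x$p[g, ])
    pv[g == gn] <- "-"
    cat("  P value:", paste(sprintf("%6s", pv), collapse = " "), "\n")
  }
  off <- x$pass
  diag(off) <- NA
  np <- sum(off, na.rm = TRUE) / 2
  nt <- sum(!is.na(off)) / 2
  cat(sprintf("pairs passing criterion: %d of %d\n", np, nt))
  if (length(x$errors)) {
    for (g in names(x$errors)) cat(sprintf("build failed for %s: %s\n", g, x$errors[[g]]))
  }
  invisible(x)
}

#' Write a robustness report as a CSV correlation matrix
#' @param report an `hpu_robustness` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_robustness <- function(report, path) {
  stopifnot(inherits(report, "hpu_robustness"))
  utils::write.csv(report$r, path, row.names = TRUE)
  invisible(path)
}

#' Stratified audit sample of target articles
#'
#' Draws, independently within each newspaper, a simple random sample
#' without replacement of `ceiling(fraction * n)` of that newspaper's
#' target-article ids.  Reproducible bit-for-bit from the seed; the
#' caller's RNG state is untouched.  Newspapers with no target articles are
#' skipped with a warning.
#'
#' @param target_ids named list, newspaper id -> character vector of target
#'   article ids (see [target_article_ids()]).
#' @param fraction sampling fraction in (0, 1]; default 0.5 (audit half of
#'   the targets per paper).
#' @param seed integer seed.
#' @return an object of class `hpu_audit_sample`: list with
#'   `sampled_ids` (named list per newspaper), `n_sampled`, `n_targets`,
#'   `fraction`, `seed`.
#' @export
sample_for_audit <- function(target_ids, fraction = 0.5, seed) {
  if (missing(seed)) stop_validation("an explicit seed is required for audit sampling")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_validation("fraction must be in (0, 1]")
  }
  if (!is.list(target_ids) || is.null(names(target_ids))) {
    stop_validation("target_ids must be a named list (newspaper -> ids)")
  }
  empty <- names(target_ids)[lengths(target_ids) == 0L]
  if (length(empty)) {
    warning("no target articles for newspaper(s), stratum skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  sampled <- with_private_seed(seed, {
    out <- list()
    for (np in sort(names(target_ids))) {
      ids <- target_ids[[np]]
      if (!length(ids)) next
      size <- ceiling(fraction * length(ids))
      out[[np]] <- sort(sample(ids, size, replace = FALSE))
    }
    out
  })
  sampled <- sampled[intersect(names(target_ids), names(sampled))]
  structure(list(sampled_ids = sampled,
                 n_sampled = vapply(sampled, length, integer(1L)),
                 n_targets = vapply(target_ids[names(sampled)], length, integer(1L)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "hpu_audit_sample")
}

#' @export
print.hpu_audit_sample <- function(x, ...) {
  cat(sprintf("<hpu_audit_sample> %d articles from %d newspapers (fraction %.2f, seed %d)\n",
              sum(x$n_sampled), length(x$sampled_ids), x$fraction, x$seed))
  invisible(x)
}

#' Audit pass rate
#'
#' Fraction of audited articles whose human review confirmed them as
#' genuine health-policy-uncertainty articles, as a percentage to one
#' decimal place alongside the raw fraction.  When two review rounds are
#' supplied, the final label is the second round's where they disagree
#' (disagreements are resolved by discussion in the second pass).
#'
#' @param labels logical (or `"pass"`/`"fail"` character) vector of final
#'   labels, named by article id; or, with `round2` supplied, the
#'   first-round labels.
#' @param round2 optional second-round labels (same ids).
#' @return a list of class `hpu_pass_rate`: `percent` (rounded to 1
#'   decimal), `passes`, `total`, `fraction` (full precision).
#' @examples
#' pass_rate(c(rep(TRUE, 483), rep(FALSE, 527 - 483)))$percent  # 91.7
#' @export
pass_rate <- function(labels, round2 = NULL) {
  as_flag <- function(v) {
    if (is.character(v)) v <- v == "pass"
    if (!is.logical(v) || anyNA(v)) {
      stop_validation("labels must be logical or \"pass\"/\"fail\" with no missing values")
    }
    v
  }
  labels <- as_flag(labels)
  if (!length(labels)) stop_validation("no audit labels supplied")
  if (!is.null(round2)) {
    round2 <- as_flag(round2)
    if (length(round2) != length(labels)) {
      stop_validation("round2 labels must match the first round in length")
    }
    labels <- round2  # second round carries the adjudicated decision
  }
  passes <- sum(labels)
  total <- length(labels)
  structure(list(percent = round(100 * passes / total, 1L),
                 passes = passes, total = total,
                 fraction = passes / total),
            class = "hpu_pass_rate")
}

#' @export
print.hpu_pass_rate <- function(x, ...) {
  cat(sprintf("pass rate %.1f%% (%d/%d)\n", x$percent, x$passes, x$total))
  invisible(x)
}

#' Compare an index against an external monthly series
#'
#' Inner-joins the index with an external two-column (month, value) series
#' on months and reports the Pearson correlation on the overlap along with
#' the aligned pair for plotting.
#'
#' @param index an [hpu_index()].
#' @param external an [hpu_index()], a data.frame with columns `month`
#'   (`"YYYY-MM"` or `"YYYY-M"`) and `value`, or a path to such a CSV.
#' @return list with `cor` (an `hpu_cor`) and `aligned`, a data.frame with
#'   columns `month`, `index`, `external`.
#' @export
compare_external <- function(index, external) {
  stopifnot(inherits(index, "hpu_index"))
  if (is.character(external) && length(external) == 1L) {
    if (!file.exists(external)) stop_io("external series file not found: ", external)
    external <- utils::read.csv(external, stringsAsFactors = FALSE)
  }
  if (inherits(external, "hpu_index")) {
    ext <- index_values(external)
  } else if (is.data.frame(external)) {
    if (!all(c("month", "value") %in% names(external))) {
      stop_validation("external series must have columns month and value")
    }
    ext <- as.numeric(external$value)
    names(ext) <- ym_canon(external$month)
    if (anyDuplicated(names(ext))) stop_validation("external series has duplicate months")
  } else {
    stop_validation("external must be an index, data.frame, or CSV path")
  }
  overlap <- intersect(names(index), names(ext))
  if (!length(overlap)) stop_validation("no overlapping months with external series")
  ct <- pearson(index_values(index), ext)
  aligned <- data.frame(month = sort(overlap),
                        index = as.numeric(index_values(index)[sort(overlap)]),
                        external = as.numeric(ext[sort(overlap)]),
                        stringsAsFactors = FALSE)
  list(cor = ct, aligned = aligned)
}
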