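# Index construction: scaling, standardization, aggregation, normalization,
# composition, and gap splicing.

#' Monthly index series
#'
#' An `hpu_index` is a monthly series: `"YYYY-MM"` keys, nonnegative values,
#' and (after [normalize_index()]) the normalization constant M such that
#' multiplying the pre-normalization series by 100/M gives the stored
#' values, whose mean is 100.
#'
#' @param values numeric vector named by `"YYYY-MM"` month keys.
#' @param normalization_constant the grand mean M of the pre-normalization
#'   series, or `NA` for a pre-normalization series.
#' @param label series label.
#' @param sigma optional named vector of the per-newspaper standard
#'   deviations used in standardization (provenance metadata).
#' @return an object of class `hpu_index`.
#' @export
hpu_index <- function(values, normalization_constant = NA_real_,
                      label = "index", sigma = NULL) {
  if (is.null(names(values))) stop_validation("index values must be named by month")
  months <- ym_canon(names(values))
  if (is.unsorted(months, strictly = TRUE)) {
    stop_validation("index months must be strictly increasing with no duplicates")
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_validation("index values must be finite")
  if (any(values < 0)) stop_validation("index values must be nonnegative")
  names(values) <- months
  structure(values,
            normalization_constant = as.numeric(normalization_constant),
            label = as.character(label),
            sigma = sigma,
            class = "hpu_index")
}

#' @export
print.hpu_index <- function(x, ...) {
  m <- attr(x, "normalization_constant")
  cat(sprintf("<hpu_index> \"%s\": %d months (%s .. %s), mean %.4f%s\n",
              attr(x, "label"), length(x),
              names(x)[1L], names(x)[length(x)],
              mean(as.numeric(x)),
              if (is.finite(m)) sprintf(", M = %.6g", m) else " (not normalized)"))
  invisible(x)
}

#' @export
as.data.frame.hpu_index <- function(x, ...) {
  data.frame(month = names(x), value = as.numeric(x), stringsAsFactors = FALSE)
}

#' @rdname hpu_index
#' @param x an `hpu_index`.
#' @export
index_months <- function(x) {
  stopifnot(inherits(x, "hpu_index"))
  names(x)
}

#' @rdname hpu_index
#' @export
index_values <- function(x) {
  stopifnot(inherits(x, "hpu_index"))
  v <- as.numeric(x)
  names(v) <- names(x)
  v
}

#' @rdname hpu_index
#' @export
norm_constant <- function(x) {
  stopifnot(inherits(x, "hpu_index"))
  attr(x, "normalization_constant")
}

#' Scale target counts by total counts
#'
#' Forms the per-cell scaled frequency X = A/B from the target-article
#' panel A and total-article panel B.  The two panels must agree in shape
#' and missingness, with A <= B cell-wise.  Covered cells with B = 0 cannot
#' form a ratio and become `NA`, with a warning naming them.
#'
#' @param A,B [count_panel()]s of target and total article counts.
#' @return a `ratio_panel`: a numeric matrix of scaled frequencies with the
#'   panel's dimnames.
#' @export
scale_counts <- function(A, B) {
  if (!identical(dim(A), dim(B)) || !identical(dimnames(A), dimnames(B))) {
    stop_validation("A and B panels differ in shape or labels")
  }
  if (!identical(is.na(unclass(A)), is.na(unclass(B)))) {
    stop_validation("A and B panels differ in missingness pattern")
  }
  present <- !is.na(A)
  if (any(A[present] > B[present])) {
    bad <- which(present & unclass(A) > unclass(B), arr.ind = TRUE)[1L, ]
    stop_validation("target count exceeds total count at ",
                    rownames(A)[bad[1L]], " ", colnames(A)[bad[2L]])
  }
  X <- unclass(A) / unclass(B)
  zero_b <- present & unclass(B) == 0
  if (any(zero_b)) {
    cells <- which(zero_b, arr.ind = TRUE)
    warning(sprintf("%d covered cell(s) with zero total articles treated as missing (e.g. %s %s)",
                    nrow(cells), rownames(A)[cells[1L, 1L]], colnames(A)[cells[1L, 2L]]),
            call. = FALSE)
    X[zero_b] <- NA_real_
  }
  structure(X, class = c("ratio_panel", "matrix", "array"))
}

#' Standardize each newspaper's series to unit standard deviation
#'
#' Divides each newspaper's scaled-frequency series by its sample standard
#' deviation (denominator n-1), computed over that newspaper's present
#' months within the panel window.  Each standardized row then has unit
#' sample SD.  A constant series (SD zero) or a series with fewer than two
#' present months is a degenerate-data error naming the newspaper.
#'
#' @param X a `ratio_panel` from [scale_counts()].
#' @return a `ratio_panel` of standardized values with attribute `sigma`,
#'   the named vector of per-newspaper SDs.
#' @export
standardize_panel <- function(X) {
  if (!is.matrix(X)) stop_validation("X must be a matrix")
  n_present <- rowSums(!is.na(X))
  if (any(n_present < 2L)) {
    stop_degenerate("newspaper(s) with fewer than 2 present months: ",
                    paste(rownames(X)[n_present < 2L], collapse = ", "))
  }
  sigma <- apply(X, 1L, stats::sd, na.rm = TRUE)
  if (any(sigma == 0)) {
    stop_degenerate("constant scaled-frequency series (zero SD) for newspaper(s): ",
                    paste(rownames(X)[sigma == 0], collapse = ", "))
  }
  Y <- unclass(X) / sigma
  structure(Y, sigma = sigma, class = c("ratio_panel", "matrix", "array"))
}

#' Average standardized series across newspapers by month
#'
#' For each month, the arithmetic mean of the standardized values over the
#' newspapers present that month (missing cells excluded from numerator and
#' denominator).  A month with no present newspaper is an error.
#'
#' @param Y a standardized `ratio_panel` from [standardize_panel()].
#' @param label label for the resulting series.
#' @return a pre-normalization [hpu_index()].
#' @export
aggregate_panel <- function(Y, label = "index") {
  if (!is.matrix(Y)) stop_validation("Y must be a matrix")
  n_present <- colSums(!is.na(Y))
  if (any(n_present == 0L)) {
    stop_degenerate("month(s) with no present newspaper: ",
                    paste(colnames(Y)[n_present == 0L], collapse = ", "))
  }
  # fixed (row-name sorted) reduction order for run-to-run determinism
  Yo <- Y[order(rownames(Y)), , drop = FALSE]
  Z <- colMeans(Yo, na.rm = TRUE)
  hpu_index(Z, normalization_constant = NA_real_, label = label,
            sigma = attr(Y, "sigma"))
}

#' Normalize a series to mean 100
#'
#' Computes the grand mean M of the series and rescales by 100/M, so the
#' output has mean exactly 100; M is stored on the result.
#'
#' @param Z an [hpu_index()] (pre- or post-normalization).
#' @return a normalized [hpu_index()].
#' @export
normalize_index <- function(Z) {
  stopifnot(inherits(Z, "hpu_index"))
  M <- mean(as.numeric(Z))
  if (M == 0) stop_degenerate("all-zero index: normalization constant M = 0")
  out <- as.numeric(Z) * (100 / M)
  names(out) <- names(Z)
  hpu_index(out, normalization_constant = M, label = attr(Z, "label"),
            sigma = attr(Z, "sigma"))
}

#' Index from count panels
#'
#' Composes scaling, standardization, aggregation and normalization on
#' already-tabulated target/total panels.
#'
#' @inheritParams scale_counts
#' @param label series label.
#' @return a normalized [hpu_index()].
#' @export
index_from_counts <- function(A, B, label = "index") {
  X <- scale_counts(A, B)
  Y <- standardize_panel(X)
  Z <- aggregate_panel(Y, label = label)
  normalize_index(Z)
}

# Restrict a corpus to a newspaper subset and/or month range.
restrict_corpus <- function(corpus, newspapers = NULL, months = NULL) {
  a <- corpus$articles
  roster <- corpus$newspapers
  if (!is.null(newspapers)) {
    newspapers <- as.character(newspapers)
    unknown <- setdiff(newspapers, roster)
    if (length(unknown)) {
      stop_validation("unknown newspaper(s) in subset: ", paste(unknown, collapse = ", "))
    }
    if (!length(newspapers)) stop_validation("newspaper subset is empty")
    a <- a[a$newspaper %in% newspapers, , drop = FALSE]
    roster <- newspapers
  }
  range_out <- corpus$month_range
  if (!is.null(months)) {
    if (length(months) != 2L) stop_validation("months must be a length-2 range")
    range_out <- ym_canon(months)
    keep <- a$month_key %in% ym_seq(range_out[1L], range_out[2L])
    a <- a[keep, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop_validation("restriction leaves an empty corpus")
  hpu_corpus(a[, c("newspaper", "year", "month", "text", "article_id")],
             newspapers = roster, month_range = range_out)
}

#' Build a health policy uncertainty index from a corpus
#'
#' End-to-end composition: screen articles against the lexicon, tabulate
#' monthly target counts A and totals B, scale (X = A/B), standardize each
#' newspaper to unit SD, average across newspapers by month, and normalize
#' the series to mean 100.  Deterministic for a fixed corpus.
#'
#' @param corpus an [hpu_corpus()].
#' @param lexicon an [hpu_lexicon()]; defaults to the builtin Chinese one.
#' @param newspapers optional subset of the roster.
#' @param months optional length-2 `"YYYY-MM"` range.
#' @param declared_gaps coverage-gap declarations, see [expand_gaps()].
#' @param label series label.
#' @return a normalized [hpu_index()] with per-newspaper `sigma` attached.
#' @examples
#' spec <- synthetic_spec(newspapers = c("p1", "p2", "p3"),
#'                        months = c("2020-01", "2020-12"), seed = 1)
#' sim <- generate_corpus(spec)
#' idx <- build_index(sim$corpus)
#' round(mean(index_values(idx)), 6)
#' @export
build_index <- function(corpus, lexicon = load_lexicon(), newspapers = NULL,
                        months = NULL, declared_gaps = NULL, label = "HPU") {
  stopifnot(inherits(corpus, "hpu_corpus"))
  corpus <- restrict_corpus(corpus, newspapers, months)
  gaps <- expand_gaps(declared_gaps, corpus$newspapers)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(errorCondition(paste0("stage ", name, ": ", conditionMessage(e)),
                            class = class(e)))
      }),
      warning = function(w) {
        warning(paste0("stage ", name, ": ", conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      })
  }
  A <- stage("count_matches", count_matches(corpus, lexicon, gaps))
  B <- stage("monthly_totals", monthly_totals(corpus, gaps))
  # months gapped for every newspaper carry no declared data at all and are
  # excluded from the window (the excluded-year pathway); months that are
  # merely partially gapped stay and average over the present newspapers
  keep <- colSums(!is.na(unclass(B))) > 0L
  if (!all(keep)) {
    A <- count_panel(unclass(A)[, keep, drop = FALSE])
    B <- count_panel(unclass(B)[, keep, drop = FALSE])
  }
  X <- stage("scale_counts", scale_counts(A, B))
  Y <- stage("standardize", standardize_panel(X))
  Z <- stage("aggregate", aggregate_panel(Y, label = label))
  stage("normalize", normalize_index(Z))
}

#' Splice a gapped index with a donor index
#'
#' Fills declared gap months of one index from a donor index built from
#' fully covered newspapers: non-gap months come from the gapped series and
#' gap months from the donor (unrescaled), after which the union is
#' re-normalized to mean 100.  The pre-splice Pearson correlation between
#' the two series on their overlapping non-gap months is reported so the
#' no-systematic-bias judgment can be applied.
#'
#' @param gapped [hpu_index()] covering the non-gap months.
#' @param donor [hpu_index()] covering (at least) the gap months.
#' @param gap_months character vector of `"YYYY-MM"` keys to take from the
#'   donor; may be empty, in which case the result is the re-normalized
#'   gapped series.
#' @param label label for the spliced series.
#' @return a list with `index` (the spliced, re-normalized [hpu_index()])
#'   and `overlap_cor`, the pre-splice [pearson()] result on the overlap
#'   (`NULL` when `gap_months` is empty and no validation is needed).
#' @export
splice_indexes <- function(gapped, donor, gap_months, label = "HPUfinal") {
  stopifnot(inherits(gapped, "hpu_index"), inherits(donor, "hpu_index"))
  gap_months <- if (length(gap_months)) ym_canon(gap_months) else character(0L)
  miss <- setdiff(gap_months, names(donor))
  if (length(miss)) {
    stop_validation("donor index does not cover gap month(s): ",
                    paste(utils::head(miss, 3L), collapse = ", "))
  }
  overlap <- setdiff(intersect(names(gapped), names(donor)), gap_months)
  if (!length(overlap)) {
    stop_validation("cannot validate splice: no overlapping non-gap months")
  }
  overlap_cor <- if (length(overlap) >= 3L) {
    pearson(gapped, donor, months = overlap)
  } else NULL
  keep <- setdiff(names(gapped), gap_months)
  vals <- c(index_values(gapped)[keep], index_values(donor)[gap_months])
  vals <- vals[order(names(vals))]
  spliced <- normalize_index(hpu_index(vals, label = label))
  list(index = spliced, overlap_cor = overlap_cor)
}

#' Write an index series to CSV with a JSON sidecar
#'
#' The CSV has columns `month` and `value` (6 decimal places); the sidecar
#' `<path>.meta.json` records the label, the normalization constant M, and
#' the per-newspaper standardization SDs when available.
#'
#' @param index an [hpu_index()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "hpu_index"))
  df <- as.data.frame(index)
  df$value <- sprintf("%.6f", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(label = attr(index, "label"),
               normalization_constant = attr(index, "normalization_constant"),
               n_months = length(index))
  if (!is.null(attr(index, "sigma"))) meta$sigma <- as.list(attr(index, "sigma"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an index series written by [write_index()]
#'
#' @param path CSV path with columns `month`, `value`.
#' @param label optional label override.
#' @return an [hpu_index()].
#' @export
read_index <- function(path, label = NULL) {
  if (!file.exists(path)) stop_io("index file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("month", "value") %in% names(df))) {
    stop_validation("index CSV must have columns month and value")
  }
  o <- order(ym_canon(df$month))
  v <- as.numeric(df$value[o])
  names(v) <- ym_canon(df$month[o])
  meta_path <- paste0(path, ".meta.json")
  M <- NA_real_
  if (is.null(label)) label <- basename(path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    if (!is.null(meta$normalization_constant)) M <- as.numeric(meta$normalization_constant)
    if (!is.null(meta$label)) label <- meta$label
  }
  hpu_index(v, normalization_constant = M, label = label)
}
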