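# Independent oracles and fixture builders.  These re-derive expected
# results by deliberately naive means (explicit loops, naive substring
# scans) and never call the package's pipeline internals.

# Straight-line re-implementation of the five index-construction steps on
# plain A/B matrices (NA = missing cell).  Loops only.
oracle_index <- function(A, B) {
  stopifnot(identical(dim(A), dim(B)))
  n <- nrow(A); m <- ncol(A)
  X <- matrix(NA_real_, n, m, dimnames = dimnames(A))
  for (i in seq_len(n)) for (t in seq_len(m)) {
    if (!is.na(A[i, t]) && !is.na(B[i, t]) && B[i, t] > 0) {
      X[i, t] <- A[i, t] / B[i, t]
    }
  }
  Y <- matrix(NA_real_, n, m, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    v <- X[i, !is.na(X[i, ])]
    mu <- sum(v) / length(v)
    s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    if (s == 0) stop("oracle: constant series")
    for (t in seq_len(m)) Y[i, t] <- X[i, t] / s
  }
  Z <- numeric(m)
  for (t in seq_len(m)) {
    v <- Y[!is.na(Y[, t]), t]
    if (!length(v)) stop("oracle: empty month")
    Z[t] <- sum(v) / length(v)
  }
  M <- sum(Z) / m
  out <- 100 * Z / M
  names(out) <- colnames(A)
  out
}

# Naive substring containment: scan every alignment by hand.
naive_contains <- function(text, term) {
  nt <- nchar(term); nx <- nchar(text)
  if (nt > nx) return(FALSE)
  for (k in seq_len(nx - nt + 1L)) {
    if (substr(text, k, k + nt - 1L) == term) return(TRUE)
  }
  FALSE
}

# Triple nested loop over categories and terms.
brute_matches <- function(text, lexicon) {
  for (cat in c("health", "policy", "uncertainty")) {
    hit <- FALSE
    for (term in lexicon[[cat]]) {
      if (naive_contains(text, term)) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# Build a corpus realizing given A (target) / B (total) count matrices:
# matching articles carry one term per category, the rest are filler.
# NA cells correspond to declared gaps, returned alongside.
corpus_from_counts <- function(A, B, lexicon = load_lexicon()) {
  papers <- rownames(A); months <- colnames(A)
  rows <- list()
  gaps <- list()
  triple <- paste0(lexicon$health[1], lexicon$policy[1], lexicon$uncertainty[1])
  for (i in seq_along(papers)) for (t in seq_along(months)) {
    if (is.na(B[i, t])) {
      gaps[[papers[i]]] <- c(gaps[[papers[i]]], months[t])
      next
    }
    n_match <- A[i, t]; n_fill <- B[i, t] - A[i, t]
    if (B[i, t] == 0) next
    p <- ym_parse(months[t])
    rows[[length(rows) + 1L]] <- data.frame(
      newspaper = papers[i], year = p$year, month = p$month,
      text = c(rep(triple, n_match), rep("zzfillzz", n_fill)),
      stringsAsFactors = FALSE)
  }
  corpus <- hpu_corpus(do.call(rbind, rows), newspapers = papers,
                       month_range = c(months[1L], months[length(months)]))
  list(corpus = corpus, gaps = gaps)
}

# Random A/B panels (<= 4 newspapers x 12 months), occasionally with gap
# cells, always valid for standardization (non-constant rows, >= 2 present
# months per row, >= 1 present newspaper per month, B >= 1).
random_panel <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(2:4, 1L); m <- sample(4:12, 1L)
    papers <- paste0("paper", seq_len(n))
    months <- ym_seq("2010-01", "2010-12")[seq_len(m)]
    B <- matrix(sample(5:60, n * m, replace = TRUE), n, m,
                dimnames = list(papers, months))
    A <- matrix(0, n, m, dimnames = list(papers, months))
    for (i in seq_len(n)) for (t in seq_len(m)) {
      A[i, t] <- sample(0:min(6, B[i, t]), 1L)
    }
    if (runif(1) < 0.4) {                      # plant a few gap cells
      k <- sample(seq_len(n * m), sample(1:3, 1L))
      A[k] <- NA; B[k] <- NA
    }
    ok_rows <- all(rowSums(!is.na(B)) >= 2L) &&
      all(apply(A / B, 1L, function(v) stats::sd(v, na.rm = TRUE) > 0))
    ok_cols <- all(colSums(!is.na(B)) >= 1L)
    if (ok_rows && ok_cols) return(list(A = A, B = B))
  }
}

# Random small latin-alphabet corpus for round-trip properties.
random_corpus <- function(seed, n = 30L) {
  set.seed(seed)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  papers <- paste0("np", 1:3)
  data.frame(
    newspaper = sample(papers, n, replace = TRUE),
    year = sample(2010:2012, n, replace = TRUE),
    month = sample(1:12, n, replace = TRUE),
    text = vapply(seq_len(n), function(k) {
      paste(sample(words, sample(3:8, 1L), replace = TRUE), collapse = " ")
    }, character(1L)),
    stringsAsFactors = FALSE)
}

# Remove all articles of given newspapers in given months (simulating a
# coverage gap in the raw data), keeping the original window.
drop_cells <- function(corpus, newspapers, months) {
  a <- corpus$articles
  keep <- !(a$newspaper %in% newspapers & a$month_key %in% months)
  hpu_corpus(a[keep, c("newspaper", "year", "month", "text", "article_id")],
             newspapers = corpus$newspapers, month_range = corpus$month_range)
}
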