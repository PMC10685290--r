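make_panel <- function(m) count_panel(m)

test_that("scaling divides target by total counts and flags impossible cells", {
  months <- c("2020-01", "2020-02")
  A <- make_panel(matrix(c(0, 2), 1, 2, dimnames = list("p", months)))
  B <- make_panel(matrix(c(100, 100), 1, 2, dimnames = list("p", months)))
  X <- scale_counts(A, B)
  expect_equal(as.numeric(X), c(0, 0.02))

  Abad <- make_panel(matrix(c(1, 2), 1, 2, dimnames = list("p", months)))
  Bbad <- make_panel(matrix(c(0, 100), 1, 2, dimnames = list("p", months)))
  expect_error(scale_counts(Abad, Bbad), class = "hpu_validation_error")

  # a covered zero-total month cannot form a ratio and becomes missing
  A0 <- make_panel(matrix(c(0, 2), 1, 2, dimnames = list("p", months)))
  expect_warning(X0 <- scale_counts(A0, Bbad), "zero total")
  expect_true(is.na(X0[1, 1]))

  # mismatched missingness is rejected
  Ana <- make_panel(matrix(c(NA, 2), 1, 2, dimnames = list("p", months)))
  expect_error(scale_counts(Ana, B), class = "hpu_validation_error")
})

test_that("standardization divides by the sample SD and records sigma", {
  months <- c("2020-01", "2020-02")
  X <- structure(matrix(c(1, 3), 1, 2, dimnames = list("p", months)),
                 class = c("ratio_panel", "matrix", "array"))
  Y <- standardize_panel(X)
  expect_equal(attr(Y, "sigma"), c(p = sqrt(2)))
  expect_equal(as.numeric(Y), c(1 / sqrt(2), 3 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(as.numeric(Y), 5), c(0.70711, 2.12132))
  expect_equal(apply(Y, 1, sd), c(p = 1))      # unit sample SD by construction

  # already unit-SD input is a fixed point (sigma recomputes to 1)
  Yu <- standardize_panel(Y)
  expect_equal(as.numeric(Yu), as.numeric(Y), tolerance = 1e-12)
  expect_equal(attr(Yu, "sigma"), c(p = 1))

  Xc <- structure(matrix(c(0.5, 0.5), 1, 2, dimnames = list("p", months)),
                  class = c("ratio_panel", "matrix", "array"))
  expect_error(standardize_panel(Xc), "constant", class = "hpu_degenerate_error")
  X1 <- structure(matrix(0.5, 1, 1, dimnames = list("p", "2020-01")),
                  class = c("ratio_panel", "matrix", "array"))
  expect_error(standardize_panel(X1), class = "hpu_degenerate_error")
})

test_that("aggregation averages present newspapers per month", {
  months <- c("2020-01", "2020-02", "2020-03")
  Y <- matrix(c(1, 3, 2, 2, 5, NA), 2, 3, byrow = FALSE,
              dimnames = list(c("p", "q"), months))
  Z <- aggregate_panel(Y)
  expect_equal(as.numeric(Z), c(mean(c(1, 3)), mean(c(2, 2)), 5))
  # brute-force mean over present cells
  for (t in seq_along(months)) {
    v <- Y[, t][!is.na(Y[, t])]
    expect_equal(as.numeric(Z)[t], sum(v) / length(v))
  }
  Yempty <- matrix(c(1, NA), 1, 2, dimnames = list("p", months[1:2]))
  expect_error(aggregate_panel(Yempty), class = "hpu_degenerate_error")
  # single newspaper: the index is its own row
  Z1 <- aggregate_panel(Y[1, , drop = FALSE])
  expect_equal(as.numeric(Z1), as.numeric(Y[1, ]))
})

test_that("normalization forces mean 100 and is idempotent", {
  Z <- hpu_index(c("2020-01" = 1, "2020-02" = 3))
  N <- normalize_index(Z)
  expect_equal(as.numeric(N), c(50, 150))
  expect_equal(norm_constant(N), 2)
  expect_equal(as.numeric(normalize_index(N)), as.numeric(N))
  for (seed in 1:20) {
    set.seed(seed)
    v <- runif(sample(3:20, 1), 0, 10)
    names(v) <- ym_seq("2000-01", "2005-12")[seq_along(v)]
    out <- normalize_index(hpu_index(v))
    expect_equal(mean(as.numeric(out)), 100, tolerance = 1e-9)
  }
  expect_error(normalize_index(hpu_index(c("2020-01" = 0, "2020-02" = 0))),
               class = "hpu_degenerate_error")
})

test_that("end-to-end build matches the straight-line oracle on a toy panel", {
  months <- c("2020-01", "2020-02", "2020-03")
  A <- matrix(c(1, 2, 3, 0, 2, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("p", "q"), months))
  B <- matrix(10, 2, 3, dimnames = list(c("p", "q"), months))
  want <- oracle_index(A, B)
  got <- index_from_counts(count_panel(A), count_panel(B))
  expect_equal(index_values(got), want, tolerance = 1e-12)
  # and through the corpus path
  fix <- corpus_from_counts(A, B)
  idx <- build_index(fix$corpus)
  expect_equal(index_values(idx), want, tolerance = 1e-12)
})

test_that("index is invariant to duplication, permutation and per-paper scaling", {
  panel <- random_panel(123)
  base <- index_values(index_from_counts(count_panel(panel$A), count_panel(panel$B)))

  # doubling one newspaper's A and B leaves X unchanged
  A2 <- panel$A; B2 <- panel$B
  A2[1, ] <- A2[1, ] * 3; B2[1, ] <- B2[1, ] * 3
  expect_equal(index_values(index_from_counts(count_panel(A2), count_panel(B2))),
               base, tolerance = 1e-12)

  # scaling one newspaper's A alone is absorbed by sigma
  A3 <- panel$A * 0; A3[] <- panel$A
  A3[2, ] <- A3[2, ] * 0.5
  expect_equal(index_values(index_from_counts(count_panel(A3), count_panel(panel$B))),
               base, tolerance = 1e-12)

  # permuting newspaper order changes nothing
  perm <- rev(seq_len(nrow(panel$A)))
  expect_equal(index_values(index_from_counts(count_panel(panel$A[perm, ]),
                                              count_panel(panel$B[perm, ]))),
               base, tolerance = 1e-12)

  # duplicating every article doubles A and B and leaves the index unchanged
  fix <- corpus_from_counts(panel$A, panel$B)
  a <- fix$corpus$articles
  dup <- rbind(a, a)[, c("newspaper", "year", "month", "text")]
  co2 <- hpu_corpus(dup, newspapers = fix$corpus$newspapers,
                    month_range = fix$corpus$month_range)
  expect_equal(index_values(build_index(co2, declared_gaps = fix$gaps)),
               index_values(build_index(fix$corpus, declared_gaps = fix$gaps)),
               tolerance = 1e-12)
})

test_that("restricting to a subset equals deleting the complement's articles", {
  spec <- synthetic_spec(newspapers = c("a", "b", "c", "d"),
                         months = c("2020-01", "2020-12"), lambda = 40, seed = 31)
  sim <- generate_corpus(spec)
  sub <- build_index(sim$corpus, newspapers = c("a", "c"))
  a <- sim$corpus$articles
  pruned <- hpu_corpus(a[a$newspaper %in% c("a", "c"),
                         c("newspaper", "year", "month", "text")],
                       newspapers = c("a", "c"),
                       month_range = sim$corpus$month_range)
  expect_equal(index_values(sub), index_values(build_index(pruned)),
               tolerance = 1e-12)
  expect_error(build_index(sim$corpus, newspapers = "nope"),
               "unknown newspaper", class = "hpu_validation_error")
})

test_that("splicing fills gap months from the donor and re-normalizes", {
  months <- ym_seq("2020-01", "2020-12")
  set.seed(5)
  v <- runif(12, 50, 150); names(v) <- months
  full <- normalize_index(hpu_index(v))
  gap <- c("2020-05", "2020-06")
  gapped <- normalize_index(hpu_index(index_values(full)[setdiff(months, gap)]))

  out <- splice_indexes(gapped, full, gap)
  expect_equal(index_months(out$index), months)
  expect_equal(mean(index_values(out$index)), 100, tolerance = 1e-9)
  expect_equal(out$overlap_cor$r, 1, tolerance = 1e-9)

  # empty gap set: re-normalized gapped series unchanged
  noop <- splice_indexes(gapped, full, character(0))
  expect_equal(index_values(noop$index), index_values(gapped), tolerance = 1e-9)

  # donor must cover the gap
  expect_error(splice_indexes(gapped, gapped, gap), class = "hpu_validation_error")
})

test_that("index CSV round-trips with its metadata sidecar", {
  idx <- normalize_index(hpu_index(c("2020-01" = 1, "2020-02" = 3), label = "toy"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_index(idx, path)
  back <- read_index(path)
  expect_equal(index_values(back), index_values(idx), tolerance = 1e-6)
  expect_equal(attr(back, "label"), "toy")
  expect_equal(norm_constant(back), norm_constant(idx))
})
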