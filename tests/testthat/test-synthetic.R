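test_that("spec validation enforces probability and vocabulary invariants", {
  expect_error(synthetic_spec(p0 = 1.2, seed = 1), class = "hpu_validation_error")
  expect_error(synthetic_spec(decoy_rate = 1, seed = 1), class = "hpu_validation_error")
  expect_error(synthetic_spec(seed = 1, events = c("1999-01" = 2)),
               class = "hpu_validation_error")
  expect_error(synthetic_spec(), class = "hpu_validation_error")  # seed required
  # filler containing a lexicon term is rejected
  expect_error(
    synthetic_spec(seed = 1, filler_vocab = c("ok", "某卫生词")),
    "filler", class = "hpu_validation_error")
  # rate bound >= 1 warns about clamping
  expect_warning(
    synthetic_spec(seed = 1, p0 = 0.5, events = c("2020-02" = 8),
                   shared_signal_sd = 0.5, idiosyncratic_sd = 0.5),
    "clamp")
})

test_that("extreme relevance rates produce the degenerate corpora they should", {
  base <- list(newspapers = c("a", "b"), months = c("2020-01", "2020-06"),
               lambda = 25, shared_signal_sd = 0, idiosyncratic_sd = 0)
  s0 <- do.call(synthetic_spec, c(base, list(p0 = 0, decoy_rate = 0, seed = 4,
                                             events = c())))
  sim0 <- generate_corpus(s0)
  expect_true(all(sim0$truth$cells$relevant == 0))
  expect_true(all(count_matches(sim0$corpus, s0$lexicon) == 0))

  s1 <- do.call(synthetic_spec, c(base, list(p0 = 1, decoy_rate = 0, seed = 4,
                                             events = c())))
  sim1 <- generate_corpus(s1)
  tp <- truth_panels(sim1$truth, s1)
  expect_equal(unclass(count_matches(sim1$corpus, s1$lexicon)), unclass(tp$A))
  expect_equal(unclass(tp$A), unclass(tp$B))   # every article is a target
})

test_that("generation is reproducible and hierarchical in the roster", {
  spec <- synthetic_spec(newspapers = c("a", "b"), months = c("2020-01", "2020-06"),
                         lambda = 30, seed = 99)
  s1 <- generate_corpus(spec)
  s2 <- generate_corpus(spec)
  expect_identical(s1$corpus$articles, s2$corpus$articles)
  expect_identical(s1$truth, s2$truth)
  # adding a newspaper does not perturb the existing newspapers' draws
  spec3 <- synthetic_spec(newspapers = c("a", "b", "c"),
                          months = c("2020-01", "2020-06"),
                          lambda = 30, seed = 99)
  s3 <- generate_corpus(spec3)
  keep <- s3$truth$cells$newspaper %in% c("a", "b")
  expect_identical(s3$truth$cells[keep, ], s1$truth$cells)
})

test_that("declared coverage gaps produce no articles and NA truth panels", {
  spec <- synthetic_spec(newspapers = c("a", "b"), months = c("2020-01", "2020-12"),
                         lambda = 20, seed = 6, gaps = list(b = c("2020-03", "2020-04")))
  sim <- generate_corpus(spec)
  expect_false(any(sim$corpus$articles$newspaper == "b" &
                     sim$corpus$articles$month_key %in% c("2020-03", "2020-04")))
  tp <- truth_panels(sim$truth, spec)
  expect_true(all(is.na(tp$B["b", c("2020-03", "2020-04")])))
  expect_false(anyNA(tp$B["a", ]))
})

test_that("empirical relevance rate concentrates on p0", {
  # lambda = 200, p0 = 0.05, no extra noise: mean of A/B across cells within
  # 3 Monte-Carlo standard errors of p0
  spec <- synthetic_spec(newspapers = "solo", months = c("2003-01", "2012-12"),
                         lambda = 200, p0 = 0.05, events = c(),
                         shared_signal_sd = 0, idiosyncratic_sd = 0,
                         decoy_rate = 0, seed = 8)
  sim <- generate_corpus(spec)
  x <- sim$truth$cells$relevant / sim$truth$cells$total
  se <- sqrt(0.05 * 0.95 / 200) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.05), 3 * se)
})

test_that("expected index peaks at the event month and rejects flat paths", {
  spec <- synthetic_spec(newspapers = c("a", "b"), months = c("2020-01", "2020-12"),
                         events = c("2020-07" = 5), seed = 1)
  ei <- expected_index(spec)
  expect_equal(names(which.max(index_values(ei))), "2020-07")
  expect_equal(mean(index_values(ei)), 100, tolerance = 1e-9)

  flat <- synthetic_spec(newspapers = c("a", "b"), months = c("2020-01", "2020-12"),
                         events = c(), seed = 1)
  expect_error(expected_index(flat), class = "hpu_degenerate_error")

  # 3-month toy path, hand-computed: path p0 * m = (.03, .06, .03),
  # sd = sqrt(3)*.01, Y = path/sd, index = 100 * Y / mean(Y)
  toy <- synthetic_spec(newspapers = "a", months = c("2020-01", "2020-03"),
                        events = c("2020-02" = 2), seed = 1)
  path <- c(0.03, 0.06, 0.03)
  want <- 100 * (path / sd(path)) / mean(path / sd(path))
  expect_equal(unname(index_values(expected_index(toy))), want, tolerance = 1e-12)

  # realized latent path variant follows the bookkept intensity
  sim <- generate_corpus(spec)
  er <- expected_index(spec, latent = sim$truth$latent)
  want_r <- sim$truth$latent$intensity
  want_r <- 100 * (want_r / sd(want_r)) / mean(want_r / sd(want_r))
  expect_equal(unname(index_values(er)), want_r, tolerance = 1e-12)
})

test_that("decoys are invisible to screening but carry two categories", {
  spec <- synthetic_spec(newspapers = "a", months = c("2020-01", "2020-03"),
                         events = c("2020-02" = 2),
                         lambda = 60, p0 = 0.1, decoy_rate = 0.5, seed = 13)
  sim <- generate_corpus(spec)
  lex <- spec$lexicon
  a <- sim$corpus$articles
  n_two_cat <- sum(vapply(a$text, function(tx) {
    hits <- article_matches(tx, lex)$hits
    sum(lengths(hits) > 0L) == 2L
  }, logical(1)))
  expect_equal(n_two_cat, sum(sim$truth$cells$decoys))
  expect_equal(unclass(count_matches(sim$corpus, lex)),
               unclass(truth_panels(sim$truth, spec)$A))
})
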