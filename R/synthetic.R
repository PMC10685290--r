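# Synthetic newspaper-corpus generator with ground-truth bookkeeping.
#
# Measurement model: for newspaper i in month t, the total article count is
# Poisson(lambda_i); each article is a genuine health-policy-uncertainty
# article with probability p_t = p0 * m_t * exp(eps_shared_t + eps_it),
# where m_t is an event multiplier, eps_shared_t ~ N(0, shared_signal_sd)
# is common to all newspapers (the signal the robustness tests presuppose)
# and eps_it ~ N(0, idiosyncratic_sd) is a house effect.  Relevant articles
# carry at least one term from each lexicon category embedded in filler
# text; a decoy fraction of non-relevant articles carries terms from
# exactly two categories; the rest are pure filler.

#' Default filler vocabulary for synthetic article texts
#'
#' Latin pseudo-words guaranteed not to contain any builtin lexicon term;
#' used as the non-keyword content of generated articles.
#'
#' @return character vector of filler tokens.
#' @export
default_filler_vocab <- function() {
  c("lorem", "ipsum", "dolor", "amet", "tempor", "incidunt", "labore",
    "magna", "aliqua", "veniam", "nostrud", "ullamco", "laboris", "nisi",
    "aliquip", "commodo", "consequat", "duis", "aute", "irure", "reprehenderit",
    "voluptate", "velit", "cillum", "fugiat", "nulla", "pariatur", "excepteur",
    "sint", "occaecat", "cupidatat", "proident", "culpa", "officia", "mollit",
    "anim", "laborum", "perspiciatis", "accusantium", "doloremque")
}

#' Specification of a synthetic newspaper corpus
#'
#' Parameterizes the generator: per-newspaper monthly volumes, the study
#' window, the baseline probability that an article is a genuine
#' health-policy-uncertainty article, month-specific event multipliers
#' (shocks), decoy and noise settings, declared coverage gaps, and the
#' lexicon whose terms get planted.
#'
#' @param newspapers character vector of newspaper ids.
#' @param months length-2 `"YYYY-MM"` range of the simulated window.
#' @param lambda expected articles per newspaper per month (scalar, or
#'   vector named by newspaper).
#' @param p0 baseline relevance probability in `[0, 1]`.
#' @param events named numeric vector, month key -> multiplier `m >= 0`
#'   applied to `p0` in that month (months absent default to 1).
#' @param decoy_rate fraction of non-relevant articles that carry terms
#'   from exactly two categories, in `[0, 1)`.
#' @param shared_signal_sd,idiosyncratic_sd standard deviations of the
#'   log-normal monthly perturbations shared across newspapers
#'   vs. newspaper-specific.
#' @param gaps declared coverage gaps (named list newspaper -> months or
#'   `"YYYY"` years); gapped cells produce no articles.
#' @param seed integer master seed; all randomness derives from it
#'   hierarchically (newspaper -> month -> article), so adding a newspaper
#'   does not perturb the other newspapers' draws.
#' @param lexicon an [hpu_lexicon()] whose terms are planted.
#' @param filler_vocab non-keyword filler tokens; no filler string may
#'   contain a lexicon term as a substring (validated).
#' @return an object of class `synthetic_spec`.
#' @details If `p0 * max(multiplier) * exp(3 * (shared_signal_sd +
#'   idiosyncratic_sd))` reaches 1 the per-cell relevance probability may
#'   clamp at 1; the constructor warns and the generator clamps.
#' @export
synthetic_spec <- function(newspapers = default_newspapers(),
                           months = c("2018-01", "2022-12"),
                           lambda = 100,
                           p0 = 0.03,
                           events = c("2020-02" = 8),
                           decoy_rate = 0.2,
                           shared_signal_sd = 0.3,
                           idiosyncratic_sd = 0.1,
                           gaps = list(),
                           seed,
                           lexicon = load_lexicon(),
                           filler_vocab = default_filler_vocab()) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  newspapers <- as.character(newspapers)
  if (!length(newspapers) || anyDuplicated(newspapers)) {
    stop_validation("newspapers must be a non-empty set of distinct ids")
  }
  if (length(lambda) == 1L) {
    lambda <- stats::setNames(rep(as.numeric(lambda), length(newspapers)), newspapers)
  } else {
    if (is.null(names(lambda)) || !setequal(names(lambda), newspapers)) {
      stop_validation("vector lambda must be named by the newspapers")
    }
    lambda <- lambda[newspapers]
  }
  if (any(lambda <= 0)) stop_validation("lambda must be positive")
  month_keys <- ym_seq(ym_canon(months[1L]), ym_canon(months[2L]))
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop_validation("p0 must be in [0, 1]")
  if (length(events)) {
    events <- unlist(events)          # tolerate YAML/JSON maps
    storage.mode(events) <- "double"
    if (is.null(names(events))) stop_validation("events must be named by month")
    names(events) <- ym_canon(names(events))
    if (any(events < 0)) stop_validation("event multipliers must be nonnegative")
    off <- setdiff(names(events), month_keys)
    if (length(off)) {
      stop_validation("event month(s) outside window: ", paste(off, collapse = ", "))
    }
  }
  if (decoy_rate < 0 || decoy_rate >= 1) stop_validation("decoy_rate must be in [0, 1)")
  if (shared_signal_sd < 0 || idiosyncratic_sd < 0) {
    stop_validation("noise SDs must be nonnegative")
  }
  stopifnot(inherits(lexicon, "hpu_lexicon"))
  filler_vocab <- as.character(filler_vocab)
  if (!length(filler_vocab)) stop_validation("filler_vocab must be non-empty")
  all_terms <- unlist(lexicon[c("health", "policy", "uncertainty")], use.names = FALSE)
  filler_nfkc <- stringi::stri_trans_nfkc(enc2utf8(filler_vocab))
  contaminated <- vapply(filler_nfkc, function(f) {
    any(stringi::stri_detect_fixed(f, all_terms))
  }, logical(1L))
  if (any(contaminated)) {
    stop_validation("filler token(s) contain lexicon terms: ",
                    paste(filler_vocab[contaminated], collapse = ", "))
  }
  gaps <- expand_gaps(gaps, newspapers)
  bound <- p0 * max(1, if (length(events)) max(events) else 1) *
    exp(3 * (shared_signal_sd + idiosyncratic_sd))
  if (bound >= 1 && p0 < 1) {
    warning(sprintf("relevance-rate bound %.3g >= 1: per-cell probabilities may clamp at 1",
                    bound), call. = FALSE)
  }
  structure(list(newspapers = newspapers, months = month_keys, lambda = lambda,
                 p0 = p0, events = events, decoy_rate = decoy_rate,
                 shared_signal_sd = shared_signal_sd,
                 idiosyncratic_sd = idiosyncratic_sd,
                 gaps = gaps, seed = as.integer(seed), lexicon = lexicon,
                 filler_vocab = filler_vocab),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d newspapers x %d months, p0 = %g, %d event(s), seed %d\n",
              length(x$newspapers), length(x$months), x$p0,
              length(x$events), x$seed))
  invisible(x)
}

# Event multiplier per month (1 where no event declared).
event_multipliers <- function(spec) {
  m <- stats::setNames(rep(1, length(spec$months)), spec$months)
  if (length(spec$events)) m[names(spec$events)] <- spec$events
  m
}

# Compose n article texts from planted term lists + filler, tokens in random
# order, terms allowed to abut.  plants: list of n character vectors.
compose_texts <- function(n, plants, filler_vocab) {
  if (n == 0L) return(character(0L))
  k_fill <- sample(3:8, n, replace = TRUE)
  fillers <- sample(filler_vocab, sum(k_fill), replace = TRUE)
  tok <- c(fillers, unlist(plants, use.names = FALSE))
  art <- c(rep(seq_len(n), k_fill), rep(seq_len(n), lengths(plants)))
  o <- order(art, stats::runif(length(art)))
  grp <- factor(art[o], levels = seq_len(n))
  unname(vapply(split(tok[o], grp), paste, character(1L), collapse = ""))
}

# Deterministic rebuild of texts with a filler separator between all tokens,
# used only when abutting tokens accidentally complete a screening triple.
compose_safe <- function(plants, filler_vocab) {
  sep <- filler_vocab[1L]
  vapply(plants, function(p) paste(c(sep, p, sep), collapse = sep), character(1L))
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws a full corpus from a [synthetic_spec()]: per-cell Poisson totals,
#' Bernoulli relevance with the log-normal shared/idiosyncratic monthly
#' perturbations, planted keyword triples in relevant articles, two-category
#' decoys, and pure-filler articles.  Every planted count is bookkept, so
#' screening results can be verified exactly.  Fully reproducible from the
#' spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `corpus` (an [hpu_corpus()]) and `truth`, a list with
#'   `cells` (data.frame: newspaper, month, total, relevant, decoys) and
#'   `latent` (data.frame: month, multiplier, eps_shared, intensity
#'   `p0 * m_t * exp(eps_shared_t)`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lex <- spec$lexicon
  cats <- c("health", "policy", "uncertainty")
  mult <- event_multipliers(spec)

  # month-level shared perturbations, seeded independently of the roster
  eps_shared <- vapply(spec$months, function(mo) {
    with_private_seed(derive_seed(spec$seed, "shared", mo),
                      stats::rnorm(1L, 0, spec$shared_signal_sd))
  }, numeric(1L))

  clamped <- 0L
  cell_rows <- list()
  art_chunks <- list()
  chunk <- 0L
  for (np in spec$newspapers) {
    gap_mo <- spec$gaps[[np]]
    for (mo in spec$months) {
      if (!is.null(gap_mo) && mo %in% gap_mo) next
      cell <- with_private_seed(derive_seed(spec$seed, "cell", np, mo), {
        total <- stats::rpois(1L, spec$lambda[[np]])
        eps_i <- stats::rnorm(1L, 0, spec$idiosyncratic_sd)
        p <- spec$p0 * mult[[mo]] * exp(eps_shared[[mo]] + eps_i)
        if (p > 1) { clamped <- clamped + 1L; p <- 1 }
        relevant <- if (total > 0L) stats::rbinom(1L, total, p) else 0L
        decoys <- if (total - relevant > 0L) {
          stats::rbinom(1L, total - relevant, spec$decoy_rate)
        } else 0L

        plants <- vector("list", total)
        if (relevant > 0L) {
          for (j in seq_len(relevant)) {
            plants[[j]] <- vapply(cats, function(cc) sample(lex[[cc]], 1L),
                                  character(1L))
          }
        }
        if (decoys > 0L) {
          for (j in seq_len(decoys)) {
            two <- sample(cats, 2L)
            plants[[relevant + j]] <- vapply(two, function(cc) sample(lex[[cc]], 1L),
                                            character(1L))
          }
        }
        if (total > relevant + decoys) {
          for (j in seq((relevant + decoys + 1L), total)) plants[[j]] <- character(0L)
        }
        texts <- compose_texts(total, plants, spec$filler_vocab)

        # guard the exact-ground-truth invariant: no non-relevant text may
        # satisfy the full triple through accidental cross-token formation
        if (total > relevant) {
          non_rel <- seq((relevant + 1L), total)
          bad <- non_rel[screen_texts(texts[non_rel], lex)]
          if (length(bad)) {
            texts[bad] <- compose_safe(plants[bad], spec$filler_vocab)
            still <- bad[screen_texts(texts[bad], lex)]
            if (length(still)) {
              stop_validation("cannot compose decoy/filler text without completing ",
                              "the screening triple; choose a different filler_vocab")
            }
          }
        }
        if (relevant > 0L && !all(screen_texts(texts[seq_len(relevant)], lex))) {
          stop_validation("internal: planted relevant article fails screening")
        }
        list(total = total, relevant = relevant, decoys = decoys, texts = texts)
      })
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        newspaper = np, month = mo, total = cell$total,
        relevant = cell$relevant, decoys = cell$decoys,
        stringsAsFactors = FALSE)
      if (cell$total > 0L) {
        p <- ym_parse(mo)
        chunk <- chunk + 1L
        art_chunks[[chunk]] <- data.frame(
          newspaper = np, year = p$year, month = p$month,
          text = cell$texts, stringsAsFactors = FALSE)
      }
    }
  }
  if (clamped > 0L) {
    warning(sprintf("relevance probability clamped at 1 in %d cell(s)", clamped),
            call. = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  articles <- do.call(rbind, art_chunks)
  if (is.null(articles) || nrow(articles) == 0L) {
    stop_degenerate("generator produced an empty corpus (all cells zero or gapped)")
  }
  corpus <- hpu_corpus(articles, newspapers = spec$newspapers,
                       month_range = c(spec$months[1L],
                                       spec$months[length(spec$months)]))
  latent <- data.frame(month = spec$months,
                       multiplier = as.numeric(mult),
                       eps_shared = as.numeric(eps_shared),
                       intensity = spec$p0 * as.numeric(mult) * exp(as.numeric(eps_shared)),
                       stringsAsFactors = FALSE)
  list(corpus = corpus, truth = list(cells = cells, latent = latent))
}

#' Ground-truth count panels from generator bookkeeping
#'
#' Reshapes the per-cell bookkeeping of [generate_corpus()] into the
#' target-count and total-count panels the pipeline should reproduce
#' exactly.
#'
#' @param truth the `truth` element returned by [generate_corpus()].
#' @param spec the [synthetic_spec()] that produced it.
#' @return list with `A` (planted relevant counts) and `B` (planted totals)
#'   as [count_panel()]s; gapped cells are `NA`.
#' @export
truth_panels <- function(truth, spec) {
  cells <- truth$cells
  shape <- matrix(NA_real_, nrow = length(spec$newspapers), ncol = length(spec$months),
                  dimnames = list(spec$newspapers, spec$months))
  A <- shape
  B <- shape
  idx <- cbind(match(cells$newspaper, spec$newspapers),
               match(cells$month, spec$months))
  A[idx] <- cells$relevant
  B[idx] <- cells$total
  list(A = count_panel(A), B = count_panel(B))
}

#' Noise-free expected index implied by a synthetic spec
#'
#' The index the pipeline targets: a latent scaled-frequency path,
#' identical across newspapers, pushed through standardization,
#' cross-newspaper averaging and mean-100 normalization.  By default the
#' path is the deterministic `p0 * m_t`; passing the `latent` bookkeeping
#' of [generate_corpus()] uses the realized intensity
#' `p0 * m_t * exp(eps_shared_t)` instead, which is the target a single
#' simulated corpus should recover up to sampling and house-effect noise.
#' A flat path (all values equal) is a degenerate-data error, mirroring
#' [standardize_panel()].
#'
#' @param spec a [synthetic_spec()].
#' @param latent optional `truth$latent` data.frame from
#'   [generate_corpus()].
#' @return an [hpu_index()] labelled `"expected"`.
#' @export
expected_index <- function(spec, latent = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  path <- if (is.null(latent)) {
    spec$p0 * event_multipliers(spec)
  } else {
    stats::setNames(latent$intensity[match(spec$months, latent$month)], spec$months)
  }
  X <- matrix(rep(path, each = length(spec$newspapers)),
              nrow = length(spec$newspapers),
              dimnames = list(spec$newspapers, spec$months))
  Y <- standardize_panel(structure(X, class = c("ratio_panel", "matrix", "array")))
  Z <- aggregate_panel(Y, label = "expected")
  normalize_index(Z)
}
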