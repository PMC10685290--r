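---
title: "Constructing newspaper-based health policy uncertainty indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing newspaper-based health policy uncertainty indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpuindex)
```

## The measurement problem

Health policy uncertainty (HPU) is the inability of health-care actors —
providers, insurers, patients — to predict whether, when and how government
will change existing health policies.  Policies themselves are plain text
and hard to measure numerically, but the *reaction* to policy is not:
introductions and reversals of policy are accompanied by bursts of news
coverage that mention both the policy domain and the language of
uncertainty.  Newspaper-count indexes therefore operationalize policy
uncertainty as the relative frequency of articles that jointly mention the
domain, the policy apparatus, and uncertainty, in the tradition of
newspaper-based economic policy uncertainty (EPU) measures.

`hpuindex` implements this measurement pipeline for monthly newspaper
panels, with a Chinese-language builtin lexicon, and ships a synthetic
corpus generator with exact ground-truth bookkeeping so that every stage
can be validated end to end without any proprietary news database.

## Screening: the three-category criterion

An article is a **target article** when its text contains at least one term
from *each* of three categories:

* **health** — health care / medicine terms (卫生, 医药);
* **policy** — policy/measures, government/authority, country leaders,
  regulation, and health-care-reform terms (制度, 体制, …, 医保);
* **uncertainty** — uncertainty, volatility, instability, unpredictability
  and plunge/surge terms (不确定, 波动, …, 滞后).

```{r lexicon}
lex <- load_lexicon()        # builtin "hpu-china-2003"
lex
article_matches("国务院发布卫生新规，前景不确定", lex)$match
```

Matching is **plain substring containment** on NFKC-normalized text.  No
Chinese word segmentation is attempted: database keyword queries behave the
same way, and a segmenter would silently change counts.  NFKC
normalization harmonizes full-width and half-width character variants,
which real newspaper exports mix freely.  The cost of the substring
convention is a known one: very short tokens (e.g. 人大) can occur inside
longer proper nouns.  `article_matches()` therefore returns per-category
hit lists so audits can inspect exactly which terms fired.

## Index construction

For newspaper $i$ and month $t$, with $A_{it}$ target articles out of
$B_{it}$ total articles:

1. $X_{it} = A_{it} / B_{it}$ — scaling by the month's total volume removes
   differences in newspaper size and secular volume drift;
2. $Y_{it} = X_{it} / \sigma_i$, where $\sigma_i$ is the standard deviation
   of newspaper $i$'s $X$ series over the study window — standardization to
   unit SD stops high-variance papers from dominating;
3. $Z_t = \frac{1}{n_t}\sum_i Y_{it}$ over the $n_t$ newspapers present in
   month $t$;
4. the index is $Z_t \cdot 100 / M$ with $M = \overline{Z}$, so the
   published series has mean 100 over the window.

Conventions the package fixes where the construction leaves room:

* $\sigma_i$ is the **sample** SD (denominator $n-1$), the statistical
  default; all internal oracles fix the same convention.
* $\sigma_i$ is computed over each newspaper's **present** months only, for
  exactly the window being built, so gapped papers standardize over the
  months they actually cover.
* A covered month with $B_{it}=0$ cannot form a ratio; the cell is treated
  as missing for that month's average, with a warning.  Dropping the cell
  biases the month least, and the situation does not arise at realistic
  volumes.
* Monthly averages use the newspapers present that month, so a partially
  gapped panel still yields a full-length index.
* Floating-point reductions run in a fixed (sorted) order, making rebuilds
  bit-reproducible.

```{r build}
spec <- synthetic_spec(newspapers = paste0("paper", 1:4),
                       months = c("2019-01", "2021-12"),
                       lambda = 50, seed = 42)
sim <- generate_corpus(spec)
idx <- build_index(sim$corpus)
idx
mean(index_values(idx))
```

## Coverage gaps and splicing

Coverage gaps are **declared metadata**, never inferred from zeros: a
month with zero articles in a covered newspaper is a legitimate zero,
while a gap month holds no information at all.  When some newspapers lack
a year of coverage, three indexes are distinguished:

* the **donor** index from the fully covered newspapers over the whole
  window;
* the **gapped** index from all newspapers with the gap months excluded
  for everyone (so all papers contribute the same months);
* the **spliced** index: gap months taken from the donor, all other months
  from the gapped series, the union re-normalized to mean 100.

Donor values are inserted *unrescaled* and the union is then re-normalized:
the construction's only stated constraint is the mean-100 normalization,
and re-normalizing restores it exactly.  `splice_indexes()` always reports
the donor/gapped correlation on their overlapping months, so the
no-systematic-bias judgment that licenses the splice is made on computed
evidence, and the decision is recorded in the output metadata.

## Robustness testing and audit

`robustness_report()` builds one index per newspaper group and computes all
pairwise Pearson correlations (two-sided p from the t transform on $n-2$
degrees of freedom), flagging pairs against a criterion of $r \ge 0.74$ —
a threshold taken from the split-sample robustness practice of
newspaper-count indexes.  The default group presets are the full roster, a
national subset excluding the two local papers, the party-newspaper pair,
and the metropolitan nine (`newspaper_groups()`).

`sample_for_audit()` draws a per-newspaper simple random sample without
replacement of $\lceil f \cdot n_i \rceil$ target articles (default
$f = 0.5$), reproducible from an explicit seed; `pass_rate()` tabulates
the human audit labels to one decimal place alongside the raw fraction.
Two review rounds are supported; where rounds disagree, the second
(discussed and verified) round carries the decision.  Audit outcomes never
feed back into the counts: the index remains a machine-screened measure.

## The synthetic corpus generator

`synthetic_spec()`/`generate_corpus()` emulate the statistical structure
the pipeline assumes:

* per-cell totals $B_{it} \sim \text{Poisson}(\lambda_i)$;
* per-article relevance $\sim \text{Bernoulli}(p_t^{(i)})$ with
  $p_t^{(i)} = p_0 \, m_t \exp(\varepsilon_t + \eta_{it})$, where $m_t$ is
  an event multiplier, $\varepsilon_t \sim N(0, \texttt{shared\_signal\_sd})$
  is common to all newspapers and $\eta_{it} \sim
  N(0, \texttt{idiosyncratic\_sd})$ is a house effect;
* relevant articles get one term from each category embedded in filler
  text; a `decoy_rate` fraction of non-relevant articles get terms from
  exactly two categories (stressing the all-three criterion); the rest are
  pure filler.  Tokens are interleaved in random order and may abut, so
  substring matching is exercised without separators; the generator
  verifies that no decoy or filler text accidentally completes the triple
  and, only in that case, re-joins the offending text with filler
  separators.
* randomness is split hierarchically (newspaper → month → article), so
  enlarging the roster does not perturb the other newspapers' draws.

Defaults mirror a plausible mid-size study: 11 newspapers at
$\lambda = 100$ articles/month over 60 months (2018-01 to 2022-12),
baseline relevance $p_0 = 0.03$, a single shock month with $m = 8$
(2020-02, a pandemic-onset analogue), `decoy_rate = 0.2`,
`shared_signal_sd = 0.3` and `idiosyncratic_sd = 0.1`.  The noise SDs keep
the documented bound
$p_0 \max(m) e^{3(\sigma_s + \sigma_\eta)} \approx 0.80$ below 1, so
relevance stays a valid probability without clamping.  What the generator
does **not** model: real Chinese prose, topic structure, syndication,
editorial house style, or volume seasonality — so green tests demonstrate
pipeline correctness under the stated measurement model, not linguistic
validity of any particular lexicon on real news.

`expected_index()` exposes the target the pipeline should recover: by
default the deterministic path $p_0 m_t$, or, given the generator's latent
bookkeeping, the realized path $p_0 m_t e^{\varepsilon_t}$.  Rank-recovery
comparisons use the realized path: with a single shock the deterministic
path is flat elsewhere (nearly all ties), while the shared monthly signal
is genuine cross-newspaper structure the index is supposed to track.

```{r expected}
er <- expected_index(spec, latent = sim$truth$latent)
cor(index_values(idx), index_values(er)[index_months(idx)],
    method = "spearman")
```

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: a
straight-line loop re-implementation of the five construction steps
(agreement to 1e-12 on random panels of up to 4 newspapers × 12 months), a
naive triple-loop substring matcher, exact agreement of screened counts
with the generator's planted bookkeeping (50 seeds, decoy rates up to
0.5), shock-month recovery of the built index across 100 seeds at the
default spec, split-half correlations with and without a shared signal,
and gap-splice recovery against a gap-free reference.  Long-running
property checks use deliberately compact corpora (3–4 newspapers, 12–36
months, $\lambda$ = 30–50) — large enough to exercise every code path
while keeping the full suite fast; the shock-recovery check keeps the full
default spec.

## Known limitations

* Substring matching cannot distinguish homographs or negated mentions;
  the audit workflow exists precisely because machine screening
  overselects.
* The index is relative within its window: values are comparable across
  months of one build, not across builds with different windows or
  rosters.
* Splicing assumes the donor tracks the gapped series up to level/scale;
  the reported overlap correlation is evidence, not proof, of no
  systematic bias.
* No seasonal adjustment, smoothing, or circulation weighting is applied.
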