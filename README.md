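# infoseekr

Tools for studying how people seek health information on the web,
centered on cancer-related query logs. When a cancer diagnosis arrives
(or looms), patients and the people around them search — and the *order*
in which they visit pages of different kinds traces an
information-seeking journey. `infoseekr` models these journeys and the
social structure around them:

* **Cohort construction** from raw query-log rows: lexicon matching of
  35 common cancers (word-boundary, case-insensitive), a severity
  partition of diseases into *aggressive* (5-year relative survival
  strictly below the lexicon median) and *indolent* groups, and
  high-interest filtering (at least five categorized page visits over
  at least two of ten page categories).
* **Crowd-label aggregation**: five votes per page, decided by a
  three-vote majority, with a vector-space analysis showing that
  undecided pages really are ambiguous (they sit roughly equidistant
  from the centroids of their candidate categories).
* **Heavy-tail fits**: frequency-weighted log-log regression slopes
  (with R²) for pages-per-user, users-per-page and contacts-per-user
  distributions, plus a maximum-likelihood cross-check.
* **Hidden Markov journey models**: discrete-emission HMMs over the ten
  page categories, fitted by Baum–Welch (C++ core), with the number of
  hidden states K chosen by holdout prediction on a 75/25 user split
  with five random restarts. For a sequence $o_{1..T}$ with latent
  states $z_t$, the model is
  $z_1 \sim \pi$, $z_{t+1} \mid z_t \sim A_{z_t\cdot}$,
  $o_t \mid z_t \sim B_{z_t\cdot}$; one-step predictions come from the
  exact forward recursion. Fitted models are summarized by *signature
  output states* (categories with emission probability above 0.05, in
  decreasing order) and a *stability ranking* (self-transition
  probabilities).
* **Co-search analysis** on a proxy social network: acquaintance pairs
  who both searched, fold enrichment over a label-permutation null with
  a one-sided permutation p-value, disease overlap versus random
  matching, lag and duration contrasts by severity (rank-sum, sign and
  signed-rank tests), and per-category preference contrasts between
  first and second searchers.
* **Epidemiological regression**: query-log disease shares regressed
  jointly on age-adjusted incidence, 5-year survival and median age at
  diagnosis.

Because real query logs of this kind are proprietary, the package ships
a synthetic generator (`simulate_log()`) that reproduces the reported
statistical structure — power-law page views (slope −2.19), page
popularity (−2.25) and contact degrees (−0.99, median 6), 10.0 ± 14.5
day search periods, severity-specific journey models, and co-searching
acquaintance pairs planted at 6× the chance expectation with 0.56
disease overlap — so the whole pipeline is testable end to end by
round-trip recovery. See `vignette("journey-models")` for the models,
the generator's design and its limitations.

## Worked example

```r
library(infoseekr)

res <- run_pipeline(
  synth = synthetic_config(n_users = 5000, seed = 42),
  candidate_Ks = c(3, 5, 7), n_restarts = 3,
  n_permutations = 500, seed = 42)
print(res)
```

```
# Information-seeking pipeline report
config hash: 28a0bd0ef8e074f45cde8041e89b0aee  seed: 42

## Cohort
- users with events: 5000
- excluded at page gate: 4558
- excluded at category gate: 269
- included: 173

## Heavy-tailed distributions
- pages/user slope -2.07 (R2 0.98)
- users/page slope -2.17 (R2 0.99)
- contact degree slope -0.98 (R2 1.00), median 6

## Crowd labels
- 8001 pages, 7222 decided (fraction 0.903)

## Journey model selection
- best K = 5 (holdout error 0.672)

## Co-search pairs
- pairs: 47
- fold enrichment 6.02 (p = 0.002)
- disease overlap 0.53 vs 0.16 random

## Query share regression
- R2 = 0.829, incidence p = 8e-13
```

Reading the report: most users view only a few pages (the page gate
removes 91% of them, as a −2 power law implies), the holdout error
curve bottoms out at five hidden journey states, co-searching
acquaintance pairs occur six times more often than the permutation null
expects, pairs share a queried cancer far more often than randomly
matched users (0.53 vs 0.16), and disease incidence alone explains most
of the variance in query shares. At this small demonstration scale the
cohort is only 173 users; the slope estimates tighten onto their
generating values at the sizes used by the acceptance script below.

Individual stages are plain functions on tibbles:

```r
sim     <- simulate_log(synthetic_config(n_users = 20000, seed = 1))
matched <- match_cancer_queries(sim$events, sim$lexicon)
cohort  <- build_profiles(matched, sim$lexicon)
sel     <- select_num_states(profile_sequences(cohort$profiles), 2:8, seed = 1)
autoplot(sel)                    # holdout error curve
pairs   <- find_pairs(cohort$profiles, sim$contacts)
enrichment_vs_chance(pairs, cohort$profiles, sim$contacts, seed = 1)
```

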