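---
title: "Modeling health information-seeking journeys in search logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling health information-seeking journeys in search logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoseekr)
```

## The problem

When someone is diagnosed with cancer — or suspects they might be — they
and the people close to them turn to web search. The order in which they
visit pages of different kinds (symptoms, general disease information,
treatment, support groups, ...) traces an information-seeking *journey*
whose shape carries signal about the searcher's situation: how aggressive
the disease is, whether the searcher is the patient or an acquaintance,
and where they are in the process. Real query logs that would let one
study this are proprietary, so `infoseekr` couples the full analysis
pipeline with a synthetic-data generator that reproduces the statistical
structure such logs are reported to have. Every estimator in the package
can therefore be exercised end to end, and every generator parameter with
a downstream estimator is checked by round-trip recovery.

The pipeline has six analysis stages over three input tables (a query
log, a contact edge list and a cancer lexicon):

1. **Cohort construction** — keep query events naming one of 35 common
   cancers, split diseases into *aggressive* (5-year relative survival
   strictly below the across-lexicon median) and *indolent* groups,
   and keep users with at least five categorized page visits spanning at
   least two of the ten page categories.
2. **Crowd-label aggregation** — combine five independent labels per
   page by a three-vote majority; classify the vote patterns of
   undecided pages and quantify their ambiguity in a vector space model.
3. **Heavy-tail fits** — slopes (with R²) of pages-per-user,
   users-per-page and contacts-per-user distributions.
4. **Journey models** — discrete-emission hidden Markov models over the
   ten categories, with the number of hidden states chosen by holdout
   prediction on a 75/25 user split with 5 random restarts.
5. **Co-search analysis** — acquaintance pairs who both searched,
   their enrichment over a permutation null, disease overlap, lag and
   duration contrasts, and category-preference contrasts.
6. **Epidemiological regression** — query-log disease shares regressed
   jointly on age-adjusted incidence, 5-year survival and median age at
   diagnosis.

## The journey model

A user's categorized page visits form a sequence $o_1, \dots, o_T$ over
the ten canonical categories. The model assumes a latent state $z_t \in
\{1..K\}$ evolving as a Markov chain with initial distribution $\pi$,
transition matrix $A$, and emissions $o_t \mid z_t \sim B_{z_t\cdot}$.
Parameters are estimated by Baum–Welch (EM with scaled forward–backward
recursions, implemented in C++), stopping when the relative
log-likelihood change falls below $10^{-6}$ or after 500 iterations.
Three numerical choices matter:

* **Emission smoothing.** Each M-step adds a Dirichlet pseudo-count of
  $10^{-3}$ to every emission cell, so a category absent from the
  training set never gets exactly zero probability; otherwise a single
  held-out event could drive the holdout likelihood to $-\infty$.
  Transition and initial rows get only a $10^{-12}$ guard against a
  state losing all occupancy. The pseudo-count is small enough that the
  likelihood trace remains monotone to well below the convergence
  tolerance; monotonicity is asserted in the test suite on every fit it
  runs.
* **Free initial distribution.** Sequences may begin mid-journey (the
  log covers 92 days, not a user's life), so $\pi$ is estimated freely
  rather than pinned to a designated start state.
* **Random restarts.** EM is restarted from random draws — sparse
  Dirichlet emission rows (concentration 0.4), transitions with a
  sticky diagonal — and the restart with the best *training*
  log-likelihood is kept. Selecting restarts on training likelihood
  rather than holdout error keeps the test set out of every choice
  except the final comparison across $K$.

### Choosing the number of states

`select_num_states()` splits *users* (never events) 75/25, fits each
candidate $K$ with 5 restarts, and evaluates one-step-ahead prediction
on the held-out users: at every position $t \ge 2$ the model sees the
true prefix and predicts the next category through the forward
recursion. Two holdout metrics are computed:

* the **argmax error** — the fraction of positions where the most
  likely predicted category differs from the observed one, and
* the **predictive log-loss** — the mean negative log-probability the
  model assigned to the observed next category.

Selection minimizes the log-loss by default. The reason is resolution,
not preference: once a model captures the dominant structure, the most
likely next category rarely changes with $K$, so the argmax error
flattens into a plateau whose $\sim 10^{-3}$ wiggles are sampling noise,
and the error minimizer over a plateau is essentially a random member of
it. The log-loss is sensitive to the calibration of the whole predictive
distribution and keeps a clear minimum at the generating state count; in
repeated simulations from the package's five-state reference models it
recovers $K = 5$ in 9 of 10 seeds, whereas argmax-error selection lands
anywhere in $\{5..8\}$. Both metrics are reported per $K$, and
`metric = "argmax"` restores the coarser rule. Ties in either metric
break toward the smaller $K$; argmax ties inside a prediction break in
canonical category order.

### Interpreting fitted models

`signature_states()` lists, per hidden state, the categories whose
emission probability strictly exceeds 0.05, in decreasing order (ties
keep canonical order and are flagged). `stability_ranking()` orders
states by self-transition probability. For the default generator truths
these reproduce the qualitative picture the pipeline is designed to
detect: aggressive-disease journeys are string-like with the first two
states most stable and no support-group signature; indolent journeys are
densely interconnected, most stable in their last three states, and
carry `support` as a signature output.

## The synthetic generator

`simulate_log()` emulates a three-month national query log. What it
reproduces, and what it deliberately does not:

* **Heavy tails.** Pages-per-user counts follow a discrete power law
  with slope −2.19, users-per-page −2.25, and contact degrees −0.99
  with lower median 6 — drawn by inverse-CDF from the zeta-normalized
  pmf. Page-count laws truncate at $10^4$; the degree law truncates at
  the point that makes the lower median exactly the target (60 for the
  defaults), chosen to maximize the margin of the median on both sides.
* **Cohort composition.** Of users passing the five-page threshold,
  41.5% browse two or more categories (the included cohort); the rest
  repeat a single category drawn from their severity model's stationary
  output mixture. Users' dominant diseases are sampled with probability
  proportional to lexicon incidence times lognormal noise (sd 0.5 on
  the log scale), which makes incidence explain roughly 65–85% of the
  variance in query shares — the regime the regression stage is meant
  to detect.
* **Search windows.** Each user's visits span a whole-day window whose
  length is lognormal, matched by method of moments to the configured
  mean and sd (10.0 ± 14.5 days for ordinary users), with the scale
  corrected so that the mean *after* capping at the 92-day window still
  equals the configured mean. The first and last visits sit on the
  window boundaries, middle visits fall uniformly; the realized span is
  `max(1, round(duration))` days, whose expectation matches the
  configured mean (a ceiling would bias it half a day high). Intra-day
  ordering follows the emission order of the journey model; the
  generator does not attempt a realistic events-per-day profile.
* **Co-search structure.** The contact graph covers searchers plus four
  background users per searcher — contacts are mostly people who never
  query about cancer — realized by stub matching of the drawn degree
  sequence. Pairs of included users joined by an edge are *qualifying
  pairs*; the generator tops planted proband–acquaintance edges up to
  `pair_enrichment` (6) times the analytic label-permutation
  expectation $m\,I(I-1)/(N(N-1))$, solving a one-line fixed point for
  the effect of the added edges on $m$. Planted pairs use dedicated
  probands and acquaintances: probands draw severity-specific durations
  (13.9 ± 18.9 indolent, 11.0 ± 14.7 aggressive) and start in the first
  half of the window; acquaintances start an exponential lag later
  (mean 15 indolent / 9 aggressive days, at least one day so the
  ordering is unambiguous) and search 5.1 ± 8.1 (indolent) or
  12.5 ± 17.3 (aggressive) days, truncated to the window. The
  acquaintance shares the proband's disease with a probability solved
  so that the *overall* pair overlap — including chance overlap of
  tangled, non-planted pairs — hits the configured 0.56. First
  searchers query more distinct diseases (about 28% more on average)
  and their page mix is tilted toward treatment and information;
  acquaintances are tilted toward causes and social media.
* **Not modeled.** Query text is templated ("`<cancer> cancer
  <topic word>`" plus 5% non-cancer noise rows); page identifiers are
  synthetic; there is no real URL or language structure, no
  relationship types, and no attempt to replicate the proprietary
  log's absolute counts.

Because the generated tables then pass through the *same* cohort code as
real data would, passing round-trip tests demonstrates that the
estimators are consistent at realistic scales — not that real query logs
look like the generator. In particular the generator's journeys are
exactly HMM-distributed, so model-selection recovery says nothing about
whether real journeys have five states; it says the procedure finds the
right answer when one exists.

The bundled lexicon (35 cancers with incidence, survival and median age
at diagnosis) contains synthetic registry-like values with realistic
magnitudes; it is a stand-in, not a redistributed registry table.

## Heavy-tail fitting

`fit_loglog_slope()` regresses $\log_{10}$ frequency on $\log_{10}$
value over the unbinned histogram, weighted by frequency. The weights
are the delta-method inverse variances of $\log \hat f$ and they matter
enormously in practice: unweighted, the hundreds of singleton counts
scattered across the tail dominate the fit and drag a −2.19 sample
toward −1.3; weighted, generating exponents across $[-3, -1.5]$ are
recovered within 0.1 at $n = 50{,}000$. On a histogram that is exactly
a power law both variants reproduce the slope exactly with $R^2 = 1$.
A truncated discrete maximum-likelihood estimate
(`fit_powerlaw_mle()`) is provided as an independent cross-check; the
regression form remains the default because slope-plus-R² is what the
downstream reports quote. `distribution_median()` is the lower median,
so it always returns an observed count.

## Statistical contrasts

All group comparisons are nonparametric, mirroring standard practice for
these skewed quantities: rank-sum (Wilcoxon) tests for between-group
contrasts (lags, per-category view shares), an exact sign test for
paired within-pair duration differences, and a signed-rank test for the
paired diseases-searched contrast. The enrichment p-value is one-sided
from the permutation distribution with the add-one correction
$(1 + \#\{C_{\mathrm{null}} \ge C_{\mathrm{obs}}\})/(B + 1)$. The
"expected by chance" model is a label permutation that reassigns the
included-searcher labels over the contact graph's nodes, preserving the
graph and the cohort size; a degree-preserving rewiring null is
available as an alternative. Degenerate cases are defined rather than
left to warning-prone defaults: strata with fewer than two pairs skip
their test with a flag, an all-tie sign test returns $p = 1$, and a
constant-response regression reports $R^2 = 0$.

For the crowd-label ambiguity analysis, the spread statistic is
$(\max - \min)/\mathrm{mean}$ of a page's cosine distances to the
centroids of the categories its labelers voted for. The distance metric
(cosine on term frequencies, lower-cased, stop words removed) and the
spread definition are package choices — reasonable defaults for a
vector space model, used only comparatively between the decided and
ambiguous groups.

## Problem sizes and runtime

The acceptance analyses use 2,000 users for model selection (scanning
$K \in \{2..8\}$, about half a minute), 50,000 draws for the page-count
slope recoveries, a 20,000-node contact graph for the degree slope and
median, a 20,000-user simulation with 1,000 permutations for the
enrichment recovery, and a 200,000-user simulation for the duration
recoveries — the latter yields roughly 8,900 included users (standard
error ≈ 0.16 days on the mean search period) and ~2,400 indolent
co-search pairs, comfortably above the thousand-pair floor the
acquaintance-duration check calls for. These sizes keep every recovery
tolerance several standard errors wide of its target.

## Known limitations

* The ambiguity analysis requires page text; the pipeline's label stage
  only simulates and aggregates ballots, since the synthetic log does
  not generate page content.
* Lag means recover slightly low (≈ 14.1 observed vs 15 configured for
  indolent pairs) because lags are capped so the acquaintance's episode
  fits the 92-day window; the direction and ordering of the contrasts
  are unaffected.
* The label-permutation null treats all graph nodes as exchangeable;
  if inclusion correlated with degree in real data, the degree-
  preserving rewiring null would be the safer comparison.
* Model selection assumes users are exchangeable; there is no per-user
  random effect, and severity groups are modeled by separate HMMs
  rather than a shared model with covariates.
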