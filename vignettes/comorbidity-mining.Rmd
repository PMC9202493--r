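---
title: "Mining and validating disease comorbidities from adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating disease comorbidities from adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem and the pipeline

Spontaneous adverse-event reporting systems collect case reports — a
patient's drugs, indications (diseases), adverse reactions, and sparse
demographics — at the scale of millions of cases per decade. Because a case
report lists *all* of a patient's indications, the corpus is implicitly a
large co-morbidity survey, and conditions that co-occur with opioid use
disorder (OUD) more often than chance can be read off from it. `comorbnet`
implements that reading as a pipeline:

preprocess → mine association rules → build a disease comorbidity network
(DCN) → prioritize by a random walk with restart (RWR) from the OUD seed →
evaluate against a gold list; plus an independent case-control arm on
population-level EHR-style counts.

This vignette explains the model behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices where the method description
left room.

## Preprocessing model

**De-duplication.** Reporting systems receive successive versions of the
same case; only the latest version is valid. We treat the `version` column
as a totally ordered key per `case_id` (the quarterly file of origin is kept
as a demographic field, not as part of the key) and keep exactly the records
carrying each case's maximal key. The operation is idempotent and preserves
input order; records with a missing key are dropped with a warning rather
than silently kept.

**Normalization.** Mapping free-text drug/indication/reaction strings to
canonical vocabularies is, in production, a dictionary/NLP problem
(RxNorm-style generic names, UMLS-style preferred terms). The package
deliberately consumes the *result* of that step as two-column mapping
tables: matching is exact after case-folding and whitespace trimming, and
unmapped strings are dropped and counted, never passed through raw. The
per-table coverage (mapped unique raw strings / unique raw strings) is part
of the run report, since mapping loss is a first-order property of any
downstream estimate.

**Cohort flagging.** Literal OUD indication terms are vanishingly rare in
raw reports, so the cohort is defined by conjunction: a case is OUD-flagged
iff it has at least one opioid drug (lexicon) *and* at least one
drug-use-disorder term among its indications or reactions. Flagged cases
receive an injected OUD indication, which then participates in mining like
any other disease. Cases that already carry literal OUD indications keep
them (union semantics): the heuristic cohort is merged with, not substituted
for, the literal one. Flagging is monotone — adding an opioid drug or a
disorder term can only turn the flag on.

## Rule mining

Transactions are per-case indication sets. Frequent itemsets of size 1–3
are mined with FP-growth (FP-tree construction plus recursive
conditional-pattern-base mining, items ordered by descending global
frequency with lexicographic tie-breaks for determinism). Supports are
exact rational counts over the transaction total, reproducible bit for bit.

Parameters (`mining_params()`):

* `min_support = 0.000002` — the operating point used at full corpus scale
  (about 24 reports out of 12 million). For small corpora the fractional
  threshold falls below one transaction, so the effective count threshold is
  `max(1, ceiling(min_support * n))` — logged — or the explicit
  `min_support_count` override.
* `max_pattern_size = 3` — the cap applies to |X ∪ Y| of a rule.
* `min_lift = 1` — the independence boundary: a retained rule's diseases
  co-occur at least as often as independent diseases would.

Every frequent itemset of size ≥ 2 is expanded into all ordered non-empty
partitions (X, Y); a 3-itemset yields 6 rules. Direction is retained in the
output because the rule format is directional, but nothing downstream uses
it — co-occurrence, not causation. Confidence is computed and reported but
never used for filtering; support and lift are the only filters. Lift is
computed from integer counts (`count(XY) * n / (count(X) * count(Y))`) to
avoid accumulating division error, and the `lift >= min_lift` comparison
carries a 1e-12 guard against representation noise at the boundary.

## The comorbidity network and the walk

Each rule's disease set is clique-expanded: all unordered pairs become
undirected, unweighted edges; duplicates across rules merge. Rule
multiplicity is stored as optional per-edge metadata for diagnostics only —
the walk never sees it.

The RWR iterates `P(k+1) = (1 − c) W P(k) + c P(0)` from the seed indicator
`P(0)`, where `W = A D^{-1}` is the column-stochastic adjacency: each node's
mass spreads equally over its neighbours and a fraction `c` restarts at the
seed. Two choices deserve note:

* **Operator orientation.** Write-ups of restart walks sometimes express the
  update through the transpose of a normalized adjacency; with a symmetric
  adjacency the transpose of the *column*-normalized matrix is the
  row-normalized (averaging) operator, which does not preserve probability
  mass. We apply the column-stochastic operator directly, which makes every
  iterate an exact probability vector (the implementation tracks the largest
  deviation of `sum(P)` from 1 across iterates; it stays at floating-point
  noise). The fixed point solves `P* = c (I − (1 − c) W)^{-1} P(0)`, and the
  iterated solution is tested against that direct linear solve.
* **Connectivity.** Restart mass can never reach components not containing
  the seed — their stationary scores are identically zero — so the walk runs
  on the seed's connected component (`seed_component()`), which keeps the
  normalization exact and the reported ranking honest. Component sizes are
  always reported so disconnectedness is visible.

Parameters (`rwr_params()`): restart probability `c = 0.15` (the
conventional network-propagation choice: high enough to stay seed-local, low
enough to exploit multi-step structure); convergence threshold `tol = 1e-6`
on the iterate-to-iterate change. The change norm is not fixed by the usual
`|P(k+1) − P(k)| < 1e-6` notation; we default to L1, which is scale-free on
the probability simplex, and make the norm configurable. A `max_iter`
safety cap (10,000) turns non-convergence into an error carrying the last
residual rather than a silent partial result.

**Ranking and deciles.** Diseases are ranked by descending stationary
score, the seed excluded; ties break lexicographically and are flagged. The
ranked list is split into 10 contiguous bins with boundaries
`ceiling(i * n / 10)`, so bin sizes differ by at most one (n = 25 gives
3,2,3,2,…). The headline "first-decile precision" follows the
screening-evaluation usage: gold-standard members found in the first decile
divided by the gold-list size — recall-shaped, despite the name, and
documented as such; the conventional precision (hits / bin size) is reported
alongside.

## Case-control arm

Population-level EHR platforms expose only stratified counts, so the
association between OUD and a candidate comorbidity is estimated with the
Cochran–Mantel–Haenszel common odds ratio over 2×2 tables stratified on
the adjustment variables (age, sex, race, risk factors — adjustment happens
through stratification, not regression, because no individual-level data
exist):

* estimate: `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`;
* 95% CI: Robins–Breslow–Greenland variance of the log odds ratio — the
  standard choice that remains consistent both with few large strata and
  many sparse strata;
* p-value: Mantel–Haenszel chi-square, 1 df, two-sided, no continuity
  correction by default (a correction flag exists).

The estimator reduces exactly to the crude odds ratio on one stratum,
inverts exactly under exposure transposition, and is cross-checked against
`stats::mantelhaen.test()` in the test suite. Degenerate (zero-total)
strata are skipped and counted. Cell arithmetic is done in double
precision; 32-bit integer products overflow at realistic EHR counts.

**Suppressed cells.** Platforms mask counts below 10 and round the rest to
tens. `masked_input_handling()` resolves suppression before estimation
under an explicit, recorded policy: `midpoint` (default, substitutes 5 —
the centre of the suppressed 1–9 range), `drop` (remove the stratum),
`zero`, or a user constant. On simulated data the midpoint and drop
estimates bracket the unmasked estimate within sampling error.

**Demographics tables.** Column percentages are of the cohort total, not of
the category sum — patients can report multiple demographics at once, so
categories need not add up — and are rounded half-up to integers, matching
the convention of published population tables.

## What the synthetic generator emulates

`generate_case_reports()` produces the four FAERS-like tables (DEMO, DRUG,
INDI, REAC; `$`-delimited by default) with:

* per-case drug and reaction counts from zero-truncated Poissons with means
  2.91 and 3.00 — the averages observed in large spontaneous-report corpora
  — and disease counts averaging 1.37 (below);
* heavy-tailed (Zipf, exponent 1) background term frequencies;
* a planted seed disease ("opioid dependence", default prevalence 5%) whose
  cases also carry one opioid drug and one disorder reaction, so cohort
  flagging provably rediscovers exactly the seed cohort;
* planted comorbid diseases whose conditional inclusion probability given
  the seed is solved from the target lift L at marginal r:
  `P(com | seed) = L·r` and `P(com | no seed) = r(1 − Lp)/(1 − p)`,
  making the population lift exact by construction; infeasible targets
  (`L·r > 1` or `L·p ≥ 1`) are rejected, never clipped;
* a configurable fraction of stale case versions (identical except a
  smaller version key and one dropped reaction) to exercise de-duplication;
* one RNG stream per invocation, seeded explicitly: identical
  configurations give byte-identical files.

**Disease-count model.** Per-case disease counts are a two-component
zero-truncated Poisson mixture: a `multimorbid_fraction` (default 4%) of
cases draw from a high-mean component (default mean 8), the rest from a low
base rate. The mixture matters: under a *single* truncated Poisson with a
mean near 1.37, the lift between any two independent background diseases
equals the factorial-moment ratio (1 − e^{−λ}) < 1, so a lift ≥ 1 filter
would remove every background edge and the comorbidity network would
collapse to the planted clique — unlike real corpora, where multimorbid
patients make co-reported background diseases positively associated. With
the mixture the background pair lift is ≈ 1.5 and the network acquires
realistic background structure. Setting `multimorbid_fraction = 0` recovers
the single truncated Poisson.

**Calibration.** The planted inclusions would inflate the disease mean
beyond its configured value, so the base rate is solved (by
`uniroot` on the analytic expectation of `max(K, S)`, where K is the count
draw and S the number of planted inclusions) to make the expected per-case
disease count equal the configured mean exactly. The test suite checks all
three means within three Monte-Carlo standard errors at 50,000 cases.

**Study conditions.** The seed prevalence default of 5% is larger than the
\~0.5% OUD fraction of real report corpora; it is chosen so that the seed
cohort at desk-scale corpus sizes (10^4–10^5 cases) is large enough for
stable pair counts. Planted comorbid marginals default to 0.02, lift to 4.
For the end-to-end recovery check the mining floor is an absolute
`min_support_count = 20` at 100,000 cases, matching the absolute-count
operating point used at full scale (~24 reports of 12 million).

**What it does not emulate:** real field inventories (outcome codes, routes,
doses), real vocabulary coding, temporal reporting dynamics, demographic
confounding inside the report corpus, or free-text noise beyond simple
upper-casing. Passing tests on synthetic data therefore demonstrate the
*pipeline's* correctness against a known truth — not that any particular
real-world association is true.

`generate_stratified_cohort()` mirrors the validation arm: per stratum the
unexposed outcome count is binomial with odds `baseline_odds` and the
exposed with odds `baseline_odds × common_or`, so the conditional odds
ratio is homogeneous and known; optional masking then suppresses cells
below 10 and rounds the rest to tens. The test suite verifies 93–97%
empirical coverage of the 95% CI over 500 replicates at common odds ratios
1, 1.45 and 3.3, and consistency within 5% at large counts.

## Numerical choices and degenerate inputs

* Supports and lifts from integer counts; FP-tree ties broken
  lexicographically; all outputs deterministically ordered so artifact
  files are byte-stable.
* Empty transaction collections, empty vocabulary maps, all-degenerate
  strata, a seed absent from the network, and non-convergent walks are
  errors with actionable messages, not warnings.
* Rules with fewer than two distinct diseases are skipped with a warning
  during clique expansion (they cannot produce an edge).
* Crude odds ratios with a zero denominator error unless the
  Haldane–Anscombe continuity correction is enabled.

## Problem sizes in the test suite

The suite exercises: FP-growth vs exhaustive enumeration on 130 random
corpora (up to 2,000 transactions, up to 60 items); the iterated walk vs
the direct linear solve on 60 random graphs (up to 200 nodes); one
end-to-end planted-recovery run at 100,000 cases, 200 diseases, 10 planted
comorbids at lift 4; and 1,500 stratified-cohort replicates for CMH
coverage. These sizes were chosen to make sampling error small relative to
the tested tolerances while keeping the default test run fast.

## Known limitations

* The OUD flagging conjunction inherits the false positives of its
  real-world counterpart (e.g. a pain patient on opioids with an unrelated
  substance-use reaction term); the synthetic generator does not model
  these, so flagging accuracy on real data will be lower than the exact
  recovery seen in tests.
* The DCN is unweighted by design; association strength influences which
  edges exist (via the lift filter) but not the walk's transition
  probabilities.
* The decile "precision" is recall-shaped (see above); both conventions are
  reported to prevent misreading.
* CMH assumes a homogeneous odds ratio across strata; no
  heterogeneity test is provided, and stratification grids with many empty
  or masked cells push the estimate's behaviour toward the chosen
  suppression policy — which is why the policy is recorded in the result.
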