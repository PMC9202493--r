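# comorbnet

Comorbidity discovery from spontaneous adverse-event case reports, with a
stratified case-control validation arm.

People with opioid use disorder (OUD) frequently carry co-occurring medical
conditions, but systematic discovery of those comorbidities is hard:
individual-level clinical data are scarce, while large public
pharmacovigilance corpora (FAERS-style quarterly case-report tables) record
millions of patients' drugs, indications and adverse reactions in a noisy,
duplicated, free-text form. `comorbnet` implements an end-to-end discovery
pipeline over such data, for epidemiologists and biomedical informaticians:

1. **Preprocessing** — de-duplicate case versions (keep each case's latest
   record), normalize raw strings to canonical vocabularies via user-supplied
   mapping tables, and flag an OUD cohort: a case is flagged iff it has an
   opioid drug *and* a drug-use-disorder term among its indications or
   reactions, in which case an OUD indication is injected.
2. **Rule mining** — FP-growth frequent-itemset mining over per-case disease
   sets (patterns up to 3 diseases), and association rules
   {X → Y} filtered by support and lift,

   lift(X → Y) = supp(X ∪ Y) / (supp(X) · supp(Y)),

   so only disease sets that co-occur more than expected under independence
   survive.
3. **Disease comorbidity network (DCN)** — clique expansion of the rules:
   every disease pair inside a rule's X ∪ Y becomes an undirected,
   unweighted edge (a 4-disease rule contributes 6 edges).
4. **Prioritization** — random walk with restart from the OUD seed,

   P(k+1) = (1 − c) · W · P(k) + c · P(0),  c = 0.15,

   with W the column-stochastic adjacency of the seed's component, iterated
   to an L1 change below 1e-6; diseases are ranked by stationary score and
   evaluated in deciles against a gold-standard comorbidity list.
5. **Case-control validation** — on population-level stratified 2×2 counts
   (as exported by de-identified EHR platforms that suppress cells below
   10), the Cochran–Mantel–Haenszel common odds ratio with
   Robins–Breslow–Greenland confidence intervals and the Mantel–Haenszel
   chi-square test, plus small-cell suppression policies and
   demographics-table summaries.

A synthetic-data generator produces FAERS-like tables with *planted*
comorbidity structure (a seed disease whose cohort carries opioid drug and
disorder-reaction triggers, plus comorbid diseases at an exact target lift)
and masked stratified cohorts with a known common odds ratio, so every stage
is testable against ground truth without any external data.

## Worked example

Simulate 20,000 case reports (seed-disease prevalence 5%, 10 planted
comorbids at lift 4), run the full discovery chain, and evaluate against the
planted truth:

```r
library(comorbnet)

cfg <- report_gen_config(n_cases = 20000, rng_seed = 1)
sim <- generate_case_reports(cfg)

tabs  <- normalize_terms(deduplicate_cases(sim$tables),
                         sim$maps$drug, sim$maps$indication,
                         sim$maps$reaction)
cases <- flag_oud_cases(build_case_reports(tabs), sim$lexicon)
tx    <- build_transactions(cases)

params <- mining_params(min_support_count = 10)
rules  <- itemsets_to_rules(mine_frequent_itemsets(tx, params), params)
net    <- rules_to_network(rules)
res    <- rwr(seed_component(net, "opioid use disorder"),
              "opioid use disorder")
decile_evaluation(rank_diseases(res), sim$truth$true_comorbids)
```

which prints (abridged):

```
flagged OUD cases: 1019
Disease comorbidity network (undirected, unweighted)
  nodes: 115  edges: 492
Random walk with restart from 'opioid use disorder'
  nodes: 115  iterations: 43  final residual: 8.461e-07
Decile evaluation (114 ranked diseases, 10 gold)
  first-decile precision: 70% of gold list (7/10)
    0- 10% |######################################## 7
   10- 20% |#################                        3
   20- 30% |                                         0
   ...
```

The 1,019 flagged cases are exactly the simulated seed-disease cohort (the
generator plants both flagging triggers). Of the 10 planted comorbids, 7
land in the first decile of the 114-disease ranking at this corpus size, the
rest just below — at 100,000 cases the first decile captures 9–10 of 10.
The walk's stationary scores sum to one and the reported residual is the
final L1 change between iterates.

The case-control arm works the same way from a known truth:

```r
strata <- data.frame(label = paste0("s", 1:4),
                     exposed = c(2000, 3000, 1500, 2500),
                     unexposed = c(20000, 30000, 15000, 25000),
                     baseline_odds = c(0.05, 0.1, 0.2, 0.08))
tab <- generate_stratified_cohort(
  cohort_gen_spec(strata, common_or = 1.45, apply_mask = FALSE,
                  rng_seed = 3))
cmh_or(tab)
#> Mantel-Haenszel common odds ratio: 1.441 (95% CI 1.347-1.542)
#>   chi-square (1 df) = 113.199, two-sided p = 1.95e-26
```

`run_pipeline()` / `run_stage()` orchestrate all stages from one
configuration, writing per-stage artifacts and a run manifest that records
the count funnel (cases read → deduplicated → flagged → transactions →
itemsets → rules → nodes/edges → walk iterations) for reproducibility.

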