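# De-duplication, term normalization, cohort flagging, transactions.

test_that("deduplication keeps only each case's maximal version", {
  recs <- data.frame(case_id = "case7", version = c(1L, 2L),
                     payload = c("2019Q1", "2020Q3"))
  out <- deduplicate_cases(recs)
  expect_identical(nrow(out), 1L)
  expect_identical(out$payload, "2020Q3")

  fx <- dedup_fixture(k = 20L)
  out <- deduplicate_cases(fx)
  # brute-force oracle: group by case, keep max version
  oracle <- do.call(rbind, lapply(split(fx, fx$case_id), function(g) {
    g[g$version == max(g$version), , drop = FALSE]
  }))
  expect_identical(nrow(out), 20L)
  expect_setequal(out$payload, oracle$payload)
  expect_true(all(startsWith(out$payload[out$case_id %in%
                                           sprintf("c%02d", 1:5)], "new_")))
})

test_that("deduplication is idempotent and is the identity without dups", {
  fx <- dedup_fixture()
  once <- deduplicate_cases(fx)
  twice <- deduplicate_cases(once)
  cols <- c("case_id", "version", "payload")
  expect_identical(as.data.frame(once)[cols], as.data.frame(twice)[cols])

  clean <- dedup_fixture(dup_ids = character(0))
  expect_identical(as.data.frame(deduplicate_cases(clean))[
    c("case_id", "version", "payload")],
    clean[c("case_id", "version", "payload")])
})

test_that("records without a version key are dropped with a warning", {
  fx <- dedup_fixture()
  fx$version[3L] <- NA
  expect_warning(out <- deduplicate_cases(fx), "version key")
  expect_false(fx$payload[3L] %in% out$payload)
})

test_that("normalization maps raw strings and drops unmapped ones", {
  tabs <- list(
    demo = data.frame(case_id = "c1", version = 1L, age_group = "Adult",
                      sex = "Female", quarter = "2020Q1"),
    drug = data.frame(case_id = "c1", version = 1L,
                      drug_raw = c("MORPHINE SULFATE", "  morphine ",
                                   "GARBAGE-123")),
    indi = data.frame(case_id = "c1", version = 1L,
                      indication_raw = "PAIN"),
    reac = data.frame(case_id = "c1", version = 1L,
                      reaction_raw = "NAUSEA")
  )
  out <- normalize_terms(
    tabs,
    drug_map = c("morphine sulfate" = "morphine", "morphine" = "morphine"),
    indication_map = c("pain" = "pain"),
    reaction_map = c("nausea" = "nausea")
  )
  expect_identical(out$drug$drug, c("morphine", "morphine"))
  cov <- attr(out, "coverage")
  expect_identical(cov$drug$rows_dropped, 1L)
  expect_error(normalize_terms(tabs, drug_map = character(0),
                               indication_map = c(pain = "pain"),
                               reaction_map = c(nausea = "nausea")),
               "empty vocabulary map")
})

test_that("mapping coverage is reported as mapped / unique raw strings", {
  raws <- sprintf("RAW%02d", 1:10)
  tabs <- list(
    demo = data.frame(case_id = "c1", version = 1L, age_group = "A",
                      sex = "F", quarter = "Q"),
    drug = data.frame(case_id = rep("c1", 10L), version = 1L,
                      drug_raw = raws),
    indi = data.frame(case_id = "c1", version = 1L, indication_raw = "X"),
    reac = data.frame(case_id = "c1", version = 1L, reaction_raw = "Y")
  )
  seven <- stats::setNames(tolower(raws[1:7]), raws[1:7])
  out <- normalize_terms(tabs, drug_map = seven,
                         indication_map = c(x = "x"),
                         reaction_map = c(y = "y"))
  expect_equal(attr(out, "coverage")$drug$coverage, 0.70)
})

test_that("OUD flagging requires an opioid drug AND a disorder term", {
  lex <- cohort_lexicon(opioid_drugs = c("morphine", "oxycodone"),
                        disorder_terms = c("drug dependence", "opioid abuse"),
                        oud_label = "OUD")
  cases <- make_cases(
    drugs = list("morphine", "morphine", character(0), "aspirin"),
    indications = list(character(0), "pain", "opioid abuse", "pain"),
    reactions = list("drug dependence", "rash", character(0), "nausea")
  )
  out <- flag_oud_cases(cases, lex)
  expect_identical(out$oud_flag, c(TRUE, FALSE, FALSE, FALSE))
  expect_true("OUD" %in% out$indications[[1L]])
  expect_false("OUD" %in% out$indications[[2L]])
  expect_identical(attr(out, "n_flagged"), 1L)
})

test_that("flagging is monotone in added opioid drugs and disorder terms", {
  lex <- cohort_lexicon("morphine", "drug dependence", oud_label = "OUD")
  set.seed(91)
  drugs <- list("morphine", "aspirin", c("aspirin", "morphine"))
  indis <- list("pain", "drug dependence", character(0))
  reacs <- list("drug dependence", "rash", "nausea")
  base <- flag_oud_cases(make_cases(drugs, indis, reacs), lex)
  more <- flag_oud_cases(make_cases(
    lapply(drugs, function(d) c(d, "morphine")),
    indis,
    lapply(reacs, function(r) c(r, "drug dependence"))
  ), lex)
  expect_true(all(more$oud_flag >= base$oud_flag))
  expect_true(all(more$oud_flag))  # both triggers now present everywhere
})

test_that("transactions project indication sets and drop empty cases", {
  cases <- make_cases(
    drugs = list("a", "b", "c"),
    indications = list(c("pain", "OUD"), character(0), "anxiety"),
    reactions = list(character(0), character(0), character(0))
  )
  tx <- build_transactions(cases)
  expect_identical(length(tx), 2L)
  expect_setequal(tx[["c001"]], c("OUD", "pain"))
  expect_identical(length(tx),
                   sum(lengths(cases$indications) > 0L))  # count oracle
})

test_that("on synthetic data the flagged set equals the seed-disease cases", {
  cfg <- report_gen_config(n_cases = 3000, rng_seed = 13)
  sim <- generate_case_reports(cfg)
  tabs <- normalize_terms(deduplicate_cases(sim$tables),
                          sim$maps$drug, sim$maps$indication,
                          sim$maps$reaction)
  cases <- flag_oud_cases(build_case_reports(tabs), sim$lexicon)
  expect_setequal(cases$case_id[cases$oud_flag], sim$truth$seed_case_ids)
})

test_that("transactions survive a TSV round trip", {
  tx <- list(c1 = c("a", "b"), c2 = "c")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transactions(tx, path)
  expect_identical(read_transactions(path), tx)
})
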