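# Crude and Mantel-Haenszel odds ratios, masking policies, demographics.

test_that("crude odds ratio: null table, printed-count arithmetic, Haldane", {
  expect_equal(crude_or(10, 10, 10, 10), 1.0)
  # 2x2 derived from a published population table: 71,430 exposed cases of
  # 370,470 exposed; 5,051,290 outcome carriers of 74,574,090 total
  or <- crude_or(71430, 370470 - 71430, 5051290 - 71430,
                 74574090 - 370470 - (5051290 - 71430))
  expect_equal(or, 3.320392, tolerance = 1e-6)
  expect_error(crude_or(5, 0, 3, 2), "zero denominator")
  h <- crude_or(0, 10, 10, 10, continuity = 0.5)
  expect_equal(h, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("CMH reduces exactly to the crude OR on a single stratum", {
  s <- stratified_table("only", a = 12, b = 30, c = 7, d = 60)
  # equality is exact up to one floating-point rounding of the shared n_i
  expect_equal(cmh_or(s)$aor, crude_or(12, 30, 7, 60), tolerance = 1e-15)
})

test_that("pooling identical strata leaves the estimate unchanged", {
  one <- stratified_table("s1", 12, 30, 7, 60)
  two <- stratified_table(c("s1", "s2"), c(12, 12), c(30, 30),
                          c(7, 7), c(60, 60))
  expect_equal(cmh_or(two)$aor, cmh_or(one)$aor)
})

test_that("swapping exposure rows inverts the OR and negates the log CI", {
  s <- stratified_table(c("s1", "s2"), a = c(40, 15), b = c(60, 85),
                        c = c(25, 10), d = c(75, 90))
  fwd <- cmh_or(s)
  swapped <- stratified_table(s$stratum, a = s$c, b = s$d,
                              c = s$a, d = s$b)
  rev <- cmh_or(swapped)
  expect_equal(rev$aor, 1 / fwd$aor, tolerance = 1e-12)
  expect_equal(rev$ci_low, 1 / fwd$ci_high, tolerance = 1e-12)
  expect_equal(rev$ci_high, 1 / fwd$ci_low, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("CMH agrees with the reference stratified test", {
  set.seed(401)
  for (rep_i in 1:20) {
    k <- sample(2:5, 1L)
    a <- rpois(k, 40) + 1L; b <- rpois(k, 120) + 1L
    c_ <- rpois(k, 60) + 1L; d <- rpois(k, 300) + 1L
    s <- stratified_table(paste0("s", seq_len(k)), a, b, c_, d)
    mine <- cmh_or(s)
    arr <- array(0, c(2, 2, k))
    for (i in seq_len(k)) arr[, , i] <- matrix(c(a[i], c_[i], b[i], d[i]), 2)
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    expect_equal(mine$aor, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(c(mine$ci_low, mine$ci_high),
                 as.numeric(ref$conf.int), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate strata are skipped; suppressed cells are rejected", {
  s <- stratified_table(c("s1", "empty"), a = c(12, 0), b = c(30, 0),
                        c = c(7, 0), d = c(60, 0))
  res <- cmh_or(s)
  expect_identical(res$strata_used, 1L)
  expect_identical(res$strata_skipped, 1L)
  masked <- stratified_table("s1", NA, 30, 7, 60)
  expect_error(cmh_or(masked), "masked_input_handling")
})

test_that("masking policies: identity, drop, midpoint", {
  clean <- stratified_table("s1", 12, 30, 7, 60)
  same <- masked_input_handling(clean)
  expect_identical(as.data.frame(same)[1:5], as.data.frame(clean)[1:5])
  expect_identical(attr(same, "mask_policy")$cells_affected, 0L)

  masked <- stratified_table(c("s1", "s2"), a = c(NA, 40), b = c(30, 60),
                             c = c(7, 25), d = c(60, 75))
  dropped <- masked_input_handling(masked, policy = "drop")
  expect_identical(nrow(dropped), 1L)
  expect_identical(attr(dropped, "mask_policy")$strata_dropped, 1L)
  mid <- masked_input_handling(masked, policy = "midpoint")
  expect_identical(mid$a[1L], 5)
  expect_identical(cmh_or(mid)$strata_used, 2L)
})

test_that("midpoint and drop policies bracket the unmasked estimate", {
  strata <- data.frame(label = paste0("s", 1:6),
                       exposed = c(60, 80, 120, 2000, 90, 70),
                       unexposed = c(600, 800, 1200, 20000, 900, 700),
                       baseline_odds = 0.08)
  spec <- cohort_gen_spec(strata, common_or = 2, rng_seed = 11)
  masked <- generate_stratified_cohort(spec)
  unmasked <- attr(masked, "unmasked")
  truth_est <- cmh_or(unmasked)$aor
  mid_est <- cmh_or(masked_input_handling(masked, "midpoint"))$aor
  drop_est <- cmh_or(masked_input_handling(masked, "drop"))$aor
  # both policies stay in the neighbourhood of the unmasked estimate
  expect_lt(abs(log(mid_est) - log(truth_est)), log(1.5))
  expect_lt(abs(log(drop_est) - log(truth_est)), log(1.5))
})

test_that("demographic percentages reproduce published-table arithmetic", {
  counts <- data.frame(
    cohort = c("All", "OUD", "Hypo", "All"),
    variable = c("sex", "sex", "sex", "age"),
    category = c("Female", "Female", "Female", "Junior"),
    count = c(40008930, 188490, 2817360, 10347920)
  )
  totals <- c(All = 74574090, OUD = 370470, Hypo = 3739290)
  out <- summarize_demographics(counts, totals)
  expect_identical(out$percent, c(54L, 51L, 75L, 14L))
})

test_that("a one-person cohort reports 100% and tallies match by hand", {
  one <- make_cases(drugs = list("a"), indications = list("pain"),
                    reactions = list(character(0)))
  out <- summarize_demographics(list(solo = one))
  fem <- out[out$variable == "sex" & out$category == "Female", ]
  expect_identical(fem$count, 1L)
  expect_identical(fem$percent, 100L)

  set.seed(411)
  n <- 40L
  cases <- make_cases(rep(list("a"), n), rep(list("pain"), n),
                      rep(list(character(0)), n))
  cases$sex <- sample(c("Female", "Male"), n, replace = TRUE)
  cases$age_group <- sample(c("Adult", "Senior"), n, replace = TRUE)
  out <- summarize_demographics(list(g = cases))
  males <- out[out$category == "Male", ]
  expect_identical(males$count, sum(cases$sex == "Male"))
  expect_identical(males$percent,
                   as.integer(floor(100 * sum(cases$sex == "Male") / n + 0.5)))
})

test_that("half-up rounding matches table formatting conventions", {
  counts <- data.frame(cohort = "x", variable = "v",
                       category = c("a", "b"), count = c(5, 15))
  out <- summarize_demographics(counts, totals = c(x = 200))
  # 2.5% rounds up to 3, 7.5% rounds up to 8 (no banker's rounding)
  expect_identical(out$percent, c(3L, 8L))
})
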