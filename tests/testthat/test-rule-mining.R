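# FP-growth mining, rule generation, comorbidity extraction,
# precision/recall.

test_that("FP-growth reproduces the hand-checked example", {
  tx <- list(c("a", "b"), c("a", "b"), c("a", "c"), "b")
  fi <- mine_frequent_itemsets(tx, mining_params(min_support_count = 2))
  sup <- stats::setNames(fi$support, fi$itemset)
  expect_equal(sup[["a"]], 3 / 4)
  expect_equal(sup[["b"]], 3 / 4)
  expect_equal(sup[["a;b"]], 2 / 4)
  expect_false("c" %in% fi$itemset)
  expect_setequal(fi$itemset, c("a", "b", "a;b"))
})

test_that("support threshold boundaries behave as defined", {
  tx <- list(c("a", "b"), c("a", "b"), c("a", "c"), "b")
  # threshold above every count: nothing survives
  none <- mine_frequent_itemsets(tx, mining_params(min_support_count = 5))
  expect_identical(nrow(none), 0L)
  # fractional threshold of ~1: only itemsets present in every transaction
  suppressMessages(
    all_tx <- mine_frequent_itemsets(
      list(c("a", "b"), c("a", "b"), c("a", "b")),
      mining_params(min_support = 0.999))
  )
  expect_setequal(all_tx$itemset, c("a", "b", "a;b"))
  expect_error(mine_frequent_itemsets(list(), mining_params()), "empty")
})

test_that("FP-growth agrees with exhaustive enumeration on random corpora", {
  set.seed(101)
  for (rep in 1:30) {
    tx <- random_transactions(n = sample(c(50, 200, 500), 1L),
                              n_items = sample(10:40, 1L))
    minc <- sample(1:4, 1L)
    fi <- mine_frequent_itemsets(tx, mining_params(min_support_count = minc))
    got <- as.data.frame(fi)[order(fi$itemset), c("itemset", "count")]
    rownames(got) <- NULL
    want <- oracle_itemsets(tx, minc)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("every subset of a frequent itemset is at least as frequent", {
  set.seed(111)
  tx <- random_transactions(n = 400, n_items = 20)
  fi <- mine_frequent_itemsets(tx, mining_params(min_support_count = 3))
  sup <- stats::setNames(fi$count, fi$itemset)
  for (i in which(fi$size >= 2L)) {
    members <- strsplit(fi$itemset[i], ";", fixed = TRUE)[[1L]]
    for (k in seq_len(length(members) - 1L)) {
      subs <- utils::combn(members, k, paste, collapse = ";")
      expect_true(all(subs %in% names(sup)))
      expect_true(all(sup[subs] >= fi$count[i]))
    }
  }
})

test_that("rule lift follows the independence arithmetic", {
  # supports: a = 0.4, b = 0.5, {a,b} = 0.2 -> lift exactly 1
  tx <- c(rep(list(c("a", "b")), 2), rep(list("a"), 2), rep(list("b"), 3),
          rep(list("z"), 3))
  p <- mining_params(min_support_count = 2, min_lift = 0.5)
  rules <- itemsets_to_rules(mine_frequent_itemsets(tx, p), p)
  ab <- rules[rules$antecedent == "a" & rules$consequent == "b", ]
  expect_equal(ab$lift, 1.0)
  expect_equal(ab$support, 0.2)
  expect_equal(ab$confidence, 0.5)
})

test_that("a size-3 itemset yields the 6 ordered partitions", {
  tx <- rep(list(c("a", "b", "c")), 3)
  p <- mining_params(min_support_count = 2, min_lift = 0.1)
  rules <- itemsets_to_rules(mine_frequent_itemsets(tx, p), p)
  three <- rules[nchar(rules$antecedent) + nchar(rules$consequent) == 4L, ]
  got <- paste(three$antecedent, three$consequent, sep = "->")
  expect_setequal(got, c("a->b;c", "b->a;c", "c->a;b",
                         "a;b->c", "a;c->b", "b;c->a"))
})

test_that("lift is symmetric under antecedent/consequent exchange", {
  set.seed(121)
  tx <- random_transactions(n = 300, n_items = 12)
  p <- mining_params(min_support_count = 2, min_lift = 0.01)
  rules <- itemsets_to_rules(mine_frequent_itemsets(tx, p), p)
  key_fwd <- paste(rules$antecedent, rules$consequent, sep = "->")
  key_rev <- paste(rules$consequent, rules$antecedent, sep = "->")
  lift_by_key <- stats::setNames(rules$lift, key_fwd)
  expect_true(all(key_rev %in% key_fwd))
  expect_equal(unname(lift_by_key[key_rev]), rules$lift)
})

test_that("rules with lift below the threshold are filtered", {
  set.seed(131)
  tx <- random_transactions(n = 300, n_items = 12)
  p <- mining_params(min_support_count = 2, min_lift = 1)
  rules <- itemsets_to_rules(mine_frequent_itemsets(tx, p), p)
  expect_true(all(rules$lift >= 1 - 1e-12))
})

test_that("OUD comorbidities are the non-OUD items of OUD rules", {
  rules <- structure(data.frame(
    antecedent = c("OUD", "anxiety", "pain"),
    consequent = c("pain", "OUD", "fever"),
    support = 0.1, confidence = 0.5, lift = 2, count = 10
  ), class = c("association_rules", "data.frame"))
  expect_setequal(oud_comorbidities_from_rules(rules, "OUD"),
                  c("pain", "anxiety"))
  none <- rules[3L, , drop = FALSE]
  class(none) <- c("association_rules", "data.frame")
  expect_identical(oud_comorbidities_from_rules(none, "OUD"), character(0))
})

test_that("precision and recall follow their definitions", {
  expect_equal(precision_recall(c("a", "b"), c("a", "b")),
               c(precision = 1, recall = 1))
  expect_equal(precision_recall(c("x", "y"), c("a", "b")),
               c(precision = 0, recall = 0))
  pred <- sprintf("p%02d", 1:10)
  gold <- c(pred[1:4], sprintf("g%02d", 1:4))  # overlap 4, |gold| 8
  expect_equal(precision_recall(pred, gold),
               c(precision = 0.4, recall = 0.5))
  expect_equal(precision_recall(character(0), gold),
               c(precision = 0, recall = 0))
  expect_error(precision_recall("a", character(0)), "non-empty")
})

test_that("rules survive a TSV round trip", {
  set.seed(141)
  tx <- random_transactions(n = 100, n_items = 8)
  p <- mining_params(min_support_count = 2, min_lift = 0.1)
  rules <- itemsets_to_rules(mine_frequent_itemsets(tx, p), p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(as.data.frame(back), as.data.frame(rules), tolerance = 1e-12,
               ignore_attr = TRUE)
})
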