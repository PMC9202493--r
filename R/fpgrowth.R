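# Frequent-pattern mining: an FP-growth implementation (FP-tree construction
# plus recursive conditional-pattern-base mining) over disease transactions,
# and lift-filtered association-rule generation.

#' Mining parameters
#'
#' @param min_support minimum support fraction for a frequent itemset; the
#'   default 0.000002 is the operating point used for full-scale
#'   spontaneous-report corpora (about 24 reports out of 12 million)
#' @param max_pattern_size maximum number of diseases in a pattern,
#'   i.e. `|X ∪ Y|` for a rule (default 3)
#' @param min_lift minimum lift for a rule to be retained (default 1,
#'   the independence boundary)
#' @param min_support_count optional absolute-count override; useful for
#'   small corpora where `min_support * n` would fall below one transaction.
#'   When `NULL`, the threshold is `max(1, ceiling(min_support * n))`.
#' @return an object of class `mining_params`
#' @export
mining_params <- function(min_support = 0.000002, max_pattern_size = 3L,
                          min_lift = 1, min_support_count = NULL) {
  if (min_support <= 0 || min_support >= 1) {
    stop("min_support must lie in (0, 1)")
  }
  if (max_pattern_size < 2L) stop("max_pattern_size must be >= 2")
  if (min_lift <= 0) stop("min_lift must be > 0")
  if (!is.null(min_support_count) && min_support_count < 1) {
    stop("min_support_count must be >= 1")
  }
  structure(list(min_support = min_support,
                 max_pattern_size = as.integer(max_pattern_size),
                 min_lift = min_lift,
                 min_support_count = if (is.null(min_support_count)) NULL
                                     else as.integer(min_support_count)),
            class = "mining_params")
}

# --- FP-tree ----------------------------------------------------------------
# Nodes are environments: item (integer rank), count, parent, children (an
# environment keyed by item rank), nxt (header-chain link). Item ranks are
# assigned by descending global frequency, ties broken lexicographically, and
# every root-to-leaf path lists items in ascending rank (global) order.

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item
  e$count <- 0
  e$parent <- parent
  e$children <- new.env(parent = emptyenv())
  e$nxt <- NULL
  e
}

# Build an FP-tree from integer-coded transactions (ascending rank order)
# with per-transaction weights; m is the item-universe size.
fp_build <- function(tx, wt, m) {
  root <- fp_node(0L, NULL)
  header <- vector("list", m)
  total <- numeric(m)
  for (j in seq_along(tx)) {
    items <- tx[[j]]
    w <- wt[j]
    cur <- root
    for (it in items) {
      key <- as.character(it)
      child <- get0(key, envir = cur$children, inherits = FALSE)
      if (is.null(child)) {
        child <- fp_node(it, cur)
        assign(key, child, envir = cur$children)
        child$nxt <- header[[it]]
        header[[it]] <- child
      }
      child$count <- child$count + w
      total[it] <- total[it] + w
      cur <- child
    }
  }
  list(header = header, total = total)
}

# Recursive conditional-pattern-base mining. Emits (itemset, count) pairs
# into the accumulator environment keyed by the integer ranks.
fp_mine_rec <- function(tree, minc, max_size, suffix, acc) {
  present <- which(tree$total >= minc)
  for (i in rev(present)) {          # least-frequent first, classic order
    cnt <- tree$total[i]
    iset <- c(i, suffix)
    assign(paste(sort(iset), collapse = " "), cnt, envir = acc)
    if (length(iset) < max_size) {
      paths <- list()
      wts <- numeric(0)
      node <- tree$header[[i]]
      while (!is.null(node)) {
        p <- integer(0)
        par <- node$parent
        while (!is.null(par$parent)) {
          p <- c(p, par$item)
          par <- par$parent
        }
        if (length(p)) {
          paths[[length(paths) + 1L]] <- rev(p)
          wts <- c(wts, node$count)
        }
        node <- node$nxt
      }
      if (length(paths)) {
        cond_tot <- numeric(length(tree$total))
        for (jj in seq_along(paths)) {
          cond_tot[paths[[jj]]] <- cond_tot[paths[[jj]]] + wts[jj]
        }
        keep <- cond_tot >= minc
        if (any(keep)) {
          fpaths <- lapply(paths, function(p) p[keep[p]])
          nz <- lengths(fpaths) > 0L
          if (any(nz)) {
            ctree <- fp_build(fpaths[nz], wts[nz], length(tree$total))
            fp_mine_rec(ctree, minc, max_size, iset, acc)
          }
        }
      }
    }
  }
}

#' Mine frequent disease itemsets with FP-growth
#'
#' Returns every itemset of size 1..`max_pattern_size` whose support count
#' reaches the threshold, with exact supports (integer count / number of
#' transactions). The threshold is `min_support_count` when supplied,
#' otherwise `max(1, ceiling(min_support * n))`.
#'
#' @param transactions a list of character vectors (one itemset per case);
#'   duplicate items within a transaction are ignored
#' @param params a [mining_params()] object
#' @return a data.frame of class `frequent_itemsets` with columns `itemset`
#'   (semicolon-joined, lexicographically sorted), `size`, `count`,
#'   `support`; attributes `n_transactions` and `min_count`
#' @export
mine_frequent_itemsets <- function(transactions, params = mining_params()) {
  stopifnot(inherits(params, "mining_params"))
  n <- length(transactions)
  if (n == 0L) stop("transaction collection is empty")
  minc <- params$min_support_count %||%
    max(1L, as.integer(ceiling(params$min_support * n)))
  if (is.null(params$min_support_count)) {
    message("support threshold: ceiling(", params$min_support, " * ", n,
            ") = ", minc, " transaction(s)")
  }

  counts <- table(unlist(lapply(transactions, unique), use.names = FALSE))
  keep <- counts[counts >= minc]
  if (length(keep) == 0L) {
    out <- data.frame(itemset = character(0), size = integer(0),
                      count = numeric(0), support = numeric(0))
    class(out) <- c("frequent_itemsets", "data.frame")
    attr(out, "n_transactions") <- n
    attr(out, "min_count") <- minc
    return(out)
  }
  items <- names(keep)[order(-as.numeric(keep), names(keep))]
  rank_of <- stats::setNames(seq_along(items), items)

  tx_int <- lapply(transactions, function(t) {
    r <- rank_of[unique(t)]
    sort(unname(r[!is.na(r)]))
  })
  tx_int <- tx_int[lengths(tx_int) > 0L]

  tree <- fp_build(tx_int, rep(1, length(tx_int)), length(items))
  acc <- new.env(parent = emptyenv())
  fp_mine_rec(tree, minc, params$max_pattern_size, integer(0), acc)

  keys <- ls(acc, sorted = TRUE)
  cnts <- unlist(mget(keys, envir = acc), use.names = FALSE)
  named <- vapply(strsplit(keys, " ", fixed = TRUE), function(r) {
    join_terms(items[as.integer(r)])
  }, character(1))
  out <- data.frame(itemset = named,
                    size = lengths(strsplit(keys, " ", fixed = TRUE)),
                    count = cnts,
                    support = cnts / n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$size, out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frequent_itemsets", "data.frame")
  attr(out, "n_transactions") <- n
  attr(out, "min_count") <- minc
  out
}

#' Generate lift-filtered association rules from frequent itemsets
#'
#' For each frequent itemset of size >= 2, every ordered partition into
#' non-empty disjoint antecedent X and consequent Y is emitted (an itemset of
#' size 3 yields 6 candidate rules). Lift is computed as
#' `support(X ∪ Y) / (support(X) * support(Y))` from exact counts;
#' confidence is reported but never used for filtering. Rules with lift
#' below `min_lift` are discarded.
#'
#' @param itemsets a `frequent_itemsets` object
#' @param params a [mining_params()] (supplies `min_lift`)
#' @return a data.frame of class `association_rules` with columns
#'   `antecedent`, `consequent` (semicolon-joined), `support`, `confidence`,
#'   `lift`, `count`; attribute `rule_counts` reports the number of rules
#'   counted as ordered partitions and as unordered partition pairs
#' @export
itemsets_to_rules <- function(itemsets, params = mining_params()) {
  stopifnot(inherits(itemsets, "frequent_itemsets"))
  n <- attr(itemsets, "n_transactions")
  # hashed support lookup (a named-vector scan would be quadratic overall)
  sup_env <- list2env(
    stats::setNames(as.list(itemsets$count), itemsets$itemset),
    hash = TRUE, parent = emptyenv()
  )
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  cap <- if (nrow(big)) sum(2^big$size - 2) else 0L  # partition-count bound
  acc_a <- character(cap); acc_c <- character(cap)
  acc_sup <- numeric(cap); acc_conf <- numeric(cap)
  acc_lift <- numeric(cap); acc_cnt <- numeric(cap)
  n_out <- 0L
  for (ri in seq_len(nrow(big))) {
    members <- sort(split_terms(big$itemset[ri])[[1L]])
    len <- length(members)
    c_xy <- big$count[ri]
    for (sz in seq_len(len - 1L)) {
      picks <- utils::combn(len, sz)
      for (ci in seq_len(ncol(picks))) {
        x <- members[picks[, ci]]
        y <- members[-picks[, ci]]
        kx <- join_terms(x)
        ky <- join_terms(y)
        c_x <- get0(kx, envir = sup_env, inherits = FALSE)
        c_y <- get0(ky, envir = sup_env, inherits = FALSE)
        if (is.null(c_x) || is.null(c_y)) {
          stop("missing subset support for {", if (is.null(c_x)) kx else ky,
               "}: itemset table inconsistent")
        }
        lift <- c_xy * n / (c_x * c_y)
        if (lift >= params$min_lift - 1e-12) {
          n_out <- n_out + 1L
          acc_a[n_out] <- kx; acc_c[n_out] <- ky
          acc_sup[n_out] <- c_xy / n
          acc_conf[n_out] <- c_xy / c_x
          acc_lift[n_out] <- lift
          acc_cnt[n_out] <- c_xy
        }
      }
    }
  }
  idx <- seq_len(n_out)
  out <- data.frame(antecedent = acc_a[idx], consequent = acc_c[idx],
                    support = acc_sup[idx], confidence = acc_conf[idx],
                    lift = acc_lift[idx], count = acc_cnt[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("association_rules", "data.frame")
  attr(out, "n_transactions") <- n
  attr(out, "rule_counts") <- list(ordered = nrow(out),
                                   unordered_pairs = nrow(out) / 2)
  out
}

#' @export
print.association_rules <- function(x, n = 10L, ...) {
  cat("Association rules:", nrow(x), "(ordered partitions)\n")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Diseases co-occurring with OUD in any rule
#'
#' The mined OUD comorbidity set: the union of all non-OUD items over every
#' rule whose combined itemset `X ∪ Y` contains the OUD label.
#'
#' @param rules an `association_rules` object
#' @param oud_label the canonical OUD term
#' @return a sorted character vector of disease terms
#' @export
oud_comorbidities_from_rules <- function(rules,
                                         oud_label = "opioid use disorder") {
  if (nrow(rules) == 0L) return(character(0))
  ante <- split_terms(rules$antecedent)
  cons <- split_terms(rules$consequent)
  hits <- mapply(function(a, b) oud_label %in% c(a, b), ante, cons)
  if (!any(hits)) return(character(0))
  out <- unique(unlist(c(ante[hits], cons[hits]), use.names = FALSE))
  sort(setdiff(out, oud_label))
}

#' Precision and recall of a predicted comorbidity set
#'
#' @param predicted character vector of predicted disease terms
#' @param gold non-empty character vector of gold-standard terms
#' @return named numeric vector `c(precision =, recall =)`; precision is 0
#'   when `predicted` is empty
#' @export
precision_recall <- function(predicted, gold) {
  if (length(gold) == 0L) stop("gold-standard set must be non-empty")
  predicted <- unique(predicted)
  gold <- unique(gold)
  hit <- length(intersect(predicted, gold))
  c(precision = if (length(predicted)) hit / length(predicted) else 0,
    recall = hit / length(gold))
}

#' Write / read association rules as TSV
#'
#' Columns: `antecedent`, `consequent` (semicolon-joined), `support`,
#' `confidence`, `lift`, `count`.
#'
#' @param rules an `association_rules` object
#' @param path file path
#' @export
write_rules <- function(rules, path) {
  data.table::fwrite(as.data.frame(rules), path, sep = "\t")
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  class(x) <- c("association_rules", "data.frame")
  x
}
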