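# Independent oracles and fixture builders shared across tests. Each oracle
# is a direct, brute-force computation with no code shared with the
# implementation it checks.

# Exhaustive (Apriori-style) itemset enumeration: counts every sub-itemset
# of size 1..max_size of every transaction, then applies the threshold.
oracle_itemsets <- function(transactions, min_count, max_size = 3L) {
  keys <- unlist(lapply(transactions, function(t) {
    t <- sort(unique(t))
    unlist(lapply(seq_len(min(length(t), max_size)), function(k) {
      utils::combn(t, k, paste, collapse = ";")
    }))
  }), use.names = FALSE)
  tab <- table(keys)
  tab <- tab[tab >= min_count]
  out <- data.frame(itemset = names(tab), count = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out[order(out$itemset), , drop = FALSE]
}

# Random transaction corpora with a fixed vocabulary.
random_transactions <- function(n, n_items, max_len = 5L) {
  vocab <- sprintf("i%02d", seq_len(n_items))
  lapply(seq_len(n), function(i) {
    sort(sample(vocab, sample.int(max_len, 1L)))
  })
}

# Brute-force clique expansion of rules: all unordered pairs over X union Y.
oracle_edges <- function(ante, cons) {
  pairs <- unique(unlist(lapply(seq_along(ante), function(i) {
    m <- sort(unique(c(ante[[i]], cons[[i]])))
    if (length(m) < 2L) return(character(0))
    utils::combn(m, 2L, paste, collapse = "|")
  })))
  sort(pairs)
}

# Hand-rolled breadth-first search over an edge list (component membership).
oracle_component <- function(u, v, start) {
  adj <- split(c(v, u), c(u, v))
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# Random connected graph as a dcn: G(n, p) plus a spanning path so the walk
# is well posed on the whole vertex set.
random_connected_dcn <- function(n, p = 2 / n) {
  nodes <- sprintf("n%03d", seq_len(n))
  path_u <- nodes[-n]
  path_v <- nodes[-1L]
  extra <- which(matrix(stats::runif(n * n), n, n) < p & upper.tri(diag(n)),
                 arr.ind = TRUE)
  dcn_from_edges(c(path_u, nodes[extra[, 1L]]),
                 c(path_v, nodes[extra[, 2L]]))
}

# Tiny raw-record fixture for dedup tests: k cases, dup_ids carry a stale
# version 1 alongside version 2.
dedup_fixture <- function(k = 20L, dup_ids = sprintf("c%02d", 1:5)) {
  ids <- sprintf("c%02d", seq_len(k))
  latest <- data.frame(case_id = ids,
                       version = ifelse(ids %in% dup_ids, 2L, 1L),
                       payload = paste0("new_", ids),
                       stringsAsFactors = FALSE)
  if (length(dup_ids) == 0L) return(latest)
  stale <- data.frame(case_id = dup_ids, version = 1L,
                      payload = paste0("old_", dup_ids),
                      stringsAsFactors = FALSE)
  rbind(latest, stale)
}

# Minimal case_reports-shaped table for flagging tests.
make_cases <- function(drugs, indications, reactions) {
  n <- length(drugs)
  structure(data.table::data.table(
    case_id = sprintf("c%03d", seq_len(n)),
    age_group = rep("Adult", n), sex = rep("Female", n),
    quarter = rep("2020Q1", n),
    drugs = drugs, indications = indications, reactions = reactions
  ), class = c("case_reports", "data.table", "data.frame"))
}
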