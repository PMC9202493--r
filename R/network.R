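# Disease comorbidity network (DCN): undirected, unweighted graph built by
# clique expansion of mined association rules.

#' Build the disease comorbidity network from association rules
#'
#' Every pair of diseases within a rule's combined itemset `X ∪ Y` becomes an
#' undirected, unweighted edge (clique expansion): a rule with k distinct
#' diseases contributes `choose(k, 2)` candidate edges, e.g. the rule
#' `{OUD, cancer} -> {fever, pain}` contributes 6. Duplicate edges across
#' rules are merged; the number of rules supporting each edge is kept as
#' diagnostic metadata only (never used by the ranking walk). Rules with
#' fewer than two distinct diseases are skipped with a warning.
#'
#' @param rules an `association_rules` object (non-empty)
#' @return an object of class `dcn`
#' @export
rules_to_network <- function(rules) {
  if (nrow(rules) == 0L) stop("rule collection is empty")
  ante <- split_terms(rules$antecedent)
  cons <- split_terms(rules$consequent)
  pair_u <- vector("list", nrow(rules))
  pair_v <- vector("list", nrow(rules))
  skipped <- 0L
  for (ri in seq_len(nrow(rules))) {
    members <- sort(unique(c(ante[[ri]], cons[[ri]])))
    k <- length(members)
    if (k < 2L) {
      skipped <- skipped + 1L
      next
    }
    pairs <- utils::combn(members, 2L)
    pair_u[[ri]] <- pairs[1L, ]
    pair_v[[ri]] <- pairs[2L, ]
  }
  if (skipped > 0L) {
    warning(skipped, " rule(s) with fewer than two distinct diseases skipped")
  }
  edge_u <- unlist(pair_u, use.names = FALSE)
  edge_v <- unlist(pair_v, use.names = FALSE)
  if (length(edge_u) == 0L) stop("no rule yielded an edge")
  dt <- data.table::data.table(u = pmin(edge_u, edge_v),
                               v = pmax(edge_u, edge_v))
  edges <- dt[, list(rule_count = .N), by = c("u", "v")]
  data.table::setorder(edges, u, v)
  dcn_from_edges(edges$u, edges$v, rule_count = edges$rule_count)
}

#' Construct a DCN directly from an edge list
#'
#' @param u,v character vectors of edge endpoints (self-loops forbidden);
#'   parallel edges are merged
#' @param rule_count optional per-edge rule multiplicity (diagnostic only)
#' @return an object of class `dcn`: a list with the `igraph` graph and the
#'   unique-edge table
#' @export
dcn_from_edges <- function(u, v, rule_count = NULL) {
  stopifnot(length(u) == length(v))
  if (any(u == v)) stop("self-loops are not allowed in a DCN")
  edges <- data.table::data.table(u = pmin(u, v), v = pmax(u, v),
                                  rule_count = rule_count %||%
                                    rep(1L, length(u)))
  edges <- edges[, list(rule_count = sum(rule_count)), by = c("u", "v")]
  data.table::setorder(edges, u, v)
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(edges[, c("u", "v"), with = FALSE],
                                  directed = FALSE)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(list(graph = g, edges = edges), class = "dcn")
}

#' @export
print.dcn <- function(x, ...) {
  s <- network_stats(x)
  cat("Disease comorbidity network (undirected, unweighted)\n")
  cat("  nodes:", s$node_count, " edges:", s$edge_count, "\n")
  if (length(s$component_sizes)) {
    cat("  components:", length(s$component_sizes),
        " largest:", max(s$component_sizes), "\n")
  }
  invisible(x)
}

#' Node, edge, degree and component statistics of a DCN
#'
#' @param dcn a `dcn` object
#' @return a list: `node_count`, `edge_count`, `degree` (named integer
#'   vector), `component_sizes` (descending)
#' @export
network_stats <- function(dcn) {
  stopifnot(inherits(dcn, "dcn"))
  g <- dcn$graph
  deg <- igraph::degree(g)
  if (length(deg)) deg <- deg[order(names(deg))]
  comp <- igraph::components(g)
  list(node_count = as.integer(igraph::vcount(g)),
       edge_count = as.integer(igraph::ecount(g)),
       degree = deg,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Nodes of a DCN
#' @param dcn a `dcn` object
#' @return sorted character vector of disease terms
#' @export
dcn_nodes <- function(dcn) sort(igraph::V(dcn$graph)$name)

#' Restrict a DCN to the connected component containing a seed disease
#'
#' The ranking walk is run on the seed's component: restart mass can never
#' reach other components (their stationary probability is zero), so the
#' restriction makes the probability normalization exact and the reported
#' ranking honest.
#'
#' @param dcn a `dcn` object
#' @param seed a disease term present in the network
#' @return the induced `dcn` on the seed's component
#' @export
seed_component <- function(dcn, seed) {
  stopifnot(inherits(dcn, "dcn"))
  nodes <- igraph::V(dcn$graph)$name
  if (!seed %in% nodes) {
    stop("seed disease '", seed, "' is not a node of the network")
  }
  comp <- igraph::components(dcn$graph)
  keep <- names(comp$membership)[comp$membership ==
                                   comp$membership[[seed]]]
  edges <- dcn$edges[dcn$edges$u %in% keep & dcn$edges$v %in% keep]
  dcn_from_edges(edges$u, edges$v, rule_count = edges$rule_count)
}

#' Write a DCN edge list as TSV
#'
#' Columns: `u`, `v`, `rule_count`.
#' @param dcn a `dcn` object
#' @param path file path
#' @export
write_edges <- function(dcn, path) {
  data.table::fwrite(dcn$edges, path, sep = "\t")
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  dcn_from_edges(x$u, x$v, rule_count = x$rule_count)
}
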