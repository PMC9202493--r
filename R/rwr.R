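# Random walk with restart over the disease comorbidity network, disease
# ranking from the converged probability vector, and decile evaluation of
# the ranking against a gold-standard comorbidity list.

#' Random-walk-with-restart parameters
#'
#' @param c restart probability in (0, 1); 0.15 is the conventional choice
#' @param tol convergence threshold on the iterate-to-iterate change
#'   (default 1e-6); the L1 norm is used by default — under the probability
#'   simplex it is scale-free — but the norm is configurable
#' @param max_iter safety cap on iterations
#' @param norm which norm to apply to `P_{k+1} - P_k`
#' @return an object of class `rwr_params`
#' @export
rwr_params <- function(c = 0.15, tol = 1e-6, max_iter = 10000L,
                       norm = c("l1", "linf")) {
  if (c <= 0 || c >= 1) stop("restart probability c must lie in (0, 1)")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(c = c, tol = tol, max_iter = as.integer(max_iter),
                 norm = match.arg(norm)),
            class = "rwr_params")
}

#' Random walk with restart from a seed disease
#'
#' Iterates `P_{k+1} = (1 - c) W P_k + c P_0` from the seed indicator vector
#' `P_0`, where `W = A D^{-1}` is the column-normalized (column-stochastic)
#' adjacency of the seed's connected component: at each step the walker's
#' mass at a node is spread equally over that node's neighbours, and a
#' fraction `c` restarts at the seed. Because `W` is column-stochastic and
#' the update is a convex combination, the probability vector sums to 1 at
#' every iterate. Iteration stops when the change between iterates drops
#' below `tol`.
#'
#' If the network is disconnected it is restricted to the seed's component
#' first (see [seed_component()]); scores are reported for that component
#' only.
#'
#' @param dcn a `dcn` object containing `seed`
#' @param seed the seed disease term
#' @param params an [rwr_params()] object
#' @return an object of class `rwr_result`: list with `p` (named converged
#'   probability vector), `iterations`, `residual`, `max_mass_error` (the
#'   largest deviation of `sum(P)` from 1 observed at any iterate), `seed`,
#'   `params`
#' @export
rwr <- function(dcn, seed, params = rwr_params()) {
  stopifnot(inherits(dcn, "dcn"), inherits(params, "rwr_params"))
  if (!seed %in% igraph::V(dcn$graph)$name) {
    stop("seed disease '", seed, "' is not a node of the network")
  }
  comp <- igraph::components(dcn$graph)
  if (comp$no > 1L) {
    message("network is disconnected; restricting to the seed's component (",
            comp$csize[comp$membership[[seed]]], " of ",
            igraph::vcount(dcn$graph), " nodes)")
    dcn <- seed_component(dcn, seed)
  }
  A <- igraph::as_adjacency_matrix(dcn$graph, sparse = FALSE)
  nodes <- rownames(A)
  deg <- colSums(A)
  W <- sweep(A, 2L, deg, "/")   # column-stochastic: every column sums to 1
  p0 <- as.numeric(nodes == seed)
  p <- p0
  cc <- params$c
  norm_fun <- if (params$norm == "l1") {
    function(x) sum(abs(x))
  } else {
    function(x) max(abs(x))
  }
  iter <- 0L
  max_mass_error <- 0
  repeat {
    p_new <- (1 - cc) * as.numeric(W %*% p) + cc * p0
    resid <- norm_fun(p_new - p)
    p <- p_new
    iter <- iter + 1L
    max_mass_error <- max(max_mass_error, abs(sum(p) - 1))
    if (resid < params$tol) break
    if (iter >= params$max_iter) {
      stop("random walk did not converge after ", iter,
           " iterations (last residual ", signif(resid, 4), ")")
    }
  }
  structure(list(p = stats::setNames(p, nodes), iterations = iter,
                 residual = resid, max_mass_error = max_mass_error,
                 seed = seed, params = params),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("Random walk with restart from '", x$seed, "'\n", sep = "")
  cat("  nodes:", length(x$p), " iterations:", x$iterations,
      " final residual:", signif(x$residual, 4), "\n")
  top <- utils::head(sort(x$p[names(x$p) != x$seed], decreasing = TRUE), 5L)
  cat("  top scores:", paste(names(top), signif(top, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Direct linear solve of the RWR stationary state
#'
#' The fixed point of the restart iteration in closed form:
#' `P* = c (I - (1 - c) W)^{-1} P_0`. Useful as an independent check of the
#' iterated solution on small graphs.
#'
#' @inheritParams rwr
#' @return named stationary probability vector
#' @export
rwr_direct <- function(dcn, seed, params = rwr_params()) {
  stopifnot(inherits(dcn, "dcn"))
  dcn <- seed_component(dcn, seed)
  A <- igraph::as_adjacency_matrix(dcn$graph, sparse = FALSE)
  nodes <- rownames(A)
  W <- sweep(A, 2L, colSums(A), "/")
  p0 <- as.numeric(nodes == seed)
  p <- solve(diag(length(nodes)) - (1 - params$c) * W, params$c * p0)
  stats::setNames(p, nodes)
}

#' Rank diseases by their walk score
#'
#' Diseases are sorted by descending stationary probability; the seed itself
#' is excluded from the ranking. Ties are broken lexicographically and
#' flagged.
#'
#' @param result an `rwr_result` (or a named numeric probability vector)
#' @param seed the seed disease to exclude (taken from the result when
#'   omitted)
#' @return a data.frame `rank`, `disease`, `score`; attribute `ties` is TRUE
#'   when any scores were tied
#' @export
rank_diseases <- function(result, seed = NULL) {
  if (inherits(result, "rwr_result")) {
    p <- result$p
    seed <- seed %||% result$seed
  } else {
    p <- result
    if (is.null(seed)) stop("seed must be supplied with a bare vector")
  }
  p <- p[names(p) != seed]
  ord <- order(-p, names(p))
  out <- data.frame(rank = seq_along(ord), disease = names(p)[ord],
                    score = unname(p[ord]), stringsAsFactors = FALSE)
  attr(out, "ties") <- anyDuplicated(out$score) > 0L
  out
}

#' Decile evaluation of a ranked disease list
#'
#' Partitions the ranked list into 10 contiguous bins (top 0-10%, 10-20%,
#' ..., 90-100%) whose sizes differ by at most one — bin boundaries are
#' `ceiling(i * n / 10)` — and counts gold-standard members per bin. The
#' headline first-decile precision follows the pharmacovigilance-screening
#' usage: gold members found in the first decile divided by the gold-list
#' size (recall-shaped; e.g. 43 of 55 gives 78.2%). The conventional
#' precision (hits / bin size) is reported alongside.
#'
#' @param ranked a data.frame from [rank_diseases()] or a character vector of
#'   diseases in rank order (seed excluded)
#' @param gold non-empty character vector: the gold-standard comorbidity list
#' @return an object of class `decile_report`: list with `bins` (data.frame
#'   `decile`, `from`, `to`, `size`, `true_positives`),
#'   `first_decile_precision_pct` (percentage, 1 decimal),
#'   `first_decile_hit_rate` (hits / bin size), `n_ranked`, `n_gold`,
#'   `gold_in_ranking`
#' @export
decile_evaluation <- function(ranked, gold) {
  if (is.data.frame(ranked)) ranked <- ranked$disease
  if (length(ranked) == 0L) stop("ranked list is empty")
  if (length(gold) == 0L) stop("gold-standard list must be non-empty")
  gold <- unique(gold)
  n <- length(ranked)
  bounds <- as.integer(ceiling(seq_len(10L) * n / 10))
  from <- c(1L, utils::head(bounds, -1L) + 1L)
  to <- bounds
  is_gold <- ranked %in% gold
  tp <- vapply(seq_len(10L), function(i) {
    if (from[i] > to[i]) 0L else sum(is_gold[from[i]:to[i]])
  }, integer(1))
  bins <- data.frame(decile = seq_len(10L), from = from, to = to,
                     size = pmax(to - from + 1L, 0L), true_positives = tp)
  structure(list(
    bins = bins,
    first_decile_precision_pct = round(100 * tp[1L] / length(gold), 1L),
    first_decile_hit_rate = if (bins$size[1L] > 0) tp[1L] / bins$size[1L]
                            else NA_real_,
    n_ranked = n,
    n_gold = length(gold),
    gold_in_ranking = sum(is_gold)
  ), class = "decile_report")
}

#' @export
print.decile_report <- function(x, width = 40L, ...) {
  cat("Decile evaluation (", x$n_ranked, " ranked diseases, ",
      x$n_gold, " gold)\n", sep = "")
  cat("  first-decile precision: ", x$first_decile_precision_pct,
      "% of gold list (", x$bins$true_positives[1L], "/", x$n_gold, ")\n",
      sep = "")
  maxtp <- max(x$bins$true_positives, 1L)
  for (i in seq_len(10L)) {
    bar <- strrep("#", round(width * x$bins$true_positives[i] / maxtp))
    cat(sprintf("  %3d-%3d%% |%-*s %d\n", (i - 1L) * 10L, i * 10L,
                width, bar, x$bins$true_positives[i]))
  }
  invisible(x)
}

#' Write a ranking as TSV
#'
#' Columns: `rank`, `disease`, `score`, `is_gold`.
#' @param ranked data.frame from [rank_diseases()]
#' @param path file path
#' @param gold optional gold list used to fill `is_gold`
#' @export
write_ranking <- function(ranked, path, gold = character(0)) {
  out <- ranked
  out$is_gold <- out$disease %in% gold
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
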