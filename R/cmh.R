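# Stratified case-control analysis on population-level counts: crude and
# Cochran-Mantel-Haenszel common odds ratios with Robins-Breslow-Greenland
# confidence intervals, Mantel-Haenszel chi-square p-values, suppressed-cell
# policies, and demographic summary tables.

#' Crude odds ratio of a single 2x2 table
#'
#' `(a * d) / (b * c)` for exposed-with-outcome `a`, exposed-without `b`,
#' unexposed-with `c`, unexposed-without `d`. With `continuity > 0` the
#' Haldane-Anscombe correction adds that constant to every cell, keeping the
#' estimate finite when a cell is zero.
#'
#' @param a,b,c,d non-negative cell counts
#' @param continuity continuity-correction constant (0 = none)
#' @return the odds ratio
#' @export
crude_or <- function(a, b, c, d, continuity = 0) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells))) {
    stop("cells contain suppression markers; resolve them first ",
         "(see masked_input_handling)")
  }
  if (any(cells < 0)) stop("counts must be non-negative")
  cells <- cells + continuity
  if (cells[["b"]] * cells[["c"]] == 0) {
    stop("zero denominator (b * c = 0); enable a continuity correction")
  }
  unname((cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]]))
}

#' Cochran-Mantel-Haenszel common odds ratio across strata
#'
#' The Mantel-Haenszel estimate
#' `sum_i(a_i d_i / n_i) / sum_i(b_i c_i / n_i)`, its 95% confidence
#' interval from the Robins-Breslow-Greenland variance of the log odds
#' ratio (the standard sparse-data-robust choice), and a two-sided p-value
#' from the Mantel-Haenszel chi-square statistic (1 df, no continuity
#' correction unless requested). Strata with zero total are skipped and
#' counted. Reduces exactly to [crude_or()] on a single stratum.
#'
#' @param s a [stratified_table()]; suppressed cells must be resolved first
#'   via [masked_input_handling()]
#' @param conf_level confidence level (default 0.95)
#' @param correct apply the 0.5 continuity correction to the chi-square
#'   statistic
#' @return an object of class `cmh_result`: `aor`, `ci_low`, `ci_high`,
#'   `p_value`, `chisq`, `strata_used`, `strata_skipped`, `conf_level`
#' @export
cmh_or <- function(s, conf_level = 0.95, correct = FALSE) {
  stopifnot(inherits(s, "stratified_table"))
  if (any(is.na(s$a) | is.na(s$b) | is.na(s$c) | is.na(s$d))) {
    stop("stratified table contains suppressed cells; apply ",
         "masked_input_handling() first")
  }
  n_i <- s$a + s$b + s$c + s$d
  keep <- n_i > 0
  skipped <- sum(!keep)
  # double precision throughout: cell products overflow 32-bit integers
  a <- as.numeric(s$a[keep]); b <- as.numeric(s$b[keep])
  c_ <- as.numeric(s$c[keep]); d <- as.numeric(s$d[keep])
  n <- a + b + c_ + d
  if (length(n) == 0L) stop("all strata are degenerate (zero totals)")
  R <- a * d / n
  S <- b * c_ / n
  sum_r <- sum(R)
  sum_s <- sum(S)
  if (sum_s == 0) stop("Mantel-Haenszel denominator is zero (sum b*c/n = 0)")
  if (sum_r == 0) stop("Mantel-Haenszel numerator is zero (sum a*d/n = 0)")
  aor <- sum_r / sum_s

  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n
  Q <- (b + c_) / n
  var_log <- sum(P * R) / (2 * sum_r^2) +
    sum(P * S + Q * R) / (2 * sum_r * sum_s) +
    sum(Q * S) / (2 * sum_s^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(aor) + c(-1, 1) * z * sqrt(var_log))

  # Mantel-Haenszel chi-square (1 df), hypergeometric mean/variance of a_i
  e_a <- (a + b) * (a + c_) / n
  v_a <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  v_a[n <= 1] <- 0
  num <- abs(sum(a - e_a)) - if (correct) 0.5 else 0
  chisq <- max(num, 0)^2 / sum(v_a)
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)

  structure(list(aor = aor, ci_low = ci[1L], ci_high = ci[2L],
                 p_value = p, chisq = chisq,
                 strata_used = length(n), strata_skipped = skipped,
                 conf_level = conf_level, correct = correct),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf(
    "Mantel-Haenszel common odds ratio: %.3f (%d%% CI %.3f-%.3f)\n",
    x$aor, round(100 * x$conf_level), x$ci_low, x$ci_high))
  cat(sprintf("  chi-square (1 df) = %.3f, two-sided p = %.3g\n",
              x$chisq, x$p_value))
  cat("  strata used:", x$strata_used,
      if (x$strata_skipped) paste0("(", x$strata_skipped, " skipped)") else "",
      "\n")
  invisible(x)
}

#' Resolve suppressed cells in a masked stratified table
#'
#' Population-level EHR exports suppress cells below the reporting threshold
#' (typically counts 1-9). Policies: `"midpoint"` substitutes the midpoint
#' of the suppressed range (`mask_below / 2`, default 5), `"drop"` removes
#' any stratum with a suppressed cell, `"zero"` substitutes 0, `"constant"`
#' substitutes a user value. The chosen policy is recorded on the result.
#'
#' @param s a [stratified_table()] possibly containing `NA` (suppressed)
#'   cells
#' @param policy one of `"midpoint"`, `"drop"`, `"zero"`, `"constant"`
#' @param mask_below the suppression threshold that produced the masking
#' @param constant substitute value for `policy = "constant"`
#' @return the resolved [stratified_table()]; attribute `mask_policy`
#'   records the policy and the number of cells / strata affected
#' @export
masked_input_handling <- function(s, policy = c("midpoint", "drop", "zero",
                                                "constant"),
                                  mask_below = 10L, constant = NULL) {
  stopifnot(inherits(s, "stratified_table"))
  policy <- match.arg(policy)
  cells <- as.matrix(s[, c("a", "b", "c", "d")])
  masked <- is.na(cells)
  n_masked <- sum(masked)
  if (n_masked == 0L) {
    attr(s, "mask_policy") <- list(policy = policy, cells_affected = 0L,
                                   strata_dropped = 0L)
    return(s)
  }
  if (policy == "drop") {
    bad <- rowSums(masked) > 0L
    out <- stratified_table(s$stratum[!bad], s$a[!bad], s$b[!bad],
                            s$c[!bad], s$d[!bad])
    attr(out, "mask_policy") <- list(policy = policy,
                                     cells_affected = n_masked,
                                     strata_dropped = sum(bad))
    return(out)
  }
  fill <- switch(policy,
                 midpoint = mask_below / 2,
                 zero = 0,
                 constant = constant %||%
                   stop("policy = 'constant' needs a value"))
  for (col in c("a", "b", "c", "d")) {
    v <- s[[col]]
    v[is.na(v)] <- fill
    s[[col]] <- v
  }
  attr(s, "mask_policy") <- list(policy = policy, cells_affected = n_masked,
                                 strata_dropped = 0L, fill = fill)
  s
}

#' Demographic summary table with column percentages
#'
#' Produces counts and column percentages per cohort, in the layout of a
#' demographics-and-outcomes table: one row per (variable, category), one
#' count/percent pair per cohort. Percentages are of the cohort total
#' (patients can report multiple demographics at once, so category counts
#' need not sum to the total) and are rounded half-up to the nearest integer
#' percent.
#'
#' Input is either a count table (data.frame with columns `cohort`,
#' `variable`, `category`, `count`) plus named cohort `totals`, or a named
#' list of `case_reports` tables from which sex and age-group counts are
#' tallied.
#'
#' @param cohorts count data.frame or named list of `case_reports` tables
#' @param totals named numeric vector of cohort sizes (required for a count
#'   data.frame)
#' @return a data.frame of class `demographics_summary`: `cohort`,
#'   `variable`, `category`, `count`, `percent`
#' @export
summarize_demographics <- function(cohorts, totals = NULL) {
  if (is.data.frame(cohorts)) {
    counts <- cohorts
    if (is.null(totals)) stop("totals must be supplied with a count table")
  } else {
    stopifnot(is.list(cohorts), !is.null(names(cohorts)))
    counts <- do.call(rbind, lapply(names(cohorts), function(nm) {
      cases <- cohorts[[nm]]
      rbind(
        data.frame(cohort = nm, variable = "sex",
                   category = names(table(cases$sex)),
                   count = as.integer(table(cases$sex))),
        data.frame(cohort = nm, variable = "age",
                   category = names(table(cases$age_group)),
                   count = as.integer(table(cases$age_group)))
      )
    }))
    totals <- vapply(cohorts, nrow, 0L)
  }
  need <- c("cohort", "variable", "category", "count")
  if (!all(need %in% names(counts))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  tot <- totals[counts$cohort]
  counts$percent <- as.integer(round_half_up(100 * counts$count / tot))
  rownames(counts) <- NULL
  class(counts) <- c("demographics_summary", "data.frame")
  counts
}
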