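# Synthetic population-level stratified cohort counts with a known common
# odds ratio, emulating the masked aggregate tables exported by
# population-level EHR platforms (cells below 10 suppressed, the rest
# rounded to tens).

#' Specification for the stratified cohort generator
#'
#' @param strata a data.frame with columns `label`, `exposed`, `unexposed`
#'   (arm sizes) and `baseline_odds` (outcome odds among the unexposed)
#' @param common_or conditional odds ratio shared by all strata (> 0); the
#'   outcome odds among the exposed are `baseline_odds * common_or`
#' @param mask_below suppression threshold: generated cells strictly below
#'   this are replaced by a suppression marker (default 10)
#' @param round_to masked tables round remaining cells to the nearest
#'   multiple of this (default 10)
#' @param apply_mask whether [generate_stratified_cohort()] returns the
#'   masked table (the unmasked table is always attached as an attribute)
#' @param rng_seed integer seed
#' @return an object of class `cohort_gen_spec`
#' @export
cohort_gen_spec <- function(strata, common_or, mask_below = 10L,
                            round_to = 10L, apply_mask = TRUE,
                            rng_seed = 1L) {
  strata <- as.data.frame(strata)
  req <- c("label", "exposed", "unexposed", "baseline_odds")
  if (!all(req %in% names(strata))) {
    stop("strata must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(strata$label)) stop("stratum labels must be unique")
  if (any(strata$exposed < 0) || any(strata$unexposed < 0)) {
    stop("arm sizes must be non-negative")
  }
  if (any(strata$baseline_odds <= 0)) stop("baseline_odds must be > 0")
  if (!is.numeric(common_or) || common_or <= 0) stop("common_or must be > 0")
  structure(list(strata = strata, common_or = common_or,
                 mask_below = as.integer(mask_below),
                 round_to = as.integer(round_to),
                 apply_mask = isTRUE(apply_mask),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_gen_spec")
}

#' Stratified 2x2 count table
#'
#' Container for per-stratum exposure-by-outcome counts: `a` exposed with
#' outcome, `b` exposed without, `c` unexposed with outcome, `d` unexposed
#' without. Suppressed (masked) cells are stored as `NA` and written to TSV
#' as `"<10"`-style markers.
#'
#' @param stratum character vector of stratum labels
#' @param a,b,c,d cell counts (NA = suppressed)
#' @return a data.frame of class `stratified_table`
#' @export
stratified_table <- function(stratum, a, b, c, d) {
  x <- data.frame(stratum = as.character(stratum), a = a, b = b, c = c, d = d,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$stratum)) stop("stratum labels must be unique")
  cells <- as.matrix(x[, c("a", "b", "c", "d")])
  if (any(cells < 0, na.rm = TRUE)) stop("counts must be non-negative")
  class(x) <- c("stratified_table", "data.frame")
  x
}

#' Generate masked stratified cohort counts with a known common odds ratio
#'
#' For each stratum the outcome count among the unexposed is binomial with
#' odds `baseline_odds`, and among the exposed binomial with odds
#' `baseline_odds * common_or`, so the conditional (stratum-specific) odds
#' ratio is `common_or` everywhere. When masking is applied, any cell below
#' `mask_below` becomes `NA` (a suppression marker) and the remaining cells
#' are rounded to the nearest `round_to`, mirroring population-level EHR
#' platforms that never report cohorts smaller than 10.
#'
#' @param spec a [cohort_gen_spec()]
#' @return a [stratified_table()]; attributes `unmasked` (the pre-masking
#'   table) and `truth` (the generating common odds ratio) are attached
#' @export
generate_stratified_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  set.seed(spec$rng_seed)
  st <- spec$strata
  odds1 <- st$baseline_odds * spec$common_or
  p1 <- odds1 / (1 + odds1)
  p0 <- st$baseline_odds / (1 + st$baseline_odds)
  a <- stats::rbinom(nrow(st), st$exposed, p1)
  c_ <- stats::rbinom(nrow(st), st$unexposed, p0)
  tab <- stratified_table(st$label, a = a, b = st$exposed - a,
                          c = c_, d = st$unexposed - c_)
  out <- if (spec$apply_mask) {
    mask_stratified_table(tab, mask_below = spec$mask_below,
                          round_to = spec$round_to)
  } else {
    tab
  }
  attr(out, "unmasked") <- tab
  attr(out, "truth") <- spec$common_or
  out
}

#' Apply small-cell suppression and rounding to a stratified table
#'
#' @param tab a [stratified_table()]
#' @param mask_below cells strictly below this become `NA` (suppressed)
#' @param round_to remaining cells are rounded to the nearest multiple
#' @return the masked [stratified_table()]
#' @export
mask_stratified_table <- function(tab, mask_below = 10L, round_to = 10L) {
  stopifnot(inherits(tab, "stratified_table"))
  for (col in c("a", "b", "c", "d")) {
    v <- tab[[col]]
    v[!is.na(v) & v < mask_below] <- NA
    v[!is.na(v)] <- round_half_up(v[!is.na(v)] / round_to) * round_to
    tab[[col]] <- v
  }
  tab
}

#' Write / read a stratified table as TSV with suppression markers
#'
#' Suppressed cells are written as `"<{mask_below}"` (e.g. `"<10"`) and read
#' back as `NA`.
#'
#' @param tab a [stratified_table()]
#' @param path file path
#' @param mask_below threshold used to render the suppression marker
#' @return `path` invisibly (write); a [stratified_table()] (read)
#' @export
write_stratified_table <- function(tab, path, mask_below = 10L) {
  stopifnot(inherits(tab, "stratified_table"))
  out <- data.frame(stratum = tab$stratum)
  marker <- paste0("<", mask_below)
  for (col in c("a", "b", "c", "d")) {
    v <- as.character(tab[[col]])
    v[is.na(v)] <- marker
    out[[col]] <- v
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_stratified_table
#' @export
read_stratified_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", colClasses = "character",
                         data.table = FALSE)
  for (col in c("a", "b", "c", "d")) {
    v <- x[[col]]
    v[grepl("^<", v)] <- NA
    x[[col]] <- as.numeric(v)
  }
  stratified_table(x$stratum, x$a, x$b, x$c, x$d)
}
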