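# Preprocessing: raw FAERS-style tables -> de-duplicated, term-normalized
# per-case reports -> disease transactions, with OUD-cohort flagging.

#' Read FAERS-like delimited tables
#'
#' Reads the four quarterly-style tables (`DEMO.txt`, `DRUG.txt`, `INDI.txt`,
#' `REAC.txt`) written in the dialect produced by [write_faers_tables()]:
#' UTF-8, header row, configurable single-character delimiter (`"$"` by
#' default, the FAERS ASCII convention; comma and tab also work).
#'
#' @param dir directory containing the four tables
#' @param delim field delimiter
#' @return a named list of data.tables (`demo`, `drug`, `indi`, `reac`) of
#'   class `faers_tables`
#' @export
read_faers_tables <- function(dir, delim = "$") {
  files <- c(demo = "DEMO.txt", drug = "DRUG.txt", indi = "INDI.txt",
             reac = "REAC.txt")
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing)) {
    stop("missing table file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  }
  tabs <- lapply(files, function(f) {
    data.table::fread(file.path(dir, f), sep = delim, encoding = "UTF-8")
  })
  structure(tabs, class = "faers_tables")
}

#' Keep only the latest version of every case
#'
#' FAERS-style corpora contain superseded versions of the same case report.
#' For each `case_id` the maximal `version` key seen in any table is the
#' latest; only records carrying that key survive. Records with a missing
#' version key are dropped with a warning. Input row order is otherwise
#' preserved, and the operation is idempotent.
#'
#' @param tables a `faers_tables` list (or a single data.frame with
#'   `case_id` and `version` columns)
#' @return the de-duplicated tables, with attribute `dedup_counts` recording
#'   rows before/after and the number of distinct cases
#' @export
deduplicate_cases <- function(tables) {
  single <- is.data.frame(tables)
  tabs <- if (single) list(tab = data.table::as.data.table(tables)) else tables
  for (nm in names(tabs)) {
    miss <- is.na(tabs[[nm]]$version)
    if (any(miss)) {
      warning(sum(miss), " record(s) in '", nm,
              "' lack a version key and were dropped")
      tabs[[nm]] <- tabs[[nm]][!miss]
    }
  }
  all_keys <- data.table::rbindlist(
    lapply(tabs, function(t) t[, c("case_id", "version"), with = FALSE])
  )
  latest <- all_keys[, list(version = max(version)), by = "case_id"]
  rows_before <- vapply(tabs, nrow, 0L)
  out <- lapply(tabs, function(t) {
    # match against the per-case maximum, preserving t's row order
    vmax <- latest$version[match(t$case_id, latest$case_id)]
    t[t$version == vmax]
  })
  rows_after <- vapply(out, nrow, 0L)
  res <- if (single) out$tab else structure(out, class = "faers_tables")
  attr(res, "dedup_counts") <- list(
    rows_before = rows_before, rows_after = rows_after,
    n_cases = nrow(latest)
  )
  res
}

#' Read a raw-to-canonical vocabulary map
#'
#' Two-column TSV (`raw`, `canonical`). Keys are case-folded and trimmed, so
#' lookups are exact after that canonicalization (no fuzzy matching).
#'
#' @param path TSV file path
#' @return a named character vector: `canonical` named by normalized `raw`
#' @export
read_vocabulary_map <- function(path) {
  x <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("raw", "canonical") %in% names(x))) {
    stop("vocabulary map must have columns 'raw' and 'canonical'")
  }
  stats::setNames(x$canonical, normalize_key(x$raw))
}

#' Normalize raw strings to canonical vocabulary terms
#'
#' Replaces each raw drug / indication / reaction string by its canonical
#' term from the supplied maps (the stand-in for dictionary-based concept
#' normalization). Matching is exact after case-folding and whitespace
#' trimming. Unmapped strings are dropped — never passed through raw — and
#' counted; a per-table coverage report (mapped unique raws / unique raws)
#' is attached.
#'
#' @param tables de-duplicated `faers_tables`
#' @param drug_map,indication_map,reaction_map named character vectors as
#'   returned by [read_vocabulary_map()] (names are raw keys)
#' @return the tables with canonical `drug`, `indication`, `reaction`
#'   columns; attribute `coverage` holds the mapping-coverage report
#' @export
normalize_terms <- function(tables, drug_map, indication_map, reaction_map) {
  maps <- list(drug = drug_map, indi = indication_map, reac = reaction_map)
  raw_cols <- c(drug = "drug_raw", indi = "indication_raw",
                reac = "reaction_raw")
  out_cols <- c(drug = "drug", indi = "indication", reac = "reaction")
  for (nm in names(maps)) {
    if (length(maps[[nm]]) == 0L) stop("empty vocabulary map for '", nm, "'")
    names(maps[[nm]]) <- normalize_key(names(maps[[nm]]))
  }
  coverage <- list()
  for (nm in names(maps)) {
    tab <- data.table::as.data.table(tables[[nm]])
    raw <- tab[[raw_cols[[nm]]]]
    keys <- normalize_key(raw)
    mapped <- unname(maps[[nm]][keys])
    uniq <- unique(keys)
    n_mapped_uniq <- sum(uniq %in% names(maps[[nm]]))
    coverage[[nm]] <- list(
      unique_raw = length(uniq),
      mapped_unique_raw = n_mapped_uniq,
      coverage = n_mapped_uniq / length(uniq),
      rows_dropped = sum(is.na(mapped))
    )
    tab[[out_cols[[nm]]]] <- mapped
    tab <- tab[!is.na(mapped)]
    tables[[nm]] <- tab
  }
  attr(tables, "coverage") <- coverage
  tables
}

#' Assemble one report per case from the long tables
#'
#' @param tables de-duplicated, normalized `faers_tables`
#' @return a data.table of class `case_reports` with one row per case:
#'   `case_id`, list-columns `drugs`, `indications`, `reactions` (unique
#'   canonical terms), and demographics (`age_group`, `sex`, `quarter`)
#' @export
build_case_reports <- function(tables) {
  demo <- data.table::as.data.table(tables$demo)
  agg <- function(tab, col) {
    tab <- data.table::as.data.table(tab)
    tab[, list(terms = list(sort(unique(.SD[[1L]])))),
        by = "case_id", .SDcols = col]
  }
  drugs <- agg(tables$drug, "drug")
  indis <- agg(tables$indi, "indication")
  reacs <- agg(tables$reac, "reaction")
  cases <- demo[, c("case_id", "age_group", "sex", "quarter"), with = FALSE]
  cases <- unique(cases, by = "case_id")
  data.table::setnames(drugs, "terms", "drugs")
  data.table::setnames(indis, "terms", "indications")
  data.table::setnames(reacs, "terms", "reactions")
  for (t in list(drugs, indis, reacs)) {
    cases <- merge(cases, t, by = "case_id", all.x = TRUE)
  }
  empty_chr <- list(character(0))
  for (col in c("drugs", "indications", "reactions")) {
    isnull <- vapply(cases[[col]], is.null, logical(1))
    if (any(isnull)) cases[[col]][isnull] <- empty_chr
  }
  data.table::setorder(cases, case_id)
  class(cases) <- c("case_reports", class(cases))
  cases
}

#' Cohort lexicon for OUD flagging
#'
#' @param opioid_drugs canonical opioid drug names (non-empty)
#' @param disorder_terms canonical drug-use-disorder terms matched against
#'   indications and reactions (non-empty)
#' @param oud_label canonical label injected into flagged cases' indications
#' @return an object of class `cohort_lexicon`
#' @export
cohort_lexicon <- function(opioid_drugs, disorder_terms,
                           oud_label = "opioid use disorder") {
  if (!length(opioid_drugs) || !length(disorder_terms)) {
    stop("opioid_drugs and disorder_terms must be non-empty")
  }
  structure(list(opioid_drugs = as.character(opioid_drugs),
                 disorder_terms = as.character(disorder_terms),
                 oud_label = as.character(oud_label)),
            class = "cohort_lexicon")
}

#' @describeIn cohort_lexicon Read the lexicon from one-term-per-line files.
#' @param opioid_file,disorder_file paths to one-term-per-line text files
#' @export
read_cohort_lexicon <- function(opioid_file, disorder_file,
                                oud_label = "opioid use disorder") {
  cohort_lexicon(readLines(opioid_file), readLines(disorder_file), oud_label)
}

# which cases contain at least one term from `set` in list-column `lst`
.cases_hitting <- function(lst, set) {
  n <- length(lst)
  u <- unlist(lst, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(lst))
  as.logical(tabulate(idx[u %in% set], nbins = n))
}

#' Flag the OUD cohort and inject the OUD indication
#'
#' A case is flagged iff it has at least one opioid drug AND at least one
#' drug-use-disorder term among its indications or reactions (e.g. a
#' "morphine" drug record together with a "drug dependence" reaction). The
#' lexicon's `oud_label` is added to the indications of every flagged case,
#' so that the synthesized OUD indication participates in rule mining like
#' any other disease term. Cases whose indications already contain literal
#' OUD terms keep them (the heuristic cohort is merged by union).
#'
#' @param cases a `case_reports` table from [build_case_reports()]
#' @param lexicon a [cohort_lexicon()]
#' @return `cases` with a logical `oud_flag` column and the label injected;
#'   attribute `n_flagged` reports the cohort size
#' @export
flag_oud_cases <- function(cases, lexicon) {
  stopifnot(inherits(lexicon, "cohort_lexicon"))
  drug_hit <- .cases_hitting(cases$drugs, lexicon$opioid_drugs)
  dis_hit <- .cases_hitting(cases$indications, lexicon$disorder_terms) |
    .cases_hitting(cases$reactions, lexicon$disorder_terms)
  flag <- drug_hit & dis_hit
  cases$oud_flag <- flag
  if (any(flag)) {
    cases$indications[flag] <- lapply(cases$indications[flag], function(x) {
      sort(unique(c(x, lexicon$oud_label)))
    })
  }
  attr(cases, "n_flagged") <- sum(flag)
  cases
}

#' Project flagged case reports onto disease transactions
#'
#' One transaction per case: its indication set (including any injected OUD
#' label). Cases with no indications yield no transaction.
#'
#' @param cases a `case_reports` table (typically after [flag_oud_cases()])
#' @return a named list of character vectors (names are case ids)
#' @export
build_transactions <- function(cases) {
  tx <- cases$indications
  names(tx) <- cases$case_id
  tx[lengths(tx) > 0L]
}

#' Write transactions as one-line-per-case TSV
#'
#' Columns: `case_id`, semicolon-joined `items`.
#'
#' @param transactions named list of character vectors
#' @param path file path
#' @return `path`, invisibly
#' @export
write_transactions <- function(transactions, path) {
  data.table::fwrite(
    data.table::data.table(
      case_id = names(transactions),
      items = vapply(transactions, join_terms, character(1))
    ),
    path, sep = "\t"
  )
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  x <- data.table::fread(path, sep = "\t", colClasses = "character")
  tx <- split_terms(x$items)
  names(tx) <- x$case_id
  tx
}
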