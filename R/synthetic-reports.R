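# Synthetic FAERS-like case-report generator with planted comorbidity
# structure. Every downstream stage (dedup, normalization, cohort flagging,
# rule mining, network ranking) can be tested against the planted truth.

#' Configuration for the synthetic case-report generator
#'
#' The generator emulates the shape of FAERS quarterly tables: one
#' demographics row per case version, and long-format drug, indication and
#' reaction tables keyed by case id and version. Per-case counts of drugs,
#' diseases and reactions follow zero-truncated Poisson distributions whose
#' default means (2.91, 1.37, 3.00) are the averages observed in large
#' spontaneous-report corpora. Background disease/drug/reaction terms are
#' drawn from a Zipf-ranked marginal (spontaneous-report term frequencies are
#' heavy-tailed). A designated seed disease (opioid dependence) is planted
#' with prevalence `seed_disease_prevalence`; given the seed, each of
#' `n_true_comorbid` comorbid diseases is included with the conditional
#' probability that makes the population lift of the (seed, comorbid) pair
#' exactly `planted_lift` while keeping the comorbid's marginal at
#' `comorbid_marginal`. Cases carrying the seed disease also carry one opioid
#' drug and one drug-use-disorder reaction so that cohort flagging can
#' rediscover them. A `duplicate_fraction` of cases additionally emit a stale
#' earlier version (smaller version key, one reaction dropped) to exercise
#' de-duplication.
#'
#' @param n_cases number of case reports to generate
#' @param n_diseases disease vocabulary size (seed + comorbids + background)
#' @param n_drugs drug vocabulary size (5 opioids + background), must be >= 6
#' @param n_reactions reaction vocabulary size (3 disorder terms + background)
#' @param mean_diseases_per_case target mean distinct diseases per case (> 1)
#' @param mean_drugs_per_case target mean distinct drugs per case (> 1)
#' @param mean_reactions_per_case target mean distinct reactions per case (> 1)
#' @param seed_disease_prevalence probability a case carries the seed disease
#' @param n_true_comorbid number of planted comorbid diseases
#' @param planted_lift target population lift of each (seed, comorbid) pair,
#'   >= 1; infeasible targets (implied conditional probability > 1, or
#'   `planted_lift * seed_disease_prevalence >= 1`) are rejected
#' @param comorbid_marginal marginal inclusion probability of each planted
#'   comorbid disease
#' @param multimorbid_fraction fraction of cases drawn from the multimorbid
#'   component of the disease-count mixture. The per-case disease count is a
#'   two-component zero-truncated Poisson mixture: most cases report around
#'   one disease, while a small multimorbid fraction reports many. The
#'   resulting overdispersion is what gives co-reported background diseases
#'   their positive association (lift > 1), as in real spontaneous-report
#'   corpora; a single truncated Poisson at a mean near 1.37 would make
#'   every background pair negatively associated and a lift-filtered network
#'   would keep almost none of them. Set to 0 for a pure zero-truncated
#'   Poisson. Drug and reaction counts are always single zero-truncated
#'   Poisson.
#' @param multimorbid_mean Poisson mean of the multimorbid component
#' @param zipf_exponent exponent of the Zipf background marginal
#' @param duplicate_fraction fraction of cases emitting a stale earlier
#'   version, in `[0, 1)`
#' @param rng_seed integer seed; identical configurations and seeds produce
#'   byte-identical output files
#' @param delim field delimiter used when tables are written (FAERS ASCII
#'   convention is `"$"`)
#' @return a validated configuration object of class `report_gen_config`
#' @seealso [generate_case_reports()]
#' @export
report_gen_config <- function(n_cases,
                              n_diseases = 200L,
                              n_drugs = 100L,
                              n_reactions = 150L,
                              mean_diseases_per_case = 1.37,
                              mean_drugs_per_case = 2.91,
                              mean_reactions_per_case = 3.00,
                              seed_disease_prevalence = 0.05,
                              n_true_comorbid = 10L,
                              planted_lift = 4,
                              comorbid_marginal = 0.02,
                              multimorbid_fraction = 0.04,
                              multimorbid_mean = 8,
                              zipf_exponent = 1,
                              duplicate_fraction = 0.05,
                              rng_seed = 1L,
                              delim = "$") {
  cfg <- list(
    n_cases = as.integer(n_cases), n_diseases = as.integer(n_diseases),
    n_drugs = as.integer(n_drugs), n_reactions = as.integer(n_reactions),
    mean_diseases_per_case = mean_diseases_per_case,
    mean_drugs_per_case = mean_drugs_per_case,
    mean_reactions_per_case = mean_reactions_per_case,
    seed_disease_prevalence = seed_disease_prevalence,
    n_true_comorbid = as.integer(n_true_comorbid),
    planted_lift = planted_lift,
    comorbid_marginal = comorbid_marginal,
    multimorbid_fraction = multimorbid_fraction,
    multimorbid_mean = multimorbid_mean,
    zipf_exponent = zipf_exponent,
    duplicate_fraction = duplicate_fraction,
    rng_seed = as.integer(rng_seed),
    delim = delim
  )
  class(cfg) <- "report_gen_config"
  validate_report_gen_config(cfg)
  cfg
}

validate_report_gen_config <- function(cfg) {
  with(cfg, {
    if (n_cases < 1L) stop("n_cases must be a positive integer")
    if (n_drugs < 6L) stop("n_drugs must be >= 6 (5 opioids + background)")
    if (n_reactions < 4L) stop("n_reactions must be >= 4")
    means <- c(mean_diseases_per_case, mean_drugs_per_case,
               mean_reactions_per_case)
    if (any(means <= 1)) {
      stop("per-case means must exceed 1 (zero-truncated counts)")
    }
    if (seed_disease_prevalence <= 0 || seed_disease_prevalence >= 1) {
      stop("seed_disease_prevalence must lie in (0, 1)")
    }
    if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
      stop("duplicate_fraction must lie in [0, 1)")
    }
    if (planted_lift < 1) stop("planted_lift must be >= 1")
    if (n_true_comorbid < 0L || n_true_comorbid >= n_diseases) {
      stop("n_true_comorbid must be non-negative and < n_diseases")
    }
    if (comorbid_marginal <= 0 || comorbid_marginal >= 1) {
      stop("comorbid_marginal must lie in (0, 1)")
    }
    if (multimorbid_fraction < 0 || multimorbid_fraction >= 1) {
      stop("multimorbid_fraction must lie in [0, 1)")
    }
    if (multimorbid_mean <= 1) stop("multimorbid_mean must exceed 1")
    mm_contrib <- multimorbid_fraction *
      multimorbid_mean / (1 - exp(-multimorbid_mean))
    if (mean_diseases_per_case - mm_contrib <=
          (1 - multimorbid_fraction)) {
      stop("mean_diseases_per_case too small for the multimorbid mixture: ",
           "the base component would need mean <= 1")
    }
    # lift feasibility: conditional and off-seed inclusion probabilities
    q <- planted_lift * comorbid_marginal
    if (q > 1) {
      stop("infeasible planted_lift: implied P(comorbid | seed) = ",
           signif(q, 4), " > 1; lower planted_lift or comorbid_marginal")
    }
    if (planted_lift * seed_disease_prevalence >= 1) {
      stop("infeasible planted_lift: planted_lift * seed_disease_prevalence ",
           "must be < 1 so off-seed inclusion probability stays non-negative")
    }
    invisible(NULL)
  })
  invisible(cfg)
}

# Fixed canonical vocabulary pieces ------------------------------------------

.seed_disease_term <- "opioid dependence"
.oud_label <- "opioid use disorder"
.opioid_drugs <- c("morphine", "oxycodone", "fentanyl", "hydrocodone",
                   "methadone")
.disorder_terms <- c("drug dependence", "drug abuse",
                     "drug withdrawal syndrome")

sim_vocabulary <- function(cfg) {
  k <- cfg$n_true_comorbid
  n_bg_dis <- cfg$n_diseases - 1L - k
  if (n_bg_dis < 1L) stop("n_diseases too small for seed + comorbids")
  list(
    seed = .seed_disease_term,
    comorbids = if (k > 0L) sprintf("disease_%04d", seq_len(k)) else character(0),
    bg_diseases = sprintf("disease_%04d", k + seq_len(n_bg_dis)),
    opioids = .opioid_drugs,
    bg_drugs = sprintf("drug_%04d", seq_len(cfg$n_drugs - 5L)),
    disorders = .disorder_terms,
    bg_reactions = sprintf("reaction_%04d", seq_len(cfg$n_reactions - 3L))
  )
}

# Planted-lift arithmetic: with marginal r, prevalence p and lift L,
#   P(comorbid | seed)     q  = L * r
#   P(comorbid | no seed)  r' = r * (1 - L * p) / (1 - p)
planted_probs <- function(cfg) {
  r <- cfg$comorbid_marginal
  p <- cfg$seed_disease_prevalence
  L <- cfg$planted_lift
  list(q = L * r, r_off = r * (1 - L * p) / (1 - p))
}

# Disease-count calibration: the per-case total is max(K, S) where K is the
# background budget — a two-component zero-truncated Poisson mixture
# (multimorbid fraction at multimorbid_mean, the rest at a base rate) — and
# S the number of planted inclusions (seed + comorbids). Solve the base rate
# so that the analytic expectation E[max(K, S)] equals the configured mean.
disease_count_rate <- function(cfg) {
  m <- cfg$mean_diseases_per_case
  pi_m <- cfg$multimorbid_fraction
  lam_m <- cfg$multimorbid_mean
  pp <- planted_probs(cfg)
  k <- cfg$n_true_comorbid
  p <- cfg$seed_disease_prevalence
  pmf_seed <- c(0, poisbinom_pmf(rep(pp$q, k)))      # S = 1 + Binom-like
  pmf_off <- c(poisbinom_pmf(rep(pp$r_off, k)), 0)   # S = Binom-like
  p_s <- p * pmf_seed + (1 - p) * pmf_off            # P(S = 0..k+1)
  smax <- length(p_s) - 1L
  mix_pmf <- function(j, lam_b) {
    pi_m * ztp_pmf(j, lam_m) + (1 - pi_m) * ztp_pmf(j, lam_b)
  }
  mix_mean <- function(lam_b) {
    pi_m * lam_m / (1 - exp(-lam_m)) +
      (1 - pi_m) * lam_b / (1 - exp(-lam_b))
  }
  expected_total <- function(lam_b) {
    # E[max(K, s)] = E[K] + sum_{j < s} (s - j) P(K = j)
    corr <- vapply(0:smax, function(s) {
      if (s < 2L) return(0)
      j <- seq_len(s - 1L)
      sum((s - j) * mix_pmf(j, lam_b))
    }, numeric(1))
    mix_mean(lam_b) + sum(p_s * corr)
  }
  m_min <- expected_total(1e-9)
  if (m <= m_min) {
    stop("mean_diseases_per_case = ", m, " is not attainable: the ",
         "multimorbid component and planted inclusions alone give an ",
         "expected per-case count of ", signif(m_min, 5))
  }
  stats::uniroot(function(l) expected_total(l) - m,
                 interval = c(1e-9, ztp_rate(max(m, 1 + 1e-6)) + 1e-9),
                 tol = 1e-12)$root
}

# Draw the background disease budget from the mixture.
sample_disease_counts <- function(n, cfg, lam_b) {
  is_multi <- stats::runif(n) < cfg$multimorbid_fraction
  K <- integer(n)
  K[is_multi] <- rztpois(sum(is_multi), cfg$multimorbid_mean)
  K[!is_multi] <- rztpois(sum(!is_multi), lam_b)
  K
}

# Background term sampling: counts[i] distinct terms for case i, drawn
# without replacement with Zipf weights. Single draws are vectorized.
sample_background <- function(counts, n_terms, weights) {
  out <- vector("list", length(counts))
  counts <- pmin(counts, n_terms)
  singles <- which(counts == 1L)
  if (length(singles)) {
    draws <- sample.int(n_terms, length(singles), replace = TRUE,
                        prob = weights)
    for (ii in seq_along(singles)) out[[singles[ii]]] <- draws[ii]
  }
  for (i in which(counts > 1L)) {
    out[[i]] <- sample.int(n_terms, counts[i], prob = weights)
  }
  out
}

#' Generate synthetic FAERS-like case reports with planted comorbidities
#'
#' Draws `n_cases` case reports under the generative model described in
#' [report_gen_config()] and returns the four FAERS-like raw tables (DEMO,
#' DRUG, INDI, REAC), the vocabulary maps and cohort lexicon needed by the
#' preprocessing stage, and the planted truth (seed disease, true comorbids,
#' per-disease marginals, seed-case ids). Raw strings are upper-cased
#' canonical terms, so the emitted vocabulary maps exercise normalization.
#'
#' @param config a [report_gen_config()] object
#' @param out_dir optional directory; when given, all tables and sidecars are
#'   written there via [write_faers_tables()]
#' @return an object of class `faers_sim`: a list with elements `tables`
#'   (data.tables `demo`, `drug`, `indi`, `reac`), `maps` (raw-to-canonical
#'   vocabulary maps for drugs, indications, reactions), `lexicon` (a
#'   [cohort_lexicon()]), `truth` (class `planted_truth`) and `config`
#' @export
generate_case_reports <- function(config, out_dir = NULL) {
  validate_report_gen_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)
  voc <- sim_vocabulary(cfg)
  pp <- planted_probs(cfg)
  n <- cfg$n_cases
  k <- cfg$n_true_comorbid

  case_id <- sprintf("case%07d", seq_len(n))

  # --- planted structure ----------------------------------------------------
  seed_present <- stats::runif(n) < cfg$seed_disease_prevalence
  probs <- ifelse(seed_present, pp$q, pp$r_off)
  com <- if (k > 0L) {
    matrix(stats::runif(n * k), n, k) < probs   # recycles probs down columns
  } else {
    matrix(FALSE, n, 0L)
  }
  n_special <- as.integer(seed_present) + rowSums(com)

  # --- indications ----------------------------------------------------------
  lam_base <- disease_count_rate(cfg)
  K <- sample_disease_counts(n, cfg, lam_base)
  n_bg <- pmax(K - n_special, 0L)
  w_dis <- zipf_weights(length(voc$bg_diseases), cfg$zipf_exponent)
  bg_draw <- sample_background(n_bg, length(voc$bg_diseases), w_dis)

  com_idx <- which(com, arr.ind = TRUE)
  indi <- data.table::data.table(
    case = c(which(seed_present),
             com_idx[, 1L],
             rep.int(seq_len(n), vapply(bg_draw, length, 0L))),
    term = c(rep(voc$seed, sum(seed_present)),
             voc$comorbids[com_idx[, 2L]],
             voc$bg_diseases[unlist(bg_draw, use.names = FALSE)])
  )

  # --- drugs ----------------------------------------------------------------
  lambda_drug <- ztp_rate(cfg$mean_drugs_per_case)
  Kd <- rztpois(n, lambda_drug)
  n_bg_drug <- Kd - as.integer(seed_present)  # one slot taken by the opioid
  w_drug <- zipf_weights(length(voc$bg_drugs), cfg$zipf_exponent)
  drug_draw <- sample_background(n_bg_drug, length(voc$bg_drugs), w_drug)
  opioid_pick <- sample.int(length(voc$opioids), sum(seed_present),
                            replace = TRUE)
  drug <- data.table::data.table(
    case = c(which(seed_present),
             rep.int(seq_len(n), vapply(drug_draw, length, 0L))),
    term = c(voc$opioids[opioid_pick],
             voc$bg_drugs[unlist(drug_draw, use.names = FALSE)])
  )

  # --- reactions ------------------------------------------------------------
  lambda_reac <- ztp_rate(cfg$mean_reactions_per_case)
  Kr <- rztpois(n, lambda_reac)
  n_bg_reac <- Kr - as.integer(seed_present)
  w_reac <- zipf_weights(length(voc$bg_reactions), cfg$zipf_exponent)
  reac_draw <- sample_background(n_bg_reac, length(voc$bg_reactions), w_reac)
  disorder_pick <- sample.int(length(voc$disorders), sum(seed_present),
                              replace = TRUE)
  reac <- data.table::data.table(
    case = c(which(seed_present),
             rep.int(seq_len(n), vapply(reac_draw, length, 0L))),
    term = c(voc$disorders[disorder_pick],
             voc$bg_reactions[unlist(reac_draw, use.names = FALSE)])
  )

  # --- demographics ---------------------------------------------------------
  age_group <- sample(c("Adult", "Senior", "Junior", "Unknown"), n,
                      replace = TRUE, prob = c(0.60, 0.25, 0.14, 0.01))
  sex <- sample(c("Female", "Male", "Unknown"), n,
                replace = TRUE, prob = c(0.54, 0.45, 0.01))
  quarter <- sample(paste0(rep(2019:2020, each = 4), "Q", 1:4), n,
                    replace = TRUE)

  # --- versions and stale duplicates ---------------------------------------
  dup <- stats::runif(n) < cfg$duplicate_fraction
  latest_version <- ifelse(dup, 2L, 1L)

  demo <- data.table::data.table(
    case_id = case_id, version = latest_version,
    age_group = age_group, sex = sex, quarter = quarter
  )
  drug_tab <- data.table::data.table(
    case_id = case_id[drug$case], version = latest_version[drug$case],
    drug_raw = toupper(drug$term)
  )
  indi_tab <- data.table::data.table(
    case_id = case_id[indi$case], version = latest_version[indi$case],
    indication_raw = toupper(indi$term)
  )
  reac_tab <- data.table::data.table(
    case_id = case_id[reac$case], version = latest_version[reac$case],
    reaction_raw = toupper(reac$term)
  )

  if (any(dup)) {
    dup_ids <- case_id[dup]
    demo_stale <- demo[demo$case_id %in% dup_ids]
    demo_stale$version <- 1L
    drug_stale <- drug_tab[drug_tab$case_id %in% dup_ids]
    drug_stale$version <- 1L
    indi_stale <- indi_tab[indi_tab$case_id %in% dup_ids]
    indi_stale$version <- 1L
    # the stale version drops that case's last reaction row (a detectable
    # difference for dedup tests); cases with one reaction get none
    reac_stale <- reac_tab[reac_tab$case_id %in% dup_ids]
    keep <- rev(!duplicated(rev(reac_stale$case_id)))  # last row per case
    reac_stale <- reac_stale[!keep]
    reac_stale$version <- 1L
    demo <- rbind(demo, demo_stale)
    drug_tab <- rbind(drug_tab, drug_stale)
    indi_tab <- rbind(indi_tab, indi_stale)
    reac_tab <- rbind(reac_tab, reac_stale)
  }
  data.table::setorder(demo, case_id, version)
  data.table::setorder(drug_tab, case_id, version, drug_raw)
  data.table::setorder(indi_tab, case_id, version, indication_raw)
  data.table::setorder(reac_tab, case_id, version, reaction_raw)

  # --- vocabulary maps and lexicon -----------------------------------------
  all_dis <- c(voc$seed, voc$comorbids, voc$bg_diseases)
  all_drug <- c(voc$opioids, voc$bg_drugs)
  all_reac <- c(voc$disorders, voc$bg_reactions)
  maps <- list(
    drug = stats::setNames(all_drug, toupper(all_drug)),
    indication = stats::setNames(all_dis, toupper(all_dis)),
    reaction = stats::setNames(all_reac, toupper(all_reac))
  )
  lexicon <- cohort_lexicon(opioid_drugs = voc$opioids,
                            disorder_terms = voc$disorders,
                            oud_label = .oud_label)

  # --- planted truth --------------------------------------------------------
  e_bg <- sum(n_bg) / n  # realized mean background budget
  marginals <- c(
    stats::setNames(cfg$seed_disease_prevalence, voc$seed),
    stats::setNames(rep(cfg$comorbid_marginal, k), voc$comorbids),
    stats::setNames(pmin(e_bg * w_dis, 0.999), voc$bg_diseases)
  )
  truth <- structure(list(
    seed_disease = voc$seed,
    true_comorbids = voc$comorbids,
    planted_lift = cfg$planted_lift,
    marginals = marginals,
    conditional_prob = pp$q,
    off_seed_prob = pp$r_off,
    seed_case_ids = case_id[seed_present],
    oud_label = .oud_label
  ), class = "planted_truth")

  sim <- structure(list(
    tables = list(demo = demo, drug = drug_tab, indi = indi_tab,
                  reac = reac_tab),
    maps = maps,
    lexicon = lexicon,
    truth = truth,
    config = cfg
  ), class = "faers_sim")

  if (!is.null(out_dir)) write_faers_tables(sim, out_dir)
  sim
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("Synthetic FAERS-like case reports\n")
  cat("  cases:              ", x$config$n_cases, "\n")
  cat("  seed disease:       ", x$truth$seed_disease,
      sprintf(" (prevalence %.3g)", x$config$seed_disease_prevalence), "\n")
  cat("  planted comorbids:  ", length(x$truth$true_comorbids),
      sprintf(" (lift %.3g)", x$truth$planted_lift), "\n")
  cat("  table rows:          demo", nrow(x$tables$demo),
      "drug", nrow(x$tables$drug), "indi", nrow(x$tables$indi),
      "reac", nrow(x$tables$reac), "\n")
  invisible(x)
}

#' Write the synthetic tables and sidecars to a directory
#'
#' Emits the four FAERS-like delimited tables (`DEMO.txt`, `DRUG.txt`,
#' `INDI.txt`, `REAC.txt`; delimiter from the generator configuration,
#' default `"$"`), the raw-to-canonical vocabulary maps as two-column TSVs,
#' the cohort lexicon files (one term per line), the planted gold-standard
#' comorbidity list, and a machine-readable `truth.json` sidecar.
#'
#' @param sim a `faers_sim` object from [generate_case_reports()]
#' @param dir output directory, created if needed
#' @return `dir`, invisibly
#' @export
write_faers_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  delim <- sim$config$delim
  tabs <- sim$tables
  data.table::fwrite(tabs$demo, file.path(dir, "DEMO.txt"), sep = delim)
  data.table::fwrite(tabs$drug, file.path(dir, "DRUG.txt"), sep = delim)
  data.table::fwrite(tabs$indi, file.path(dir, "INDI.txt"), sep = delim)
  data.table::fwrite(tabs$reac, file.path(dir, "REAC.txt"), sep = delim)
  for (nm in names(sim$maps)) {
    m <- sim$maps[[nm]]
    data.table::fwrite(
      data.table::data.table(raw = names(m), canonical = unname(m)),
      file.path(dir, paste0("map_", nm, ".tsv")), sep = "\t"
    )
  }
  writeLines(sim$lexicon$opioid_drugs, file.path(dir, "opioid_drugs.txt"))
  writeLines(sim$lexicon$disorder_terms, file.path(dir, "disorder_terms.txt"))
  writeLines(sim$truth$true_comorbids,
             file.path(dir, "gold_comorbidities.txt"))
  truth <- sim$truth
  data.table::fwrite(
    data.table::data.table(
      term = names(truth$marginals),
      marginal = unname(truth$marginals),
      is_seed = names(truth$marginals) == truth$seed_disease,
      is_comorbid = names(truth$marginals) %in% truth$true_comorbids
    ),
    file.path(dir, "planted_truth.tsv"), sep = "\t"
  )
  jsonlite::write_json(
    list(seed_disease = truth$seed_disease,
         true_comorbids = truth$true_comorbids,
         planted_lift = truth$planted_lift,
         conditional_prob = truth$conditional_prob,
         off_seed_prob = truth$off_seed_prob,
         oud_label = truth$oud_label,
         n_seed_cases = length(truth$seed_case_ids)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Empirical lift of a disease pair in a transaction collection
#'
#' `support(a, b) / (support(a) * support(b))` with supports taken as exact
#' transaction fractions. Useful for checking planted co-occurrence strength.
#'
#' @param transactions a list of character vectors (one itemset per case)
#' @param a,b disease terms
#' @return the empirical lift (possibly `NaN` when a marginal support is 0)
#' @export
empirical_lift <- function(transactions, a, b) {
  n <- length(transactions)
  has_a <- vapply(transactions, function(t) a %in% t, logical(1))
  has_b <- vapply(transactions, function(t) b %in% t, logical(1))
  (sum(has_a & has_b) / n) / ((sum(has_a) / n) * (sum(has_b) / n))
}
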