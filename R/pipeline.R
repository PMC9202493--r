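# Stage orchestration: runs the discovery pipeline (simulate -> preprocess
# -> mine -> network -> rank -> evaluate) and the case-control arm from one
# configuration, with deterministic seeding and a run manifest that records
# the count funnel at every filtering step.

#' Pipeline configuration
#'
#' A single configuration object shared by all stages. Artifacts are written
#' under `out_dir` in per-stage subdirectories; later stages read the
#' artifacts of earlier ones, so stages can be run one at a time.
#'
#' @param out_dir output directory for all stage artifacts
#' @param rng_seed integer seed driving every stochastic stage
#' @param report_config a [report_gen_config()] for the simulate stage
#' @param mining a [mining_params()]
#' @param rwr an [rwr_params()]
#' @param cohort_spec optional [cohort_gen_spec()] for the case-control arm
#' @param gold_path optional path to a one-term-per-line gold-standard list;
#'   defaults to the planted truth written by the simulate stage
#' @param oud_label canonical OUD term used as ranking seed
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            rng_seed = 1L,
                            report_config = NULL,
                            mining = mining_params(),
                            rwr = rwr_params(),
                            cohort_spec = NULL,
                            gold_path = NULL,
                            oud_label = "opioid use disorder") {
  structure(list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 report_config = report_config, mining = mining,
                 rwr = rwr, cohort_spec = cohort_spec,
                 gold_path = gold_path, oud_label = oud_label),
            class = "pipeline_config")
}

.stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.require_artifact <- function(path, stage_needed) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", path, "': run the '", stage_needed,
         "' stage first")
  }
  path
}

config_fingerprint <- function(config) {
  # fingerprint the scientific parameters, not artifact locations
  keep <- setdiff(names(config), c("out_dir", "gold_path"))
  serializable <- lapply(config[keep], function(x) {
    if (is.list(x)) unclass(x) else x
  })
  string_fingerprint(jsonlite::toJSON(serializable, auto_unbox = TRUE,
                                      digits = 12, null = "null",
                                      force = TRUE))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic FAERS-like tables), `preprocess` (dedup,
#' normalize, flag, transactions), `mine` (frequent itemsets and rules),
#' `network` (clique-expansion DCN), `rank` (RWR from the OUD seed),
#' `evaluate` (decile report against the gold list), `casecontrol`
#' (stratified cohort simulation + CMH), or `all` (every discovery stage in
#' order, plus `casecontrol` when a cohort spec is configured). Each stage
#' writes its artifacts under `out_dir/<stage>/` and contributes its counts
#' to the run manifest (`manifest.json`), which records the configuration
#' fingerprint, the seed, and the in/out counts of every filtering step.
#'
#' @param name stage name (see above)
#' @param config a [pipeline_config()]
#' @return the manifest (a list), invisibly for `"all"`; individual stages
#'   return their primary in-memory artifact with the manifest attached as
#'   attribute `manifest`
#' @export
run_stage <- function(name = c("simulate", "preprocess", "mine", "network",
                               "rank", "evaluate", "casecontrol", "all"),
                      config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  if (name == "all") return(run_pipeline(config))

  manifest <- read_manifest(config)
  out <- switch(name,
    simulate = {
      cfg <- config$report_config
      if (is.null(cfg)) stop("config$report_config is required for simulate")
      sim <- generate_case_reports(cfg, out_dir = .stage_dir(config,
                                                             "simulate"))
      manifest$counts$cases_generated <- cfg$n_cases
      manifest$counts$raw_rows <- vapply(sim$tables, nrow, 0L)
      sim
    },
    preprocess = {
      sim_dir <- file.path(config$out_dir, "simulate")
      .require_artifact(file.path(sim_dir, "DEMO.txt"), "simulate")
      delim <- if (!is.null(config$report_config)) config$report_config$delim
               else "$"
      tabs <- read_faers_tables(sim_dir, delim = delim)
      tabs <- deduplicate_cases(tabs)
      dd <- attr(tabs, "dedup_counts")
      tabs <- normalize_terms(
        tabs,
        drug_map = read_vocabulary_map(file.path(sim_dir, "map_drug.tsv")),
        indication_map = read_vocabulary_map(file.path(sim_dir,
                                                       "map_indication.tsv")),
        reaction_map = read_vocabulary_map(file.path(sim_dir,
                                                     "map_reaction.tsv"))
      )
      cov <- attr(tabs, "coverage")
      lex <- read_cohort_lexicon(file.path(sim_dir, "opioid_drugs.txt"),
                                 file.path(sim_dir, "disorder_terms.txt"),
                                 oud_label = config$oud_label)
      cases <- build_case_reports(tabs)
      cases <- flag_oud_cases(cases, lex)
      tx <- build_transactions(cases)
      d <- .stage_dir(config, "preprocess")
      write_transactions(tx, file.path(d, "transactions.tsv"))
      report <- list(
        rows_before_dedup = as.list(dd$rows_before),
        rows_after_dedup = as.list(dd$rows_after),
        n_cases = dd$n_cases,
        coverage = cov,
        n_flagged = attr(cases, "n_flagged"),
        n_transactions = length(tx)
      )
      jsonlite::write_json(report, file.path(d, "run_report.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$counts$cases_deduped <- dd$n_cases
      manifest$counts$cases_flagged <- attr(cases, "n_flagged")
      manifest$counts$transactions <- length(tx)
      tx
    },
    mine = {
      tx_path <- .require_artifact(
        file.path(config$out_dir, "preprocess", "transactions.tsv"),
        "preprocess")
      tx <- read_transactions(tx_path)
      fi <- mine_frequent_itemsets(tx, config$mining)
      rules <- itemsets_to_rules(fi, config$mining)
      d <- .stage_dir(config, "mine")
      data.table::fwrite(as.data.frame(fi), file.path(d, "itemsets.tsv"),
                         sep = "\t")
      write_rules(rules, file.path(d, "rules.tsv"))
      manifest$counts$frequent_itemsets <- nrow(fi)
      manifest$counts$rules_ordered <- nrow(rules)
      manifest$counts$rules_unordered_pairs <- nrow(rules) / 2
      rules
    },
    network = {
      rules_path <- .require_artifact(
        file.path(config$out_dir, "mine", "rules.tsv"), "mine")
      rules <- read_rules(rules_path)
      net <- rules_to_network(rules)
      d <- .stage_dir(config, "network")
      write_edges(net, file.path(d, "edges.tsv"))
      s <- network_stats(net)
      manifest$counts$network_nodes <- s$node_count
      manifest$counts$network_edges <- s$edge_count
      manifest$counts$network_components <- length(s$component_sizes)
      net
    },
    rank = {
      edges_path <- .require_artifact(
        file.path(config$out_dir, "network", "edges.tsv"), "network")
      net <- read_edges(edges_path)
      res <- rwr(net, config$oud_label, config$rwr)
      ranked <- rank_diseases(res)
      d <- .stage_dir(config, "rank")
      gold <- .pipeline_gold(config)
      write_ranking(ranked, file.path(d, "ranking.tsv"), gold = gold)
      manifest$counts$rwr_iterations <- res$iterations
      manifest$counts$ranked_diseases <- nrow(ranked)
      ranked
    },
    evaluate = {
      rank_path <- .require_artifact(
        file.path(config$out_dir, "rank", "ranking.tsv"), "rank")
      ranked <- data.table::fread(rank_path, sep = "\t", data.table = FALSE)
      gold <- .pipeline_gold(config)
      rep <- decile_evaluation(ranked$disease, gold)
      d <- .stage_dir(config, "evaluate")
      data.table::fwrite(rep$bins, file.path(d, "deciles.tsv"), sep = "\t")
      jsonlite::write_json(
        list(first_decile_precision_pct = rep$first_decile_precision_pct,
             first_decile_hit_rate = rep$first_decile_hit_rate,
             n_ranked = rep$n_ranked, n_gold = rep$n_gold,
             gold_in_ranking = rep$gold_in_ranking),
        file.path(d, "decile_report.json"), auto_unbox = TRUE, digits = NA)
      manifest$counts$gold_in_first_decile <- rep$bins$true_positives[1L]
      rep
    },
    casecontrol = {
      spec <- config$cohort_spec
      if (is.null(spec)) stop("config$cohort_spec is required for casecontrol")
      tab <- generate_stratified_cohort(spec)
      resolved <- masked_input_handling(tab, policy = "midpoint",
                                        mask_below = spec$mask_below)
      res <- cmh_or(resolved)
      d <- .stage_dir(config, "casecontrol")
      write_stratified_table(tab, file.path(d, "strata.tsv"),
                             mask_below = spec$mask_below)
      jsonlite::write_json(
        list(aor = res$aor, ci_low = res$ci_low, ci_high = res$ci_high,
             p_value = res$p_value, strata_used = res$strata_used,
             mask_policy = attr(resolved, "mask_policy")$policy),
        file.path(d, "cmh.json"), auto_unbox = TRUE, digits = NA)
      manifest$counts$casecontrol_strata <- res$strata_used
      res
    }
  )
  manifest$stages <- unique(c(manifest$stages, name))
  write_manifest(manifest, config)
  attr(out, "manifest") <- manifest
  out
}

.pipeline_gold <- function(config) {
  path <- config$gold_path %||%
    file.path(config$out_dir, "simulate", "gold_comorbidities.txt")
  .require_artifact(path, "simulate")
  readLines(path)
}

read_manifest <- function(config) {
  path <- file.path(config$out_dir, "manifest.json")
  if (file.exists(path)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    m$counts <- as.list(m$counts)
    m
  } else {
    list(package = "comorbnet",
         version = as.character(utils::packageVersion("comorbnet")),
         config_fingerprint = config_fingerprint(config),
         rng_seed = config$rng_seed,
         stages = character(0),
         counts = list())
  }
}

write_manifest <- function(manifest, config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run the whole discovery pipeline
#'
#' Executes `simulate`, `preprocess`, `mine`, `network`, `rank`, `evaluate`
#' in order (and `casecontrol` when a cohort spec is configured) and returns
#' the final manifest. Identical configurations and seeds produce
#' byte-identical artifacts and manifests.
#'
#' @param config a [pipeline_config()]
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "preprocess", "mine", "network", "rank", "evaluate")
  if (!is.null(config$cohort_spec)) stages <- c(stages, "casecontrol")
  for (s in stages) run_stage(s, config)
  invisible(read_manifest(config))
}
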