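# Configuration and one-command orchestration: ingest -> features -> stats ->
# classification -> clinical correlations, with structured logging and a
# serialized config copy in every output directory.

#' Build and validate a run configuration
#'
#' @param inputs Named list of input paths: `transcripts`, `norms`,
#'   `vectors`, `taxonomy_edges`, `taxonomy_mapping`, `participants`,
#'   `clinical`.
#' @param features Feature options: `metric`, `var_type`, `adjacency`,
#'   `log_base`, `sense`.
#' @param stats Stats options: `fence_k`, `alpha`, `covariate`.
#' @param classifier Classifier options: `n_folds`, `n_iterations`, `seed`,
#'   `paper_mode`.
#' @param outdir Output directory.
#' @return A validated `plt_run_config` list.
#' @export
run_config <- function(inputs, outdir,
                       features = list(), stats = list(), classifier = list()) {
  cfg <- list(
    inputs = inputs,
    outdir = outdir,
    features = modifyList(list(metric = "cosine", var_type = "sample",
                               adjacency = "concat", log_base = exp(1),
                               sense = "min"), features),
    stats = modifyList(list(fence_k = 3, alpha = 0.05, covariate = "education"),
                       stats),
    classifier = modifyList(list(n_folds = 5, n_iterations = 1000, seed = 1,
                                 paper_mode = FALSE), classifier)
  )
  required <- c("transcripts", "norms", "vectors", "taxonomy_edges",
                "taxonomy_mapping", "participants", "clinical")
  missing <- setdiff(required, names(cfg$inputs))
  if (length(missing) > 0L) {
    abort_schema(paste0("config missing input path(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in required) {
    if (!file.exists(cfg$inputs[[nm]])) {
      abort_validation(paste0("input file for '", nm, "' not found: ", cfg$inputs[[nm]]))
    }
  }
  stopifnot(cfg$stats$fence_k > 0, cfg$stats$alpha > 0, cfg$stats$alpha < 1,
            cfg$classifier$n_folds >= 2, cfg$classifier$n_iterations >= 1)
  class(cfg) <- "plt_run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments (`inputs:`, `features:`,
#' `stats:`, `classifier:`, `outdir:`); relative input paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param outdir Optional override of the configured output directory.
#' @return A validated `plt_run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  inputs <- lapply(raw$inputs, function(p) {
    if (file.exists(p)) p else file.path(base, p)
  })
  run_config(inputs, outdir %||% raw$outdir %||% file.path(base, "plt-output"),
             features = raw$features %||% list(),
             stats = raw$stats %||% list(),
             classifier = raw$classifier %||% list())
}

log_stage <- function(log, stage, key, value) {
  line <- sprintf("[%s] %s = %s", stage, key, paste(value, collapse = ","))
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> feature extraction -> group statistics -> subject-level
#' classification (PD-HC, bvFTD-HC, PD-bvFTD) -> clinical correlations for
#' significant features, writing the feature matrix, per-concept audit table,
#' relevance table, group-comparison tables, classifier reports, correlation
#' table, a structured run log with conservation counts at every filtering
#' stage, and a serialized copy of the configuration.
#'
#' @param config A `plt_run_config` (or YAML path).
#' @param tagger Optional tagger for transcripts without pre-tagged tokens.
#' @return Invisibly, a list with every computed object and `outdir`.
#' @export
run_pipeline <- function(config, tagger = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "plt_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character()

  # ingest
  records <- parse_responses(config$inputs$transcripts)
  log <- log_stage(log, "ingest", "records_in", nrow(records))
  filtered <- filter_valid(records)
  excl <- exclusion_counts(filtered)
  for (nm in names(excl)) log <- log_stage(log, "ingest", paste0("excluded_", nm), excl[[nm]])
  log <- log_stage(log, "ingest", "records_retained", nrow(filtered))
  filtered <- extract_content_tokens(filtered, tagger = tagger)

  # resources
  norms <- load_norms(config$inputs$norms)
  lexicon <- load_vectors(config$inputs$vectors)
  taxonomy <- load_taxonomy(config$inputs$taxonomy_edges, config$inputs$taxonomy_mapping)
  participants <- readr::read_csv(config$inputs$participants, show_col_types = FALSE,
                                  progress = FALSE)
  clinical <- readr::read_csv(config$inputs$clinical, show_col_types = FALSE,
                              progress = FALSE)

  lemmas <- unlist(lapply(filtered$tokens, function(tk) tk$lemma))
  oov <- mean(is.na(lookup_vectors(lexicon, lemmas)[, 1]))
  log <- log_stage(log, "features", "oov_rate_vectors", sprintf("%.4f", oov))

  # features
  fo <- config$features
  cf <- concept_features(filtered, norms, lexicon, taxonomy,
                         metric = fo$metric, var_type = fo$var_type,
                         adjacency = fo$adjacency, log_base = fo$log_base,
                         sense = fo$sense)
  fm <- aggregate_participants(
    cf, participants[, intersect(names(participants), c("participant_id", "education"))]
  )
  rel <- relevance_distinctiveness(production_counts(filtered), log_base = fo$log_base)
  log <- log_stage(log, "features", "participants", nrow(fm))

  # group statistics
  comparisons <- compare_all_features(fm, covariate = config$stats$covariate,
                                      k = config$stats$fence_k,
                                      alpha = config$stats$alpha)
  log <- log_stage(log, "stats", "outliers_removed_total", sum(comparisons$n_removed))
  sig <- comparisons$feature[comparisons$significant]
  log <- log_stage(log, "stats", "significant_features",
                   if (length(sig)) paste(sig, collapse = ";") else "none")

  # classification, three pairings
  pairs <- list(c("PD", "HC"), c("bvFTD", "HC"), c("PD", "bvFTD"))
  reports <- lapply(pairs, function(pr) {
    rep <- crossval_classify(fm, pr, n_folds = config$classifier$n_folds,
                             n_iterations = config$classifier$n_iterations,
                             seed = config$classifier$seed,
                             paper_mode = config$classifier$paper_mode)
    log <<- log_stage(log, "classify", rep$pair,
                      sprintf("auc %.3f sd %.3f", rep$auc_mean, rep$auc_sd))
    rep
  })
  names(reports) <- vapply(reports, `[[`, character(1), "pair")

  # clinical correlations for flagged features
  score_cols <- setdiff(names(clinical), "participant_id")
  correlations <- if (length(sig) > 0L) {
    correlate_tandems(fm, clinical, sig, score_cols, alpha = config$stats$alpha)
  } else tibble::tibble()

  # outputs
  out <- config$outdir
  readr::write_csv(fm, file.path(out, "feature_matrix.csv"))
  readr::write_csv(cf, file.path(out, "concept_features.csv"))
  readr::write_csv(rel, file.path(out, "relevance_table.csv"))
  readr::write_csv(tidyr::unnest(comparisons, "posthoc", names_sep = "_"),
                   file.path(out, "group_comparisons.csv"))
  if (nrow(correlations) > 0L) {
    readr::write_csv(correlations, file.path(out, "clinical_correlations.csv"))
  }
  for (rep in reports) {
    jsonlite::write_json(
      list(pair = rep$pair, auc_mean = rep$auc_mean, auc_sd = rep$auc_sd,
           auc = rep$auc, seed = rep$seed, n_folds = rep$n_folds,
           n_iterations = rep$n_iterations),
      file.path(out, paste0("classifier_", gsub("-vs-", "_", rep$pair), ".json")),
      auto_unbox = TRUE, digits = NA)
    readr::write_csv(rep$scores,
                     file.path(out, paste0("scores_", gsub("-vs-", "_", rep$pair), ".csv")))
  }
  cfg_out <- config
  cfg_out$features$log_base <- unname(cfg_out$features$log_base)
  jsonlite::write_json(unclass(cfg_out), file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(out, "run_log.txt"))

  invisible(list(feature_matrix = fm, concept_features = cf, relevance = rel,
                 comparisons = comparisons, classifiers = reports,
                 correlations = correlations, log = log, outdir = out))
}
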