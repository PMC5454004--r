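# End-to-end workflow orchestration: profile -> combine -> select ->
# cross-validate -> report, with a reproducible run record (config, seed,
# schema version, input hashes) carried into every output. The CLI script
# in inst/cli/fxscreen.R is a thin wrapper over these functions.

#' Run configuration for the analysis stage
#'
#' @param model algorithm name or alias (see [model_spec()]).
#' @param hyperparameters named list of overrides.
#' @param k number of CV folds.
#' @param seed run seed.
#' @param select feature selection inside training folds; defaults to TRUE
#'   for the `"optimized"` subset and FALSE otherwise.
#' @param subset profile subset: `"full"`, `"optimized"`,
#'   `"linguistic_only"`, `"cognitive_only"`, `"segment_1"` ..
#'   `"segment_5"`.
#' @param schema feature schema (records its version into outputs).
#' @return `fx_run_config` list.
#' @export
run_config <- function(model = "random_forest", hyperparameters = list(),
                       k = 10L, seed = 1L, select = NULL, subset = "full",
                       schema = default_feature_schema()) {
  spec <- model_spec(model, hyperparameters, seed = seed)
  valid_subsets <- c("full", "optimized", "linguistic_only", "cognitive_only",
                     paste0("segment_", seq_len(schema$k)))
  if (!subset %in% valid_subsets) {
    stop("subset must be one of: ", paste(valid_subsets, collapse = ", "))
  }
  if (is.null(select)) select <- identical(subset, "optimized")
  structure(list(spec = spec, k = as.integer(k), seed = as.integer(seed),
                 select = select, subset = subset,
                 schema_version = schema$version, schema = schema),
            class = "fx_run_config")
}

config_hash <- function(config) {
  flat <- list(algorithm = config$spec$algorithm,
               hyperparameters = config$spec$hyperparameters,
               k = config$k, seed = config$seed, select = config$select,
               subset = config$subset, schema_version = config$schema_version)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Profile a corpus and write the feature matrix
#'
#' @param manifest manifest CSV path or data frame.
#' @param out optional output CSV path (participant_id + 88 feature
#'   columns).
#' @param ... passed to [profile_corpus()].
#' @return the feature matrix data frame (invisibly when `out` is given).
#'   Per-file utterance counts are logged via `message()`; any unreadable
#'   transcript leaves a `"failures"` attribute (the CLI converts this into
#'   a nonzero exit status).
#' @export
run_profile <- function(manifest, out = NULL, ...) {
  profiles <- profile_corpus(manifest, ...)
  for (i in seq_len(nrow(profiles))) {
    message(sprintf("profiled %s: %d utterances, %d words",
                    profiles$participant_id[i], profiles$n_utterances[i],
                    profiles$n_words[i]))
  }
  if (!nrow(profiles)) message("empty manifest: no transcripts profiled")
  if (is.null(out)) return(profiles)
  write.csv(profiles, out, row.names = FALSE)
  invisible(profiles)
}

#' Generate a cohort from a spec file
#'
#' @param spec an `fx_cohort_spec`, or the path of a JSON/YAML spec file.
#' @param out_dir output corpus directory.
#' @return (invisibly) the [generate_cohort()] result.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  validate_cohort_spec(spec)
  generate_cohort(spec, dir = out_dir)
}

#' Rank all features of a labelled profile matrix
#'
#' Whole-dataset information-gain ranking (for reporting; classifier
#' evaluation performs selection inside training folds instead).
#'
#' @param profiles assembled profile data frame or CSV path (must contain a
#'   `label` column, or supply `labels`).
#' @param labels optional labels data frame / CSV path.
#' @param out optional gains CSV path.
#' @return `fx_gains` data frame.
#' @export
run_select <- function(profiles, labels = NULL, out = NULL) {
  if (is.character(profiles)) profiles <- read.csv(profiles,
                                                   stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- read.csv(labels,
                                                 stringsAsFactors = FALSE)
    profiles$label <- labels$group[match(profiles$participant_id,
                                         labels$participant_id)]
  }
  if (!"label" %in% names(profiles) || anyNA(profiles$label)) {
    stop("profiles must carry a complete label column")
  }
  x <- profiles[setdiff(names(profiles), c("participant_id", "label"))]
  gains <- rank_features(x, profiles$label)
  if (!is.null(out)) write.csv(as.data.frame(gains), out, row.names = FALSE)
  gains
}

#' Run the selection + cross-validation analysis stage
#'
#' Joins the linguistic matrix, cognitive table and labels, restricts to
#' the configured profile subset, cross-validates the configured
#' classifier, and (optionally) writes `metrics.json`, `gains.csv`,
#' `roc.tsv` and `folds.csv`, all carrying the seed and a config hash so a
#' run is reproducible from its stored configuration.
#'
#' @param profiles linguistic feature matrix (data frame or CSV path from
#'   [run_profile()]).
#' @param cognitive cognitive table (data frame or CSV path).
#' @param labels labels (data frame or CSV path with `participant_id`,
#'   `group`).
#' @param config an [run_config()].
#' @param out_dir optional output directory.
#' @return the `fxs_cv` result, with the config attached as attribute
#'   `"config"`.
#' @export
run_analysis <- function(profiles, cognitive, labels,
                         config = run_config(), out_dir = NULL) {
  if (is.character(profiles)) profiles <- read.csv(profiles,
                                                   stringsAsFactors = FALSE)
  if (is.character(labels)) labels <- read.csv(labels,
                                               stringsAsFactors = FALSE)
  cognitive <- load_cognitive_table(cognitive)
  assembled <- assemble_profiles(profiles, cognitive, labels)
  x <- profile_subset(assembled, config$subset, config$schema)
  cv <- cross_validate(x, assembled$label, spec = config$spec, k = config$k,
                       select = config$select, seed = config$seed)
  attr(cv, "config") <- config
  hash <- config_hash(config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      config = list(algorithm = config$spec$algorithm,
                    hyperparameters = config$spec$hyperparameters,
                    k = config$k, seed = config$seed,
                    select = config$select, subset = config$subset,
                    schema_version = config$schema_version,
                    config_hash = hash),
      n = length(cv$folds),
      confusion = cv$confusion[c("tp", "tn", "fp", "fn")],
      metrics = as.list(cv$metrics))
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    gains <- rank_features(x, assembled$label)
    write.csv(as.data.frame(gains), file.path(out_dir, "gains.csv"),
              row.names = FALSE)
    roc <- cv$roc$points
    write.table(roc, file.path(out_dir, "roc.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.csv(data.frame(participant_id = assembled$participant_id,
                         fold = cv$folds, label = assembled$label,
                         oof_score = cv$scores,
                         prediction = cv$predictions),
              file.path(out_dir, "folds.csv"), row.names = FALSE)
  }
  message(sprintf("run %s/%s (seed %d, hash %s): F1 %.3f AUC %.3f MCC %.3f",
                  config$spec$algorithm, config$subset, config$seed, hash,
                  cv$metrics["f1"], cv$metrics["auc"], cv$metrics["mcc"]))
  cv
}
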