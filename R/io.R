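## Trial-level CSV schema, second-level loading, and the end-to-end pipeline.

TRIAL_COLUMNS <- c("experiment", "participant", "session", "block",
                   "trial_index", "triplet_id", "loop_type", "common_category",
                   "trial_kind", "cue_role", "target_role", "tested_at_T1",
                   "response")

TRIAL_ENUMS <- list(
  session = c("T1", "T2"),
  loop_type = c("closed", "open"),
  common_category = c(ROLES, NA),
  trial_kind = c("direct", "inference"),
  cue_role = ROLES,
  target_role = ROLES,
  response = c("correct", "incorrect", "missing")
)

#' Write trial-level records to CSV
#'
#' Comma-separated, UTF-8, header row, lower-case enumerations; one row per
#' retrieval trial in the package's canonical column order.
#'
#' @param trials Trial-level data.frame (see [read_trials()] for the schema).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trial data lack columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read trial-level records from CSV
#'
#' Validates the header and every enumerated column (errors name the first
#' offending row), and recodes `missing` responses as `incorrect` - missing
#' responses are counted as incorrect trials in both the accuracy and
#' dependency analyses - reporting the number of recodes via `message()`.
#'
#' @param path CSV file with columns `experiment, participant, session,
#'   block, trial_index, triplet_id, loop_type, common_category, trial_kind,
#'   cue_role, target_role, tested_at_T1, response`.
#' @return data.frame of validated trial records, `response` in
#'   `{"correct", "incorrect"}`.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  ## an all-NA common_category column (purely closed-loop data) parses as
  ## logical; keep it character like the rest of the pipeline
  if ("common_category" %in% names(tr))
    tr$common_category <- as.character(tr$common_category)
  unknown <- setdiff(names(tr), TRIAL_COLUMNS)
  if (length(unknown))
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in names(TRIAL_ENUMS)) {
    ok <- tr[[col]] %in% TRIAL_ENUMS[[col]] |
      (any(is.na(TRIAL_ENUMS[[col]])) & is.na(tr[[col]]))
    if (!all(ok))
      stop("invalid value '", tr[[col]][which(!ok)[1]], "' in column '", col,
           "' at row ", which(!ok)[1])
  }
  tr$tested_at_T1 <- as.logical(tr$tested_at_T1)
  n_missing <- sum(tr$response == "missing")
  if (n_missing > 0) {
    tr$response[tr$response == "missing"] <- "incorrect"
    message(n_missing, " missing response(s) recoded as incorrect")
  }
  tr
}

#' Read second-level (per-participant) summary data
#'
#' Loads deposited second-level records - per-participant means such as
#' dependency and accuracy at each session - under an explicit column
#' mapping, since deposited files do not follow this package's schema. The
#' result feeds group contrasts directly (e.g. paired Bayes factors on
#' `dependency_T1` versus `dependency_T2`).
#'
#' @param path CSV file.
#' @param schema_map Named character vector mapping canonical names (the
#'   names) to the file's column names (the values), e.g.
#'   `c(participant = "subj", dependency_T1 = "dep_imm")`.
#' @param required Canonical names that must be mapped and present.
#' @return data.frame with the canonical column names.
#' @export
read_second_level <- function(path, schema_map,
                              required = c("participant", "dependency_T1",
                                           "dependency_T2")) {
  unmapped <- setdiff(required, names(schema_map))
  if (length(unmapped))
    stop("schema_map does not map required column(s): ",
         paste(unmapped, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(unname(schema_map), names(df))
  if (length(absent))
    stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
  out <- df[unname(schema_map)]
  names(out) <- names(schema_map)
  out
}

#' Run the full simulate-analyze-model pipeline
#'
#' Chains every stage on one configuration: simulate a cohort, write the
#' trial-level CSV, fit the retrieval-dependency model at both sessions,
#' run the independent-forgetting model (when an immediate test exists),
#' apply the inferential layer (dependency t tests per cell; paired Bayes
#' factors of observed T1 vs observed/simulated T2 closed-loop dependency),
#' and write the summary tables plus a reproducibility manifest.
#'
#' @param config A list (or path to a YAML file) with fields `experiment`
#'   (1-4), `loop` (for between-subjects designs), `params` (arguments to
#'   [gen_params()]), `seed`, `n_sims` (default 100) and `out_dir`.
#' @return Invisibly, a list with the cohort, fit, summaries, forgetting
#'   results and Bayes factors; files are written under `out_dir`.
#' @examples
#' \donttest{
#' cfg <- list(experiment = 2, loop = "closed", seed = 11, n_sims = 20,
#'             params = list(n_participants = 6), out_dir = tempdir())
#' rep <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$experiment))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_sims <- config$n_sims %||% 100L
  seed <- config$seed %||% 1L
  params <- do.call(gen_params, c(config$params %||% list(), list(seed = seed)))
  cfg <- experiment_config(config$experiment, config$loop %||% "closed")
  message("[simulate] cohort of ", params$n_participants,
          " participants (seed ", seed, ")")
  cohort <- simulate_cohort(params, cfg)
  write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
  message("[analyze] fitting retrieval dependency")
  fit <- retdep(cohort)
  utils::write.csv(fit$results, file.path(out_dir, "dependency.csv"),
                   row.names = FALSE)
  summ <- summary(fit)
  utils::write.csv(as.data.frame(summ), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  forgetting <- NULL
  bfs <- list()
  if (cfg$t1_test && any(fit$results$loop_type == "closed")) {
    message("[forgetting-model] ", n_sims, " simulations per participant")
    forgetting <- simulate.retdep(fit, nsim = n_sims,
                                  seed = derive_seed(seed, 999L))
    utils::write.csv(as.data.frame(forgetting),
                     file.path(out_dir, "forgetting_model.csv"),
                     row.names = FALSE)
    message("[stats] Bayes factors on closed-loop dependency")
    bfs$observed_t2_vs_t1 <- jzs_bayes_factor(
      forgetting$dependency_T2 - forgetting$dependency_T1,
      direction = "decrease")
    bfs$simulated_t2_vs_t1 <- jzs_bayes_factor(
      forgetting$simulated_T2 - forgetting$dependency_T1,
      direction = "decrease")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("loopdep")),
    r_version = R.version.string,
    seed = seed, n_sims = n_sims,
    experiment = cfg$experiment, loop = cfg$loop,
    params = unclass(params),
    trials_md5 = unname(tools::md5sum(file.path(out_dir, "trials.csv")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  message("[done] outputs in ", out_dir)
  invisible(list(cohort = cohort, fit = fit, summary = summ,
                 forgetting = forgetting, bayes_factors = bfs,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
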