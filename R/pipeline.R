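# End-to-end orchestration: simulate (or ingest) -> dose grids -> adherence
# measures -> PCA under candidate scalings -> stability-selected clusters ->
# single-measure surrogate tree, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' All protocol constants at their standard values: three candidate scaling
#' regimes, a 95% cumulative-variance component rule, k searched over 1-15
#' with 25 k-means initialisations, 1,000 bootstrap replicates with a 0.5
#' Jaccard dissolution threshold, 5-day minimum intermissions, CART
#' constraints (min_split 20, min_leaf 6, max_depth 2, 10 CV folds) and a
#' 70/15/15 train/validation/test split. Every value can be overridden.
#'
#' @param n_patients Cohort size for the synthetic generator (default 211).
#' @param seed Master seed; per-stage streams are derived from it.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(n_patients = 211L, seed = 20201L) {
  structure(list(
    cohort = list(n_patients = as.integer(n_patients)),
    input = NULL,  # set to list(events=, malfunctions=, followup=) paths
    scaling_methods = c("center_only", "unit_variance", "min_max"),
    unit_variance_denominator = "sd",
    variance_threshold = 0.95,
    k_max = 15L,
    k_override = NULL,
    n_init = 25L,
    n_bootstrap = 1000L,
    dissolution_threshold = 0.5,
    min_intermission = 5L,
    include_censored = TRUE,
    cart = list(min_split = 20L, min_leaf = 6L, max_depth = 2L,
                cv_folds = 10L),
    split_fractions = c(train = 0.70, validation = 0.15, test = 0.15),
    seed = as.integer(seed),
    outdir = NULL
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain list with the same fields).
#' @return The validated config, invisibly; stops with a descriptive error
#'   on the first violated constraint.
#' @export
validate_pipeline_config <- function(config) {
  assert_count(config$seed, "seed", 0L)
  assert_count(config$n_init, "n_init", 1L)
  assert_count(config$n_bootstrap, "n_bootstrap", 1L)
  assert_count(config$k_max, "k_max", 3L)
  assert_count(config$min_intermission, "min_intermission", 1L)
  assert_prob(config$variance_threshold, "variance_threshold")
  if (config$variance_threshold <= 0) {
    stop("`variance_threshold` must be in (0, 1]", call. = FALSE)
  }
  assert_prob(config$dissolution_threshold, "dissolution_threshold")
  if (!length(config$scaling_methods) ||
      !all(config$scaling_methods %in%
             c("center_only", "unit_variance", "min_max"))) {
    stop("unknown scaling method in `scaling_methods`", call. = FALSE)
  }
  if (abs(sum(config$split_fractions) - 1) > 1e-9) {
    stop("`split_fractions` must sum to 1", call. = FALSE)
  }
  do.call(cart_params, config$cart)  # validates CART constraints
  if (is.null(config$input) && is.null(config$cohort)) {
    stop("config needs either `input` paths or a `cohort` generator block",
         call. = FALSE)
  }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns the config; writing returns the
#'   path invisibly. A written-then-read config reproduces identical runs.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- default_pipeline_config()
  for (nm in names(raw)) config[[nm]] <- raw[[nm]]
  config$split_fractions <- unlist(config$split_fractions)
  config$scaling_methods <- as.character(unlist(config$scaling_methods))
  validate_pipeline_config(config)
  config
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  # yaml drops names on atomic vectors; store fractions as a map
  out$split_fractions <- as.list(out$split_fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Person-day accounting
#'
#' @param total Total person-days in the raw follow-up calendar.
#' @param missing Person-days removed as device-malfunction periods.
#' @return List with `total`, `missing`, `analyzed` (= total - missing) and
#'   `pct_missing` (nearest whole percent).
#' @export
person_day_accounting <- function(total, missing) {
  stopifnot(total >= 0, missing >= 0, missing <= total)
  list(total = total, missing = missing, analyzed = total - missing,
       pct_missing = round(100 * missing / total))
}

#' Descriptive cohort summary
#'
#' Reports the share of patients with at least one treatment intermission,
#' median time to (and duration of) the first intermission, person-day
#' accounting, and — when arm labels are supplied — the per-arm mean
#' percentage of doses taken.
#'
#' @param grids Named list of `dose_grid` objects.
#' @param profiles Adherence profiles for the same patients.
#' @param labels Optional label table with `patient_id` and `arm`.
#' @return List of summary quantities.
#' @export
summarize_cohort <- function(grids, profiles, labels = NULL) {
  total <- sum(vapply(grids, function(g) length(g$days), numeric(1)))
  analyzed <- sum(vapply(grids, function(g) g$n_observed_days, numeric(1)))
  acct <- person_day_accounting(total, total - analyzed)
  has_int <- profiles$n_intermissions > 0 |
    !is.na(profiles$first_intermission_day)
  out <- list(
    n_patients = nrow(profiles),
    person_days = acct,
    pct_with_intermission = round(100 * mean(has_int)),
    n_with_intermission = sum(has_int),
    median_first_intermission_day =
      stats::median(profiles$first_intermission_day, na.rm = TRUE),
    median_first_intermission_duration =
      stats::median(profiles$first_intermission_duration, na.rm = TRUE),
    mean_pct_doses_taken = mean(profiles$A)
  )
  if (!is.null(labels) && "arm" %in% names(labels)) {
    a <- profiles$A[match(labels$patient_id, profiles$patient_id)]
    out$arm_mean_pct_doses_taken <-
      vapply(split(a, labels$arm), mean, numeric(1), na.rm = TRUE)
  }
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full adherence-typology pipeline
#'
#' Executes every stage from input (synthetic generation or CSV ingestion)
#' to the surrogate tree's test-set confusion matrix, optionally writing all
#' tabular artifacts plus a JSON manifest (configuration, derived stage
#' seeds, artifact MD5 checksums) to `config$outdir`. Identical
#' configurations produce identical artifacts and checksums.
#'
#' @param config A `pipeline_config`; see [default_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with the cohort inputs, `grids`, `profiles`, `summary`,
#'   scaling `selection`, ordered `solution`, `split`, per-measure surrogate
#'   results, final `confusion` matrix, `test_accuracy` and the `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  validate_pipeline_config(config)
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$input)) {
    cohort <- run_stage("ingest", {
      for (p in unlist(config$input)) {
        if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
      }
      fu <- utils::read.csv(config$input$followup, stringsAsFactors = FALSE)
      fu$start_date <- as.Date(fu$start_date)
      fu$end_date <- as.Date(fu$end_date)
      list(events = parse_event_log(config$input$events),
           malfunctions = parse_malfunction_table(config$input$malfunctions),
           labels = NULL, followup = fu)
    })
    say("ingested %d events for %d patients", nrow(cohort$events),
        nrow(cohort$followup))
  } else {
    cohort <- run_stage("simulate", {
      args <- config$cohort
      args$seed <- seeds[["generator"]]
      generate_cohort(do.call(cohort_config, args))
    })
    say("simulated cohort: %d patients, %d events", nrow(cohort$followup),
        nrow(cohort$events))
  }

  # --- dose grids and measures ---------------------------------------------
  grids <- run_stage("dose_grids",
                     suppressWarnings(build_dose_grid(cohort$events,
                                                      cohort$malfunctions,
                                                      cohort$followup)))
  profiles <- run_stage("measures", {
    cohort_profiles(grids, min_intermission = config$min_intermission,
                    include_censored = config$include_censored)
  })
  m <- cohort_measure_matrix(profiles)
  summary <- summarize_cohort(grids, profiles, cohort$labels)
  say("profiles computed: n = %d, %d%% with >=1 intermission",
      nrow(profiles), summary$pct_with_intermission)

  # --- latent structure, clusters, stability -------------------------------
  selection <- run_stage("cluster_typology", {
    select_scaling(m, methods = config$scaling_methods,
                   variance_threshold = config$variance_threshold,
                   k_range = seq_len(min(config$k_max, nrow(m) - 1L)),
                   n_init = config$n_init,
                   n_bootstrap = config$n_bootstrap,
                   seed = seeds[["kmeans"]],
                   k_override = config$k_override,
                   dissolution_threshold = config$dissolution_threshold,
                   denominator = config$unit_variance_denominator)
  })
  best <- selection$per_method[[selection$best]]
  solution <- order_clusters(best$solution, profiles)
  say("scaling '%s' selected (mean Jaccard %.3f); k = %d clusters",
      selection$best, selection$mean_jaccard[[selection$best]], best$k)

  # --- surrogate tree -------------------------------------------------------
  split <- run_stage("split", {
    split_data(profiles$patient_id, config$split_fractions,
               seed = seeds[["split"]])
  })
  surrogate <- run_stage("surrogate_tree", {
    select_best_measure(profiles, solution$labels, split,
                        params = do.call(cart_params, config$cart),
                        seed = seeds[["cv"]])
  })
  eval_part <- if ("test" %in% names(split$fractions)) "test" else
    utils::tail(setdiff(names(split$fractions), "train"), 1)
  test_ids <- split[[eval_part]]
  test_idx <- match(test_ids, profiles$patient_id)
  best_tree <- surrogate$trees[[surrogate$best_measure]]
  confusion <- run_stage("evaluate", {
    evaluate(best_tree, profiles[[surrogate$best_measure]][test_idx],
             solution$labels[test_ids])
  })
  test_acc <- accuracy(confusion)
  say("best surrogate measure: %s; test accuracy %.1f%% (n = %d)",
      surrogate$best_measure, 100 * test_acc, length(test_ids))

  result <- list(config = config, seeds = seeds, cohort = cohort,
                 grids = grids, profiles = profiles, summary = summary,
                 selection = selection, solution = solution, split = split,
                 surrogate = surrogate, confusion = confusion,
                 test_accuracy = test_acc)
  if (!is.null(config$outdir)) {
    result$manifest <- run_stage("artifacts",
                                 write_pipeline_artifacts(result,
                                                          config$outdir))
  }
  invisible(result)
}

# Writes the seven tabular artifacts plus manifest.json; returns manifest.
write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  best <- result$selection$per_method[[result$selection$best]]

  paths <- c(
    profiles = "profiles.csv", pca_loadings = "pca_loadings.csv",
    wss_curve = "wss_curve.csv", stability = "stability.csv",
    clusters = "clusters.csv", measure_accuracy = "measure_accuracy.csv",
    confusion_matrix = "confusion_matrix.csv")
  paths <- stats::setNames(file.path(outdir, paths), names(paths))

  utils::write.csv(result$profiles, paths["profiles"], row.names = FALSE)

  tab <- pca_table(best$pca)
  utils::write.csv(cbind(measure = rownames(tab), tab),
                   paths["pca_loadings"], row.names = FALSE)

  utils::write.csv(as.data.frame(best$wss_curve), paths["wss_curve"],
                   row.names = FALSE)

  stab <- do.call(rbind, lapply(names(result$selection$per_method),
    function(mth) {
      s <- result$selection$per_method[[mth]]$stability
      data.frame(scaling = mth, cluster = seq_len(s$k),
                 mean_jaccard = s$mean_jaccard,
                 dissolution_rate = s$dissolution_rate,
                 n_bootstrap = s$n_bootstrap)
    }))
  utils::write.csv(stab, paths["stability"], row.names = FALSE)

  utils::write.csv(data.frame(patient_id = names(result$solution$labels),
                              cluster = unname(result$solution$labels)),
                   paths["clusters"], row.names = FALSE)

  utils::write.csv(
    data.frame(measure = names(result$surrogate$validation_accuracy),
               validation_accuracy =
                 unname(result$surrogate$validation_accuracy),
               best = names(result$surrogate$validation_accuracy) ==
                 result$surrogate$best_measure),
    paths["measure_accuracy"], row.names = FALSE)

  cm <- as.data.frame.matrix(result$confusion)
  utils::write.csv(cbind(estimated = rownames(cm), cm),
                   paths["confusion_matrix"], row.names = FALSE)

  manifest <- list(
    config = unclass(result$config),
    stage_seeds = as.list(result$seeds),
    selected_scaling = result$selection$best,
    k = result$solution$k,
    best_measure = result$surrogate$best_measure,
    test_accuracy = result$test_accuracy,
    artifacts = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}
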