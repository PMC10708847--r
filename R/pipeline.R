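#' Assemble a pipeline run configuration
#'
#' Collects paths, processing overrides and per-stage seeds for
#' [run_pipeline()]. Either point `traces_dir`/`annotation_file`/
#' `cohort_file` at existing inputs, or supply `simulate` to generate them
#' into `out_dir` first.
#'
#' @param out_dir Output directory (created if missing).
#' @param traces_dir Directory of per-subject trace CSVs (`<id>.csv` with
#'   `<id>.csv.json` sidecars). Defaults to `<out_dir>/traces` when
#'   simulating.
#' @param annotation_file Session annotation JSON.
#' @param cohort_file Cohort table CSV (`subject_id,score,answers...`).
#' @param simulate `NULL`, or a list with `n_subjects`, `target_assoc` and
#'   `seed` for the synthetic generator.
#' @param processing Named list of [processing_config()] overrides.
#' @param stats Named list: `model` (reported headline model), `n_boot`,
#'   `seed`.
#' @param classify Named list: `seed`, optionally `grid`.
#' @param verbose Emit per-stage log lines on stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, traces_dir = NULL, annotation_file = NULL,
                       cohort_file = NULL, simulate = NULL,
                       processing = list(), stats = list(), classify = list(),
                       verbose = TRUE) {
  structure(
    list(
      out_dir = out_dir,
      traces_dir = traces_dir %||% file.path(out_dir, "traces"),
      annotation_file = annotation_file %||% file.path(out_dir, "annotation.json"),
      cohort_file = cohort_file %||% file.path(out_dir, "cohort.csv"),
      simulate = simulate,
      processing = processing,
      stats = utils::modifyList(list(model = "skipped", n_boot = 2000,
                                     seed = 1L), stats),
      classify = utils::modifyList(list(seed = 1L), classify),
      verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level fields mirror the [run_config()]
#'   arguments.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- utils::modifyList(raw, list(...))
  do.call(run_config, raw)
}

pipeline_log <- function(config, stage, ...) {
  if (config$verbose) {
    message(sprintf("[betatrace:%s] %s", stage, sprintf(...)))
  }
}

#' Run the full offline pipeline
#'
#' Stage order: simulate (optional), assemble + per-epoch processing,
#' subject summaries with cohort normalization, correlation and group
#' statistics, pass/fail classification. Every stage writes its product
#' into `out_dir`:
#' * `traces/` + `annotation.json` + `cohort.csv` (when simulating),
#' * `epochs/<subject>.csv` per-subject epoch tables
#'   (`epoch_index,start_s,status,beta_power`),
#' * `summary.csv` cohort summary
#'   (`subject_id,total_mean_beta,normalized_beta,n_epochs,n_rejected`),
#' * `correlations.csv` long correlation table,
#' * `group_test.json` group analysis report,
#' * `classifier.json` + `roc.csv` classification report.
#' Identical configuration and seeds give byte-identical products. Any
#' stage failure aborts with a stage-named error.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @return Invisibly, a list with the in-memory products: `summaries`,
#'   `correlations`, `group_test`, `classifier`, and the file `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(processing_config, config$processing)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pipeline_log(config, "simulate", "n = %s, target_assoc = %s, seed = %s",
                 sim$n_subjects, sim$target_assoc %||% 0.6, sim$seed %||% 1)
    coh <- generate_cohort(cohort_spec(
      n_subjects = sim$n_subjects,
      target_assoc = sim$target_assoc %||% 0.6,
      seed = sim$seed %||% 1L
    ))
    dir.create(config$traces_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(coh$traces)) {
      write_trace_csv(coh$traces[[id]],
                      file.path(config$traces_dir, paste0(id, ".csv")),
                      subject_id = id)
    }
    write_annotation_json(coh$annotation, config$annotation_file)
    write_cohort_csv(coh$subjects, config$cohort_file)
  }

  for (p in c(config$annotation_file, config$cohort_file)) {
    if (!file.exists(p)) {
      abort(paste0("Stage 'inputs': required file is missing: ", p))
    }
  }
  annotation <- read_annotation_json(config$annotation_file)
  cohort_table <- read_cohort_csv(config$cohort_file)

  trace_files <- sort(list.files(config$traces_dir, pattern = "\\.csv$",
                                 full.names = TRUE))
  if (!length(trace_files)) {
    abort(paste0("Stage 'assemble': no trace CSVs in ", config$traces_dir))
  }
  epoch_dir <- file.path(config$out_dir, "epochs")
  dir.create(epoch_dir, showWarnings = FALSE, recursive = TRUE)
  results <- purrr::map(trace_files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    trace <- read_trace_csv(f)
    res <- process_subject(trace, id, annotation, cfg)
    readr::write_csv(
      res$epochs[, c("epoch_index", "start_s", "status", "beta_power")],
      file.path(epoch_dir, paste0(id, ".csv"))
    )
    res
  })
  processed_all <- dplyr::bind_rows(purrr::map(results, "epochs"))
  summaries <- normalize_cohort(dplyr::bind_rows(purrr::map(results, "summary")))
  pipeline_log(config, "process",
               "%d subjects, %d epochs (%d kept, %d artifact, %d masked)",
               nrow(summaries), nrow(processed_all),
               sum(summaries$n_kept), sum(summaries$n_rejected_artifact),
               sum(summaries$n_excluded_by_mask))
  summary_out <- summaries |>
    dplyr::transmute(
      .data$subject_id, .data$total_mean_beta, .data$normalized_beta,
      n_epochs = .data$n_epochs_total,
      n_rejected = .data$n_rejected_artifact + .data$n_rejected_degenerate
    )
  readr::write_csv(summary_out, file.path(config$out_dir, "summary.csv"))

  merged <- dplyr::inner_join(summaries, cohort_table, by = "subject_id")
  correlations <- correlation_table(
    merged, beta_col = "normalized_beta",
    n_boot = config$stats$n_boot, seed = config$stats$seed
  )
  readr::write_csv(correlations, file.path(config$out_dir, "correlations.csv"))
  headline <- correlations[correlations$variable == "score" &
                             correlations$model == config$stats$model, ]
  pipeline_log(config, "stats", "score ~ beta (%s): r = %.3f, p = %.4g",
               config$stats$model, headline$estimate, headline$p.value)

  group_test <- tryCatch({
    groups <- form_groups(merged, scores = "score", betas = "total_mean_beta")
    gt <- compare_groups(groups)
    list(
      group_sizes = as.list(gt$group_sizes),
      medians = as.list(gt$medians),
      normality_p = as.list(gt$normality_p),
      variance_p = gt$variance_p,
      test_used = gt$test_used,
      statistic = gt$statistic,
      p_value = gt$p_value,
      significant = gt$significant,
      exclusion_log = groups$log
    )
  }, error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(group_test, file.path(config$out_dir, "group_test.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- tryCatch({
    features <- make_features(processed_all, summaries, annotation,
                              cohort_table, cfg)
    preds <- loocv_predict(features,
                           grid = config$classify$grid %||% default_grid(),
                           seed = config$classify$seed)
    evaluate_predictions(preds)
  }, error = function(e) {
    warn(paste0("Stage 'classify' skipped: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(report)) {
    pipeline_log(config, "classify", "accuracy = %.2f, AUC = %.2f",
                 report$metrics["accuracy"], report$auc)
    jsonlite::write_json(
      list(
        confusion = as.list(report$confusion),
        metrics = as.list(report$metrics),
        reported = as.list(report$reported),
        auc = report$auc,
        hyperparams = report$hyperparams
      ),
      file.path(config$out_dir, "classifier.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    jsonlite::write_json(list(error = "classification skipped"),
                         file.path(config$out_dir, "classifier.json"),
                         auto_unbox = TRUE)
  }
  roc_tab <- if (!is.null(report)) report$roc else {
    tibble(cut = numeric(), tpr = numeric(), fpr = numeric())
  }
  readr::write_csv(roc_tab, file.path(config$out_dir, "roc.csv"))

  invisible(list(
    summaries = summaries,
    correlations = correlations,
    group_test = group_test,
    classifier = report,
    paths = list(
      summary = file.path(config$out_dir, "summary.csv"),
      correlations = file.path(config$out_dir, "correlations.csv"),
      group_test = file.path(config$out_dir, "group_test.json"),
      classifier = file.path(config$out_dir, "classifier.json"),
      roc = file.path(config$out_dir, "roc.csv")
    )
  ))
}
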