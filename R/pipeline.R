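## End-to-end orchestration: ingest -> filter -> metrics -> turns ->
## models -> reports, plus a synthetic-cohort entry point and a small
## subcommand CLI. Output files never embed wall-clock timestamps so that
## identical inputs, configuration and seed give byte-identical outputs;
## the in-memory report carries the timing log instead.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Reads a canonical segment table and cohort metadata, applies the clip
#' filters, computes per-recording environment metrics and conversational
#' turns, and fits the statistical layer: hearing-group mixed models for
#' hourly words / minutes / vocalizations with likelihood-ratio group
#' tests, the segment-level vocalization-duration group model,
#' cross-sectional age slopes on both age bases, the turns x group
#' productivity model, and (when `config$exclude_child_ids` is set) a
#' sensitivity rerun. All tables are written as CSV and model results as
#' JSON under `out_dir`.
#'
#' @param segments_path Canonical segment CSV (see
#'   [read_segment_table()]).
#' @param cohort_path Cohort metadata CSV.
#' @param config A `daylong_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed recorded in the report and set before the
#'   model stage (fits are deterministic; the seed guards any subsampling).
#' @return A `daylong_pipeline_report`: config snapshot, filter reports,
#'   output paths, fitted objects, and a stage log.
#' @export
run_pipeline <- function(segments_path, cohort_path,
                         config = analysis_config(), out_dir = ".",
                         seed = 20240216) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[daylongr] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("ingest: %s", segments_path)
  recs <- stage("ingest", read_segment_table(segments_path, config))
  cohort <- stage("ingest", read_cohort_table(cohort_path))
  note("ingest: %d recording(s), %d cohort row(s)", length(recs),
       nrow(cohort))

  flt <- stage("filter", filter_recordings(recs, config))
  for (i in seq_len(nrow(flt$report)))
    note("filter %s: removed %d/%d clip(s) [cry %d, nonspeech %d, long %d]",
         flt$report$recording_id[i],
         flt$report$n_total[i] - flt$report$n_retained[i],
         flt$report$n_total[i], flt$report$n_removed_chn_cry[i],
         flt$report$n_removed_adult_nonspeech[i],
         flt$report$n_removed_adult_long[i])
  filter_path <- file.path(out_dir, "filter_report.csv")
  data.table::fwrite(flt$report, filter_path)

  tab <- stage("metrics", metrics_table(cohort, flt$recordings, config))
  metrics_path <- file.path(out_dir, "metrics.csv")
  data.table::fwrite(tab, metrics_path)
  hourly <- stage("metrics", hourly_long_table(flt$recordings))
  hourly <- merge(hourly, cohort[, c("child_id", "hearing_group",
                                     "chrono_age_mo", "hearing_age_mo")],
                  by = "child_id")
  hourly <- hourly[order(hourly$recording_id, hourly$hour), ]
  hourly_path <- file.path(out_dir, "hourly.csv")
  data.table::fwrite(hourly, hourly_path)

  turns <- stage("turns", as.data.frame(data.table::rbindlist(
    lapply(flt$recordings, detect_turns, config = config))))
  if (!ncol(turns))
    turns <- detect_turns(recording("x", "x", 1), config)
  turns_path <- file.path(out_dir, "turns.csv")
  data.table::fwrite(turns, turns_path)
  note("turns: %d event(s) across %d recording(s)", nrow(turns),
       length(flt$recordings))

  set.seed(seed)
  segs <- as.data.frame(data.table::rbindlist(
    lapply(flt$recordings, voc_durations)))
  if (!ncol(segs))
    segs <- data.frame(recording_id = character(),
                       child_id = character(), dur_ms = numeric())
  models <- stage("models", fit_model_suite(tab, hourly, segs, cohort,
                                            config, note))
  models_path <- file.path(out_dir, "models.json")
  write_json_file(model_to_list(models$serializable), models_path)
  slopes_path <- file.path(out_dir, "slopes.csv")
  data.table::fwrite(models$slopes, slopes_path)

  report <- structure(list(
    config_used = unclass(config), seed = seed,
    filter_reports = flt$report,
    paths = list(filter = filter_path, metrics = metrics_path,
                 hourly = hourly_path, turns = turns_path,
                 models = models_path, slopes = slopes_path),
    models = models, metrics = tab, run_log = log),
    class = "daylong_pipeline_report")
  # basenames only: report.json must be byte-identical across runs into
  # different directories with the same inputs/config/seed
  write_json_file(list(config_used = unclass(config), seed = seed,
                       outputs = lapply(report$paths, basename)),
                  file.path(out_dir, "report.json"))
  report
}

## The model stage, shared by run_pipeline and re-runnable on a saved
## metrics table. Degenerate designs (e.g. an empty cohort slice or a
## constant outcome) are flagged rather than fatal.
fit_model_suite <- function(tab, hourly, segs, cohort, config, note) {
  degenerate <- function(what, e) {
    note("models: %s flagged degenerate (%s)", what, conditionMessage(e))
    NULL
  }
  try_fit <- function(what, expr)
    tryCatch(expr, error = function(e) degenerate(what, e))
  group_models <- list()
  for (spec in list(c("words", "hourly adult words"),
                    c("adult_min", "hourly adult minutes"),
                    c("voc_count", "hourly child vocalizations"))) {
    out <- spec[1]
    group_models[[out]] <- try_fit(spec[2], {
      full <- fit_group_model(hourly, out, "hearing_group",
                              c("child_id", "hour"))
      null <- fit_group_model(hourly, out, character(),
                              c("child_id", "hour"))
      list(model = full, lrt = compare_models(null, full))
    })
  }
  group_models$voc_dur_ms <- try_fit("vocalization duration", {
    d <- merge(segs, cohort[, c("child_id", "hearing_group")],
               by = "child_id")
    full <- fit_group_model(d, "dur_ms", "hearing_group", "child_id")
    null <- fit_group_model(d, "dur_ms", character(), "child_id")
    list(model = full, lrt = compare_models(null, full))
  })
  outcomes <- c("awc_per_hr", "adult_sec_per_hr", "cvc_per_hr",
                "ctc_per_hr", "input_consistency", "output_consistency",
                "turn_consistency")
  slopes <- try_fit("cross-sectional slopes", do.call(rbind, c(
    lapply(outcomes, function(o) rbind(
      cross_sectional_slopes(tab, o, "chrono", config),
      cross_sectional_slopes(tab, o, "hearing", config))),
    list(make.row.names = FALSE))))
  dur_slopes <- try_fit("duration slopes", rbind(
    voc_duration_slopes(segs, cohort, "chrono", config),
    voc_duration_slopes(segs, cohort, "hearing", config)))
  productivity <- try_fit("productivity model",
                          fit_productivity_model(tab))
  sensitivity <- NULL
  if (length(config$exclude_child_ids))
    sensitivity <- try_fit("sensitivity rerun",
                           sensitivity_rerun(tab, config, segs, cohort))
  slopes_all <- rbind(if (!is.null(slopes)) slopes,
                      if (!is.null(dur_slopes)) dur_slopes)
  if (is.null(slopes_all))
    slopes_all <- data.frame(group = character(), age_basis = character(),
                             outcome_name = character(), n = integer(),
                             beta = numeric(), se = numeric(),
                             pearson_r = numeric(), p = numeric(),
                             available = logical())
  list(group_models = group_models, slopes = slopes_all,
       productivity = productivity, sensitivity = sensitivity,
       serializable = list(
         group_models = lapply(group_models, function(x)
           if (is.null(x)) "degenerate" else
             list(model = model_to_list(x$model),
                  lrt = model_to_list(x$lrt))),
         productivity = if (is.null(productivity)) "degenerate" else
           list(model = model_to_list(productivity$model),
                interaction_lrt = model_to_list(productivity$comparison),
                group_slopes = productivity$group_slopes),
         sensitivity = if (is.null(sensitivity)) NULL else
           list(shifts = sensitivity$shifts)))
}

#' Generate a synthetic cohort and run the pipeline on it
#'
#' Writes the generated segment and cohort tables in the canonical formats
#' under `out_dir`, then delegates to [run_pipeline()]; optionally appends
#' a parameter-recovery experiment.
#'
#' @param params A `daylong_synth_params` (or path to a key=value file via
#'   `params_path`).
#' @param config A `daylong_config`.
#' @param out_dir Output directory.
#' @param recovery_reps If positive, also run [recovery_experiment()] with
#'   this many replicates and write `recovery.csv` / `recovery.json`.
#' @return The `daylong_pipeline_report`, with `synth_paths` and
#'   optionally `recovery` attached.
#' @export
run_synthetic <- function(params = synth_params(),
                          config = analysis_config(), out_dir = ".",
                          recovery_reps = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(params)
  recs <- generate_recordings(cohort, params)
  seg_path <- file.path(out_dir, "synthetic_segments.csv")
  coh_path <- file.path(out_dir, "synthetic_cohort.csv")
  write_segment_table(recs, seg_path)
  write_cohort_table(cohort, coh_path)
  report <- run_pipeline(seg_path, coh_path, config, out_dir,
                         seed = params$seed)
  report$synth_paths <- list(segments = seg_path, cohort = coh_path)
  if (recovery_reps > 0) {
    rec <- recovery_experiment(params, n_reps = recovery_reps,
                               config = config)
    data.table::fwrite(rec$summary, file.path(out_dir, "recovery.csv"))
    write_json_file(rec$summary, file.path(out_dir, "recovery.json"))
    report$recovery <- rec
  }
  report
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (segments + cohort -> full pipeline), `synth`
#' (generate a synthetic cohort and analyse it), `recover` (synthetic
#' parameter-recovery report), `ingest` (validate and canonicalize a
#' segment table), `filter`, `metrics`, `turns` (stage-level runs on a
#' segment table), `models` (refit slopes and the productivity model from
#' a saved metrics table). Common options: `--config` (key=value file),
#' `--seed`, `--out-dir`, `--exclude-child` (comma separated),
#' `--age-basis` (chrono or hearing, for `models` slope tables).
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly on success; stops on error.
#' @export
daylong_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: daylongr <subcommand> [options]",
    paste("subcommands: run-all | synth | recover | ingest | filter |",
          "metrics | turns | models"),
    sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--segments", type = "character"),
    optparse::make_option("--cohort", type = "character"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir",
                          default = "."),
    optparse::make_option("--seed", type = "integer", default = 20240216L),
    optparse::make_option("--exclude-child", type = "character",
                          dest = "exclude_child", default = ""),
    optparse::make_option("--age-basis", type = "character",
                          dest = "age_basis", default = "chrono"),
    optparse::make_option("--n-per-group", type = "integer",
                          dest = "n_per_group", default = 18L),
    optparse::make_option("--reps", type = "integer", default = 10L),
    optparse::make_option("--metrics", type = "character"),
    optparse::make_option("--outcome", type = "character",
                          default = "awc_per_hr"))
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = args[-1])
  config <- if (!is.null(parsed$config)) read_config(parsed$config) else
    analysis_config()
  if (nzchar(parsed$exclude_child))
    config$exclude_child_ids <-
      trimws(strsplit(parsed$exclude_child, ",")[[1]])
  need <- function(x, flag)
    if (is.null(x)) stop("missing required option ", flag, call. = FALSE)
  out <- switch(
    cmd,
    "run-all" = {
      need(parsed$segments, "--segments"); need(parsed$cohort, "--cohort")
      run_pipeline(parsed$segments, parsed$cohort, config, parsed$out_dir,
                   seed = parsed$seed)
    },
    "synth" = run_synthetic(
      synth_params(n_per_group = parsed$n_per_group, seed = parsed$seed),
      config, parsed$out_dir),
    "recover" = {
      rec <- recovery_experiment(
        synth_params(n_per_group = parsed$n_per_group,
                     seed = parsed$seed),
        n_reps = parsed$reps, config = config)
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(rec$summary,
                         file.path(parsed$out_dir, "recovery.csv"))
      write_json_file(rec$summary,
                      file.path(parsed$out_dir, "recovery.json"))
      print(rec$summary)
      rec
    },
    "ingest" = {
      need(parsed$segments, "--segments")
      recs <- read_segment_table(parsed$segments, config)
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_segment_table(recs,
                          file.path(parsed$out_dir, "segments.csv"))
      message(length(recs), " recording(s) validated")
      recs
    },
    "models" = {
      need(parsed$metrics, "--metrics")
      tab <- as.data.frame(data.table::fread(parsed$metrics))
      sl <- do.call(rbind, lapply(
        c("awc_per_hr", "adult_sec_per_hr", "cvc_per_hr", "ctc_per_hr"),
        function(o) cross_sectional_slopes(tab, o, parsed$age_basis,
                                           config)))
      pm <- fit_productivity_model(tab)
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(sl, file.path(parsed$out_dir, "slopes.csv"))
      write_json_file(
        list(productivity = list(
          model = model_to_list(pm$model),
          interaction_lrt = model_to_list(pm$comparison),
          group_slopes = pm$group_slopes)),
        file.path(parsed$out_dir, "models.json"))
      list(slopes = sl, productivity = pm)
    },
    "filter" = {
      need(parsed$segments, "--segments")
      recs <- read_segment_table(parsed$segments, config)
      flt <- filter_recordings(recs, config)
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(flt$report,
                         file.path(parsed$out_dir, "filter_report.csv"))
      write_segment_table(flt$recordings,
                          file.path(parsed$out_dir,
                                    "filtered_segments.csv"))
      flt$report
    },
    "metrics" = {
      need(parsed$segments, "--segments"); need(parsed$cohort, "--cohort")
      recs <- read_segment_table(parsed$segments, config)
      flt <- filter_recordings(recs, config)
      cohort <- read_cohort_table(parsed$cohort)
      tab <- metrics_table(cohort, flt$recordings, config)
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(tab, file.path(parsed$out_dir, "metrics.csv"))
      tab
    },
    "turns" = {
      need(parsed$segments, "--segments")
      recs <- read_segment_table(parsed$segments, config)
      flt <- filter_recordings(recs, config)
      turns <- do.call(rbind, c(
        lapply(flt$recordings, detect_turns, config = config),
        list(make.row.names = FALSE)))
      dir.create(parsed$out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(turns, file.path(parsed$out_dir, "turns.csv"))
      turns
    },
    stop(usage, call. = FALSE))
  invisible(out)
}
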