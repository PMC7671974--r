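# End-to-end orchestration: ingest -> metrics -> statistics -> reports.

#' Build a run configuration
#'
#' Exactly one input mode must be given: `input_dir` (a directory tree of
#' `<Exercise>/kinematics/*.txt` 76-column files with per-exercise
#' `meta_file_<Exercise>.txt` metadata) or `cohort` (a [cohort_spec()],
#' simulated into `out_dir/cohort_data` before analysis). All parameters
#' that the original motion-analysis software left unstated (smoothing
#' sigma, peak threshold, manipulator choice, SD convention, ordinal skill
#' coding) are explicit here and echoed into the run manifest.
#'
#' @param input_dir directory with recorded trials, or `NULL`.
#' @param cohort a [cohort_spec()], or `NULL`.
#' @param exercises exercises to analyze.
#' @param manipulators manipulators to compute metrics on (default both
#'   masters).
#' @param sigma_samples Gaussian smoothing sigma (samples).
#' @param min_peak_height absolute peak threshold (m/interval) or `NULL`
#'   for the adaptive 10%-of-max rule.
#' @param min_peak_separation minimum peak separation (samples); default
#'   `2 * sigma_samples`.
#' @param alpha significance level.
#' @param out_dir output directory for the report files.
#' @param seed integer seed (used only when simulating a cohort).
#' @param strict if `TRUE`, a malformed trial file aborts the run; default
#'   skips it with a warning and records it in the manifest.
#' @param n_trajectories number of per-exercise trials whose trajectories
#'   are exported as CSV (default 1, the first trial).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, cohort = NULL,
                       exercises = EXERCISES,
                       manipulators = c("master_left", "master_right"),
                       sigma_samples = 5, min_peak_height = NULL,
                       min_peak_separation = 2 * sigma_samples,
                       alpha = 0.05, out_dir, seed = NULL, strict = FALSE,
                       n_trajectories = 1) {
  if (is.null(input_dir) == is.null(cohort))
    stopf("exactly one of input_dir or cohort must be given")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  exercises <- exercise_from_token(exercises)
  bad <- setdiff(manipulators, manipulator_ids())
  if (length(bad)) stopf("unknown manipulator(s): %s", paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(
    list(input_dir = input_dir, cohort = cohort, exercises = exercises,
         manipulators = manipulators, sigma_samples = sigma_samples,
         min_peak_height = min_peak_height,
         min_peak_separation = min_peak_separation, alpha = alpha,
         out_dir = out_dir, seed = seed, strict = strict,
         n_trajectories = n_trajectories),
    class = "run_config")
}

# locate per-exercise inputs below a data directory
exercise_inputs <- function(dir, exercise) {
  token <- exercise_file_token(exercise)
  kdir <- file.path(dir, token, "kinematics")
  meta <- file.path(dir, token, sprintf("meta_file_%s.txt", token))
  files <- if (dir.exists(kdir))
    list.files(kdir, pattern = "\\.txt$", full.names = TRUE) else character(0)
  list(files = sort(files), meta = meta)
}

parse_trial_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^([A-Za-z_]+)_([A-Z])00([0-9])\\.txt$",
                          basename(path)))[[1]]
  if (!length(m)) return(NULL)
  list(exercise = exercise_from_token(m[2]), participant = m[3],
       repetition = as.integer(m[4]))
}

metrics_to_wide <- function(id, metrics) {
  row <- data.frame(exercise = id$exercise, participant = id$participant,
                    repetition = id$repetition,
                    time_s = metrics$time_s[1], stringsAsFactors = FALSE)
  side <- c(master_left = "left", master_right = "right",
            slave_left = "slave_left", slave_right = "slave_right")
  for (i in seq_len(nrow(metrics))) {
    s <- side[[metrics$manipulator[i]]]
    row[[paste0(s, "_path_length")]] <- metrics$path_length_m[i]
    row[[paste0(s, "_movements")]] <- metrics$movements[i]
  }
  row
}

#' Run the full motion-analysis pipeline
#'
#' Ingests every trial of the configured exercises, computes per-trial
#' metrics, assembles the three report tables (GRS by skill with Spearman;
#' metrics mean +/- SD by skill; pairwise Mann-Whitney p-values with the
#' Pearson kinematics-vs-GRS column), scatter data with linear trend lines,
#' trajectory exports, and a JSON run manifest, all written under
#' `config$out_dir`. Re-running with the same config and seed reproduces
#' every output byte for byte.
#'
#' @param config a [run_config()].
#' @return an object of class `analysis_report` (list with `metrics`,
#'   `table1`, `table2`, `table3`, `scatter`, `manifest`, `out_dir`),
#'   invisibly also written to disk.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- config$input_dir
  if (!is.null(config$cohort)) {
    spec <- config$cohort
    if (!is.null(config$seed)) spec$seed <- config$seed
    data_dir <- file.path(out_dir, "cohort_data")
    generate_cohort(spec, data_dir)
  }
  if (!dir.exists(data_dir)) stopf("input directory not found: %s", data_dir)

  skipped <- character(0)
  all_metrics <- list(); records <- list(); traj_files <- character(0)
  for (ex in config$exercises) {
    inp <- exercise_inputs(data_dir, ex)
    if (!length(inp$files)) {
      warnf("no trials found for exercise '%s' under %s", ex, data_dir)
      next
    }
    if (!file.exists(inp$meta))
      stopf("metadata file missing for exercise '%s': %s", ex, inp$meta)
    recs <- read_meta(inp$meta)
    records[[ex]] <- recs
    n_traj <- 0
    for (f in inp$files) {
      id <- parse_trial_filename(f)
      if (is.null(id)) {
        warnf("skipping unrecognized file name: %s", f)
        skipped <- c(skipped, f)
        next
      }
      stream <- tryCatch(read_kinematics(f), error = function(e) {
        if (config$strict) stop(e)
        warnf("skipping corrupt trial %s: %s", f, conditionMessage(e))
        NULL
      })
      if (is.null(stream)) { skipped <- c(skipped, f); next }
      message(sprintf("processed %s (%d frames)", basename(f),
                      n_samples(stream)))
      m <- compute_metrics(stream, config$manipulators,
                           config$sigma_samples, config$min_peak_height,
                           config$min_peak_separation)
      all_metrics[[length(all_metrics) + 1L]] <- metrics_to_wide(id, m)
      if (n_traj < config$n_trajectories) {
        n_traj <- n_traj + 1
        for (manip in config$manipulators) {
          tf <- file.path(out_dir, sprintf(
            "trajectory_%s_%s00%d_%s.csv", exercise_file_token(ex),
            id$participant, id$repetition, manip))
          utils::write.csv(trajectory_export(stream, manip), tf,
                           row.names = FALSE)
          traj_files <- c(traj_files, tf)
        }
      }
    }
  }
  if (!length(all_metrics))
    stopf("no analyzable trials found under %s (exercises: %s)", data_dir,
          paste(config$exercises, collapse = ", "))
  metrics <- do.call(rbind, all_metrics)
  recs <- do.call(rbind, records)
  rownames(metrics) <- rownames(recs) <- NULL

  tables <- skill_comparison_table(metrics, recs, alpha = config$alpha)
  # table 1 analog: GRS by skill + Spearman; table 2 analog: metric summaries
  grs_rows <- tables$comparisons[tables$comparisons$parameter == "grs", ]
  kin_rows <- tables$comparisons[tables$comparisons$parameter != "grs", ]
  table1 <- list(summary = grs_rows[, c(
    "exercise", "n_novice", "mean_novice", "sd_novice", "n_intermediate",
    "mean_intermediate", "sd_intermediate", "n_expert", "mean_expert",
    "sd_expert")], spearman = tables$spearman)
  table2 <- local({
    long <- list()
    for (i in seq_len(nrow(kin_rows))) for (g in skill_levels()) {
      long[[length(long) + 1L]] <- data.frame(
        exercise = kin_rows$exercise[i], skill = g,
        parameter = kin_rows$parameter[i],
        n = kin_rows[[paste0("n_", g)]][i],
        mean = kin_rows[[paste0("mean_", g)]][i],
        sd = kin_rows[[paste0("sd_", g)]][i], stringsAsFactors = FALSE)
    }
    do.call(rbind, long)
  })
  table3 <- tables$comparisons[, c(
    "exercise", "parameter", "p_novice_intermediate",
    "p_intermediate_expert", "p_novice_expert", "sig_novice_intermediate",
    "sig_intermediate_expert", "sig_novice_expert", "pearson_r_grs",
    "pearson_p_grs", "pearson_strength")]

  # scatter data (metric vs GRS) with OLS trend, per exercise x parameter
  scatter <- list()
  key <- function(d) paste(d$exercise, d$participant, d$repetition)
  idx <- match(key(metrics), key(recs))
  grs <- recs$grs_total[idx]
  for (ex in unique(metrics$exercise)) {
    sel <- metrics$exercise == ex
    for (par in setdiff(comparison_parameters(), "grs")) {
      col <- if (par == "time") "time_s" else par
      v <- metrics[[col]][sel]
      if (is.null(v) || stats::sd(v) == 0) next
      tr <- linear_trend(v, grs[sel])
      scatter[[paste(ex, par, sep = ".")]] <- data.frame(
        exercise = ex, parameter = par,
        participant = metrics$participant[sel],
        repetition = metrics$repetition[sel], value = v,
        grs_total = grs[sel], slope = tr$slope, intercept = tr$intercept,
        stringsAsFactors = FALSE)
    }
  }

  manifest <- list(
    package = "surgkin",
    version = as.character(utils::packageVersion("surgkin")),
    config = list(
      input_mode = if (is.null(config$cohort)) "jigsaws-directory"
                   else "synthetic-cohort-spec",
      input_dir = data_dir, exercises = config$exercises,
      manipulators = config$manipulators,
      sigma_samples = config$sigma_samples,
      min_peak_height = config$min_peak_height %||% "adaptive:0.1*max",
      min_peak_separation = config$min_peak_separation,
      alpha = config$alpha, seed = config$seed, strict = config$strict,
      sd_convention = "sample (n-1)",
      skill_ordinal_coding = "novice=1, intermediate=2, expert=3",
      path_length_positions = "raw (unsmoothed)"),
    n_trials = nrow(metrics), skipped_files = skipped)

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(table1$summary, file.path(out_dir, "table1_grs.csv"),
                   row.names = FALSE)
  utils::write.csv(table1$spearman,
                   file.path(out_dir, "table1_spearman.csv"),
                   row.names = FALSE)
  utils::write.csv(table2, file.path(out_dir, "table2_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(table3, file.path(out_dir, "table3_comparisons.csv"),
                   row.names = FALSE)
  if (length(scatter))
    utils::write.csv(do.call(rbind, scatter),
                     file.path(out_dir, "scatter_grs.csv"),
                     row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  structure(
    list(metrics = metrics, records = recs, table1 = table1,
         table2 = table2, table3 = table3, scatter = scatter,
         manifest = manifest, out_dir = out_dir,
         trajectory_files = traj_files),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d trials, exercises: %s, output: %s\n",
              nrow(x$metrics),
              paste(unique(x$metrics$exercise), collapse = ", "), x$out_dir))
  invisible(x)
}

#' Bundled reference values of the published tables
#'
#' The printed group summaries, trial counts, correlations and p-values of
#' the published motion analysis, as a tidy data frame. `comparability`
#' distinguishes parameter-free quantities ("exact": trial counts, time
#' means/SDs, GRS summaries and GRS-based statistics, reproducible from any
#' faithful reimplementation given the dataset) from smoothing-parameter-
#' dependent ones ("informational": path lengths, movement counts and their
#' statistics, whose original smoothing and peak parameters were never
#' published). `qualifier` is "lt" for values printed as upper bounds
#' ("p < .05").
#'
#' @return data frame with columns `table`, `exercise`, `group`,
#'   `parameter`, `statistic`, `value`, `qualifier`, `comparability`.
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.csv", package = "surgkin")
  if (!nzchar(path)) stopf("bundled reference_tables.csv not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# printed rounding tolerance: half a unit in the last printed decimal place
printed_tolerance <- function(value_chr) {
  dec <- ifelse(grepl("\\.", value_chr),
                nchar(sub("^[^.]*\\.", "", value_chr)), 0)
  0.5 * 10^(-dec)
}

#' Compare a computed report with the published reference values
#'
#' Lists every reference value side by side with the corresponding computed
#' value. Parameter-free quantities (trial counts, time means, GRS
#' summaries and statistics) get a pass/fail verdict within the printed
#' rounding; smoothing-parameter-dependent quantities (path length,
#' movements) are reported with their deltas but flagged
#' "parameter-dependent, informational". Reference rows with no computed
#' counterpart are listed as "uncomparable".
#'
#' @param report an `analysis_report` from [run_analysis()].
#' @param reference reference data frame, default [reference_tables()].
#' @return data frame of class `report_diff` with columns `exercise`,
#'   `group`, `parameter`, `statistic`, `printed`, `computed`, `delta`,
#'   `status`.
#' @export
diff_report <- function(report, reference = reference_tables()) {
  stopifnot(inherits(report, "analysis_report"))
  m <- report$metrics; recs <- report$records
  t3 <- report$table3; sp <- report$table1$spearman
  lookup <- function(ex, group, parameter, statistic) {
    if (!ex %in% unique(m$exercise)) return(NA_real_)
    d <- m[m$exercise == ex, , drop = FALSE]
    key <- function(d) paste(d$exercise, d$participant, d$repetition)
    sk <- recs$skill_level[match(key(d), key(recs))]
    grs <- recs$grs_total[match(key(d), key(recs))]
    if (statistic == "count" && parameter == "trials") return(nrow(d))
    col <- switch(parameter, time = "time_s", grs = "__grs__", parameter)
    vals <- if (col == "__grs__") grs else d[[col]]
    if (is.null(vals)) return(NA_real_)
    if (statistic %in% c("mean", "sd", "n")) {
      v <- vals[sk == group]
      if (!length(v)) return(NA_real_)
      return(switch(statistic, n = length(v), mean = mean(v),
                    sd = if (length(v) > 1) stats::sd(v) else NA_real_))
    }
    if (statistic == "spearman_r")
      return(sp$spearman_r[match(ex, sp$exercise)])
    if (statistic == "spearman_p")
      return(sp$spearman_p[match(ex, sp$exercise)])
    if (statistic == "pearson_r") {
      i <- t3$exercise == ex & t3$parameter == parameter
      return(if (any(i)) t3$pearson_r_grs[i][1] else NA_real_)
    }
    if (startsWith(statistic, "p_")) {
      i <- t3$exercise == ex & t3$parameter == parameter
      return(if (any(i)) t3[[statistic]][i][1] else NA_real_)
    }
    NA_real_
  }
  ref <- reference
  out <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    comp <- lookup(r$exercise, r$group, r$parameter, r$statistic)
    printed <- as.numeric(r$value)
    delta <- if (is.na(comp)) NA_real_ else comp - printed
    status <- if (is.na(comp)) {
      "uncomparable"
    } else if (r$comparability == "informational") {
      "parameter-dependent, informational"
    } else if (identical(r$qualifier, "lt")) {
      if (comp < printed) "pass" else "fail"
    } else if (abs(delta) <= printed_tolerance(r$value)) {
      "pass"
    } else {
      "fail"
    }
    data.frame(exercise = r$exercise, group = r$group,
               parameter = r$parameter, statistic = r$statistic,
               printed = printed, computed = comp, delta = delta,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("report_diff", class(out))
  out
}

#' Rebuild a minimal report from a written output directory
#'
#' Reads the CSV outputs of a previous [run_analysis()] run so that
#' [diff_report()] can be applied to an on-disk report (used by the CLI
#' `diff` subcommand).
#'
#' @param dir an output directory written by [run_analysis()].
#' @return an `analysis_report` (metrics and tables only).
#' @export
read_report <- function(dir) {
  need <- file.path(dir, c("metrics.csv", "table1_spearman.csv",
                           "table3_comparisons.csv"))
  if (!all(file.exists(need)))
    stopf("%s does not look like a surgkin report directory", dir)
  metrics <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  recs <- data.frame(exercise = metrics$exercise,
                     participant = metrics$participant,
                     repetition = metrics$repetition,
                     skill_level = participant_skill(metrics$participant),
                     stringsAsFactors = FALSE)
  # GRS per trial is recoverable from the scatter export when present
  scat_path <- file.path(dir, "scatter_grs.csv")
  recs$grs_total <- NA_real_
  if (file.exists(scat_path)) {
    sc <- utils::read.csv(scat_path, stringsAsFactors = FALSE)
    key <- function(d) paste(d$exercise, d$participant, d$repetition)
    recs$grs_total <- sc$grs_total[match(key(recs), key(sc))]
  }
  structure(
    list(metrics = metrics, records = recs,
         table1 = list(spearman = utils::read.csv(need[2],
                                                  stringsAsFactors = FALSE)),
         table3 = utils::read.csv(need[3], stringsAsFactors = FALSE),
         out_dir = dir),
    class = "analysis_report")
}
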