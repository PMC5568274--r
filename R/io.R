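#' Load a simulation configuration from a flat YAML/JSON file
#'
#' The file holds a flat mapping of \code{\link{sim_config}} fields
#' (\code{dose_cutpoints} as a two-element sequence). Missing fields take
#' the documented defaults; unknown keys are rejected by name. The
#' effective configuration is echoed to \code{message()} so runs are
#' self-documenting.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @param quiet suppress the echo.
#' @return a validated \code{gtb_config}.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) config_error("path", sprintf("file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) config_error("file", "must contain a key-value mapping")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    config_error(unknown[1], "unknown configuration key")
  cfg <- do.call(sim_config, raw)
  if (!quiet)
    message("effective configuration: ",
            paste(sprintf("%s=%s", names(unclass(cfg)),
                          vapply(unclass(cfg), function(v) paste(format(v), collapse = ","), "")),
                  collapse = " "))
  cfg
}

#' Save a simulation configuration to YAML
#'
#' Round-trips losslessly through \code{\link{load_config}}.
#'
#' @param config a \code{gtb_config}.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "gtb_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Write / read the per-subject cohort table
#'
#' CSV schema: \code{subject_id, intended_user, initiation_interval,
#' followup_end, event, final_dose_category}. \code{initiation_interval}
#' is empty for non-users. Round-trips losslessly.
#'
#' @param subjects the subjects table of a \code{gtb_cohort}.
#' @param path CSV path.
#' @return \code{read_subjects_csv} returns the subjects data.frame.
#' @export
write_subjects_csv <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subjects_csv
#' @export
read_subjects_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  need <- c("subject_id", "intended_user", "initiation_interval",
            "followup_end", "event", "final_dose_category")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) data_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  df$intended_user <- as.logical(df$intended_user)
  df$event <- as.logical(df$event)
  df$initiation_interval <- as.integer(df$initiation_interval)
  df$followup_end <- as.integer(df$followup_end)
  df$final_dose_category <- factor(df$final_dose_category, levels = dose_levels())
  df[need]
}

#' Write / read the counting-process table
#'
#' CSV schema: \code{subject_id, start, stop, z1, z2, z3, event}, using the
#' (start, stop] half-open convention of \code{\link{make_counting_process}}.
#'
#' @param cp a counting-process design.
#' @param path CSV path.
#' @return \code{read_counting_csv} returns the design data.frame (class
#'   \code{gtb_design}).
#' @export
write_counting_csv <- function(cp, path) {
  utils::write.csv(as.data.frame(cp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counting_csv
#' @export
read_counting_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "start", "stop", "z1", "z2", "z3", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) data_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(df$start >= df$stop)) data_error("start must be < stop in every row")
  df$start <- as.numeric(df$start)
  df$stop <- as.numeric(df$stop)
  df$event <- as.logical(df$event)
  structure(df[need], class = c("gtb_design", "data.frame"), design = "counting_process")
}

data_error <- function(msg) {
  stop(structure(class = c("gtb_data_error", "error", "condition"),
                 list(message = paste("data error:", msg), call = sys.call(-1))))
}

#' Read a user-supplied cohort with yearly dosing
#'
#' Imports a real cohort in a yearly-dose schema for analysis with the same
#' three design builders as simulated data. Required columns:
#' \code{subject_id}, \code{followup_years} (integer, 1..n_intervals),
#' \code{event} (0/1), \code{drug_start_year} (empty for never-users), and
#' per-year dose columns \code{dose_1 .. dose_K}. Yearly doses are
#' accumulated into cumulative doses and categorized with the supplied
#' cutpoints (e.g. the milligram cutpoints 1350 and 4500 of a prescription
#' registry). A subject whose event year precedes the drug start year is a
#' realized non-user.
#'
#' @param path CSV path.
#' @param dose_cutpoints two increasing positive cutpoints on the
#'   cumulative-dose scale of the file.
#' @return a \code{gtb_cohort}-shaped list with \code{subjects} and
#'   \code{long} tables.
#' @export
read_user_cohort_csv <- function(path, dose_cutpoints) {
  df <- utils::read.csv(path, na.strings = "")
  if (nrow(df) == 0L) data_error("file contains a header but no rows")
  need <- c("subject_id", "followup_years", "event", "drug_start_year")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) data_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  dose_cols <- grep("^dose_[0-9]+$", names(df), value = TRUE)
  if (length(dose_cols) == 0L) data_error("no dose_<year> columns found")
  dose_cols <- dose_cols[order(as.integer(sub("^dose_", "", dose_cols)))]
  K <- length(dose_cols)
  dose <- as.matrix(df[dose_cols])
  dose[is.na(dose)] <- 0
  for (i in seq_len(nrow(df))) {
    if (any(dose[i, ] < 0)) data_error(sprintf("negative dose in row %d", i))
    if (!is.finite(df$followup_years[i]) || df$followup_years[i] < 1 ||
        df$followup_years[i] > K || df$followup_years[i] != round(df$followup_years[i]))
      data_error(sprintf("followup_years out of 1..%d in row %d", K, i))
    w <- df$drug_start_year[i]
    if (!is.na(w) && (w < 1 || w > K || w != round(w)))
      data_error(sprintf("drug_start_year out of 1..%d in row %d", K, i))
  }
  cum <- t(apply(dose, 1L, cumsum))
  fup <- as.integer(df$followup_years)
  ev <- as.logical(df$event)
  n <- nrow(df)
  code <- dose_category_code(cum, dose_cutpoints)
  # dosing after the end of follow-up, or before drug start, is ignored
  w <- as.integer(df$drug_start_year)
  realized_user <- !is.na(w) & w <= fup
  final_code <- ifelse(realized_user, code[cbind(seq_len(n), fup)], 0L)
  subjects <- data.frame(subject_id = df$subject_id,
                         intended_user = !is.na(w),
                         initiation_interval = w,
                         followup_end = fup,
                         event = ev,
                         final_dose_category = factor(dose_levels()[final_code + 1L],
                                                      levels = dose_levels()))
  sid_idx <- rep(seq_len(n), fup)
  tt <- sequence(fup)
  code_long <- code[cbind(sid_idx, tt)]
  code_long[!realized_user[sid_idx]] <- 0L
  long <- data.frame(subject_id = df$subject_id[sid_idx],
                     interval = as.integer(tt),
                     z1 = as.integer(code_long == 1L),
                     z2 = as.integer(code_long == 2L),
                     z3 = as.integer(code_long == 3L),
                     event_this_interval = (tt == fup[sid_idx]) & ev[sid_idx])
  structure(list(subjects = subjects, long = long, config = NULL),
            class = "gtb_cohort")
}

#' Write a run manifest and export scenario tables
#'
#' \code{export_scenario_tables} writes the study tables
#' (\code{table1_type1.csv} or \code{table2_power.csv}, and
#' \code{table3_bias_mse.csv}) for a list of scenario results, preceded by
#' a JSON run manifest (\code{manifest.json}) recording the configurations,
#' root seeds, the per-replication seed rule, package version, timestamp
#' and output file list. \code{rerun_from_manifest} re-executes every
#' scenario recorded in a manifest and rewrites the same tables into
#' another directory, reproducing them byte-identically.
#'
#' @param results list of \code{gtb_scenario_result}.
#' @param out_dir output directory (created if needed).
#' @param null_scenario whether the rejection-count table is a type I error
#'   table (TRUE) or a power table.
#' @return invisibly, the manifest path.
#' @export
export_scenario_tables <- function(results, out_dir, null_scenario = TRUE) {
  if (inherits(results, "gtb_scenario_result")) results <- list(results)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  count_file <- if (null_scenario) "table1_type1.csv" else "table2_power.csv"
  files <- c(count_file, "table3_bias_mse.csv")
  manifest <- list(
    package = "gtbias",
    version = as.character(utils::packageVersion("gtbias")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed_rule = "replication r uses seed = config$seed + r",
    null_scenario = null_scenario,
    scenarios = lapply(results, function(res) {
      spec <- attr(res, "spec")
      list(config = unclass(spec$config),
           n_replications = spec$n_replications,
           alpha = spec$alpha,
           methods = spec$methods,
           landmark_times = spec$landmark_times,
           true_hr = as.list(spec$true_hr),
           ties = spec$ties)
    }),
    outputs = files)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  counts <- tabulate_scenarios(results, if (null_scenario) "type1" else "power")
  utils::write.csv(counts, file.path(out_dir, count_file), row.names = FALSE)
  bm <- tabulate_scenarios(results, "bias_mse")
  utils::write.csv(bm, file.path(out_dir, "table3_bias_mse.csv"), row.names = FALSE)
  invisible(manifest_path)
}

#' @rdname export_scenario_tables
#' @param manifest_path path to a \code{manifest.json}.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  results <- lapply(m$scenarios, function(sc) {
    cfg <- do.call(sim_config, sc$config)
    spec <- scenario_spec(cfg, n_replications = sc$n_replications,
                          alpha = sc$alpha, methods = unlist(sc$methods),
                          landmark_times = unlist(sc$landmark_times),
                          true_hr = unlist(sc$true_hr), ties = sc$ties)
    run_scenario(spec)
  })
  export_scenario_tables(results, out_dir, null_scenario = isTRUE(m$null_scenario))
}
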