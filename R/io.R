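# Stable file formats, configuration, logging, and the pipeline entry
# point. Interchange format is plain CSV so every artifact is diffable.

trials_schema_cols <- c("lab_id", "mouse_id", "session_day", "trial_index",
                        "signed_contrast", "block_p_left", "choice",
                        "correct", "trial_duration_s", "is_repeat",
                        "stage_id")

valid_contrasts <- function() {
  m <- contrast_levels()
  sort(unique(c(m, -m)))
}

#' Read and validate a trials table
#'
#' Validates the CSV against the schema: required columns, contrast
#' vocabulary, block priors in \{0.5, 0.2, 0.8\}, choices in \{-1, 0, 1\},
#' rewarded trials must have a response, and (lab, mouse, day, trial) keys
#' must be unique. Rows are returned sorted by (lab, mouse, day,
#' trial_index).
#'
#' @param path CSV file path.
#' @return Validated trials data frame.
#' @export
read_trials_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials_table(tr)
}

#' Validate an in-memory trials table
#' @param tr Data frame.
#' @return The table, typed and sorted.
#' @export
validate_trials_table <- function(tr) {
  missing_cols <- setdiff(trials_schema_cols, colnames(tr))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_row <- function(ok, what) {
    if (!all(ok))
      stop("schema error: ", what, " at row(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  bad_row(tr$signed_contrast %in% valid_contrasts(),
          "signed_contrast outside the stimulus vocabulary")
  bad_row(tr$block_p_left %in% c(0.5, 0.2, 0.8), "invalid block_p_left")
  bad_row(tr$choice %in% c(-1, 0, 1), "invalid choice code")
  bad_row(tr$correct %in% c(0, 1), "invalid correct flag")
  bad_row(!(tr$correct == 1 & tr$choice == 0),
          "rewarded trial without a response")
  bad_row(tr$trial_duration_s > 0, "non-positive trial duration")
  bad_row(tr$trial_index >= 1 & tr$session_day >= 1,
          "non-positive trial_index or session_day")
  key <- paste(tr$lab_id, tr$mouse_id, tr$session_day, tr$trial_index)
  if (anyDuplicated(key))
    stop("schema error: duplicate trial key at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  tr[order(tr$lab_id, tr$mouse_id, tr$session_day, tr$trial_index), ,
     drop = FALSE]
}

#' Write a trials table as CSV
#' @param tr Trials data frame.
#' @param path Output path (written atomically via a temporary file).
#' @export
write_trials_table <- function(tr, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(tr[, trials_schema_cols], tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Parse a flat key-value configuration file
#'
#' Lines of the form `key: value` (or `key = value`); `#` starts a comment;
#' values are auto-typed to numeric where possible. Keys are namespaced
#' (`task.*`, `cohort.*`, `fit.*`, `classify.*`, `seed`).
#'
#' @param path Config file path.
#' @return Named list.
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  known_prefix <- c("seed", "task", "cohort", "fit", "classify", "simulate")
  pref <- sub("\\..*$", "", names(out))
  if (length(bad <- names(out)[!pref %in% known_prefix]))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  out
}

log_msg <- function(level, module, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  min_lv <- getOption("wheeltask.log_level", "info")
  if (lv[[level]] < lv[[min_lv]]) return(invisible())
  message(sprintf("%s [%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, module, paste0(...)))
}

parse_flags <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(argv) || startsWith(argv[i + 1], "--"))
      stop("flag ", a, " needs a value")
    out[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

#' Run a pipeline subcommand
#'
#' Dispatches `simulate`, `fit-psychometric`, `fit-glm`, `assess-status`,
#' or `classify-labs`. Common flags: `--seed`, `--config`, `--out-dir`,
#' `--log-level`. All randomness flows from the seed; outputs are written
#' atomically; structured logs go to standard error. Returns (invisibly)
#' a process-style exit status: 0 on success, 2 on usage error, 1 on
#' failure (with a machine-readable JSON error record on stderr).
#'
#' @param argv Character vector of command-line arguments, subcommand
#'   first.
#' @return Integer exit status, invisibly.
#' @export
run_pipeline <- function(argv) {
  cmds <- c("simulate", "fit-psychometric", "fit-glm", "assess-status",
            "classify-labs")
  if (length(argv) == 0 || !argv[1] %in% cmds) {
    message("usage: wheeltask <", paste(cmds, collapse = "|"),
            "> [--seed N] [--config FILE] [--out-dir DIR] [flags]")
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- parse_flags(argv[-1])
    if (!is.null(flags$`log-level`))
      options(wheeltask.log_level = flags$`log-level`)
    cfg <- if (!is.null(flags$config)) parse_config(flags$config) else list()
    seed <- as.integer(flags$seed %||% cfg$seed %||% 1)
    out_dir <- flags$`out-dir` %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    log_msg("info", "pipeline", "command=", argv[1], " seed=", seed)
    switch(argv[1],
      simulate = cmd_simulate(flags, cfg, out_dir),
      `fit-psychometric` = cmd_fit_psychometric(flags, out_dir),
      `fit-glm` = cmd_fit_glm(flags, out_dir),
      `assess-status` = cmd_assess_status(flags, out_dir),
      `classify-labs` = cmd_classify_labs(flags, out_dir))
    0L
  }, error = function(e) {
    message(jsonlite::toJSON(list(error = conditionMessage(e),
                                  command = argv[1]), auto_unbox = TRUE))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

cmd_simulate <- function(flags, cfg, out_dir) {
  config <- cohort_config(
    n_labs = cfg$cohort.n_labs %||% 2,
    mice_per_lab = cfg$cohort.mice_per_lab %||% 2,
    max_days = cfg$cohort.max_days %||% 10,
    continue_full = isTRUE((cfg$cohort.continue_full %||% 0) > 0))
  cohort <- simulate_cohort(config)
  write_trials_table(cohort$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(cohort$mice, file.path(out_dir, "mice.csv"),
                   row.names = FALSE)
  log_msg("info", "simulate", nrow(cohort$trials), " trials written")
}

cmd_fit_psychometric <- function(flags, out_dir) {
  tr <- read_trials_table(flags$trials)
  fit <- fit_psychometric(tr)
  write_json_atomic(list(params = unclass(fit$params), nll = fit$nll,
                         n_trials = fit$n_trials, converged = fit$converged),
                    file.path(out_dir, "psychometric_fit.json"))
}

cmd_fit_glm <- function(flags, out_dir) {
  tr <- read_trials_table(flags$trials)
  variant <- flags$variant %||% "basic"
  fit <- fit_choice_glm(build_design(tr, variant),
                        penalty_strength = as.numeric(flags$penalty %||% 1e-4))
  utils::write.csv(as.data.frame(build_design(tr, variant)$design),
                   file.path(out_dir, "design_matrix.csv"), row.names = FALSE)
  write_json_atomic(list(weights = as.list(fit$weights), nll = fit$nll,
                         condition_number = fit$condition_number,
                         n_trials = fit$n_trials),
                    file.path(out_dir, "glm_fit.json"))
}

cmd_assess_status <- function(flags, out_dir) {
  tr <- read_trials_table(flags$trials)
  version <- flags$version %||% "1a"
  reports <- lapply(split(tr, tr$mouse_id), function(m) {
    summ <- lapply(split(m, m$session_day), summarize_session)
    if (version == "full") {
      days <- sort(unique(m$session_day))
      st <- evaluate_full_proficiency(
        lapply(utils::tail(days, 3), function(d) m[m$session_day == d, ]))
    } else st <- evaluate_basic_proficiency(summ, version)
    list(status = st$status, day_reached = st$day_reached,
         reasons = as.list(st$reasons))
  })
  write_json_atomic(reports, file.path(out_dir, "status_report.json"))
}

cmd_classify_labs <- function(flags, out_dir) {
  feats <- utils::read.csv(flags$features, stringsAsFactors = FALSE)
  mode_ <- gsub("-", "_", flags$mode %||% "data")
  rep_ <- classify_labs(feats, flags$classifier %||% "naive_bayes",
                        n_repeats = as.integer(flags$repeats %||% 2000),
                        mode = mode_)
  utils::write.csv(rep_$confusion_matrix,
                   file.path(out_dir, "confusion_matrix.csv"))
  write_json_atomic(list(mean_accuracy = rep_$mean_accuracy,
                         accuracies = rep_$accuracies,
                         classifier = rep_$classifier_name, mode = rep_$mode),
                    file.path(out_dir, "classification_report.json"))
}
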