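# Automated proficiency criteria (basic 1a/1b and full task) and
# cohort-level learning summaries.

#' Summarise one session for the criteria engine
#'
#' Computes the trial count, easy-trial performance (|contrast| >= 50%;
#' no-response trials already carry `correct = 0` and so count as errors),
#' the fitted psychometric parameters, the median trial duration on
#' 0%-contrast trials (`NA` when the stage has no 0% trials), and the
#' session's stage.
#'
#' @param trials Trials table for a single session.
#' @param n_restarts Restarts passed to [fit_psychometric()].
#' @return A `session_summary` list.
#' @export
summarize_session <- function(trials, n_restarts = 3) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty trials table")
  easy <- abs(trials$signed_contrast) >= 50
  zero <- trials$signed_contrast == 0
  fit <- tryCatch(fit_psychometric(trials, n_restarts = n_restarts),
                  error = function(e) NULL)
  structure(list(
    n_trials = nrow(trials),
    perf_easy = if (any(easy)) mean(trials$correct[easy]) else NA_real_,
    fit = if (is.null(fit)) NULL else fit$params,
    median_rt_zero = if (any(zero))
      stats::median(trials$trial_duration_s[zero]) else NA_real_,
    stage_id = max(trials$stage_id)
  ), class = "session_summary")
}

basic_thresholds <- function(version) {
  if (version == "1a")
    list(n_trials = 200, perf_easy = 0.80, bias = 16, threshold = 19,
         lapse = 0.2, lapse_rule = "sum", rt_zero = NA)
  else
    list(n_trials = 400, perf_easy = 0.90, bias = 10, threshold = 20,
         lapse = 0.1, lapse_rule = "each", rt_zero = 2)
}

session_passes <- function(s, th) {
  if (is.null(s$fit)) return(c(n_trials = FALSE, perf_easy = FALSE,
                               bias = FALSE, threshold = FALSE,
                               lapse = FALSE))
  lapse_ok <- if (th$lapse_rule == "sum")
    (s$fit$gamma + s$fit$lambda) < th$lapse
  else s$fit$gamma < th$lapse && s$fit$lambda < th$lapse
  c(n_trials = s$n_trials > th$n_trials,
    perf_easy = !is.na(s$perf_easy) && s$perf_easy > th$perf_easy,
    bias = abs(s$fit$mu) < th$bias,
    threshold = s$fit$sigma < th$threshold,
    lapse = lapse_ok)
}

#' Evaluate basic-task proficiency (criteria 1a or 1b)
#'
#' A mouse is trained when three consecutive sessions each satisfy, for
#' 1a/1b respectively: > 200/400 trials; easy-trial performance > 80%/90%;
#' |bias| < 16/10% contrast; threshold < 19/20% contrast; lapses summing to
#' < 0.2 (1a) or each < 0.1 (1b); and all contrasts introduced (stage >= 3).
#' 1b additionally requires the median (across the three sessions) of the
#' per-session median 0%-contrast trial duration to be < 2 s.
#'
#' @param summaries Chronological list of [summarize_session()] results.
#' @param version `"1a"` or `"1b"`.
#' @param lapse_rule Override the lapse reading: `"sum"` or `"each"`.
#' @param day_limit Mice without proficiency after this many sessions are
#'   flagged `not_trained` (default 40, the drop-from-study rule).
#' @return A `proficiency_status` list: `status`, `day_reached`, `reasons`
#'   (per-criterion pass/fail for the most recent window).
#' @export
evaluate_basic_proficiency <- function(summaries, version = c("1a", "1b"),
                                       lapse_rule = NULL, day_limit = 40) {
  version <- match.arg(version)
  th <- basic_thresholds(version)
  if (!is.null(lapse_rule)) th$lapse_rule <- match.arg(lapse_rule,
                                                       c("sum", "each"))
  n <- length(summaries)
  if (n < 3)
    return(structure(list(status = "in_training", day_reached = NA_integer_,
                          reasons = c(insufficient_sessions = TRUE)),
                     class = "proficiency_status"))
  pass <- vapply(summaries, function(s) all(session_passes(s, th)), logical(1))
  if (version == "1b") {
    rt <- vapply(summaries, function(s)
      if (is.na(s$median_rt_zero)) Inf else s$median_rt_zero, numeric(1))
    win_rt <- vapply(3:n, function(d)
      stats::median(rt[(d - 2):d]) < th$rt_zero, logical(1))
  } else win_rt <- rep(TRUE, n - 2)
  # stage precondition: all contrasts introduced by the window's last session
  introduced <- vapply(summaries, function(s) s$stage_id >= 3, logical(1))
  win <- vapply(3:n, function(d) all(pass[(d - 2):d]), logical(1)) &
    win_rt & introduced[3:n]
  if (any(win)) {
    day <- which(win)[1] + 2L
    status <- paste0("trained_", version)
  } else {
    day <- NA_integer_
    status <- if (n >= day_limit) "not_trained" else "in_training"
  }
  reasons <- c(session_passes(summaries[[n]], th),
               contrasts_introduced = introduced[n])
  structure(list(status = status, day_reached = day, reasons = reasons),
            class = "proficiency_status")
}

#' Evaluate full-task proficiency
#'
#' Requires three full-task sessions: each with at least 400 trials and at
#' least 90% correct on 100%-contrast trials; pooling the three sessions,
#' the psychometric lapses fitted separately within 20:80 and 80:20 blocks
#' must each be below 0.1, the between-block bias shift |mu(20:80) -
#' mu(80:20)| must exceed 5% contrast, and the pooled median 0%-contrast
#' trial duration must be below 2 s (set `literal_rt = TRUE` for the
#' literal "over 2 s" reading).
#'
#' @param sessions List of exactly three full-task trials tables.
#' @param literal_rt Use the literal "> 2 s" reading of the reaction-time
#'   criterion instead of the competence-consistent "< 2 s".
#' @return A `proficiency_status` list.
#' @export
evaluate_full_proficiency <- function(sessions, literal_rt = FALSE) {
  if (length(sessions) != 3) stop("exactly three sessions are required")
  if (any(vapply(sessions, function(s) all(s$block_p_left == 0.5), logical(1))))
    stop("sessions must be full-task (biased blocks present)")
  per_ok <- vapply(sessions, function(s) {
    hi <- abs(s$signed_contrast) == 100
    nrow(s) >= 400 && any(hi) && mean(s$correct[hi]) >= 0.9
  }, logical(1))
  pooled <- do.call(rbind, lapply(sessions, function(s)
    s[, c("signed_contrast", "block_p_left", "choice", "correct",
          "trial_duration_s")]))
  fit_b <- function(p) tryCatch(
    fit_psychometric(pooled[pooled$block_p_left == p, ])$params,
    error = function(e) NULL)
  f20 <- fit_b(0.2); f80 <- fit_b(0.8)
  lapse_ok <- !is.null(f20) && !is.null(f80) &&
    all(c(f20$gamma, f20$lambda, f80$gamma, f80$lambda) < 0.1)
  shift_ok <- !is.null(f20) && !is.null(f80) && abs(f20$mu - f80$mu) > 5
  zero <- pooled$signed_contrast == 0
  mrt <- if (any(zero)) stats::median(pooled$trial_duration_s[zero]) else NA
  rt_ok <- !is.na(mrt) && if (literal_rt) mrt > 2 else mrt < 2
  reasons <- c(trials_and_easy = all(per_ok), lapse = lapse_ok,
               bias_shift = shift_ok, rt_zero = rt_ok)
  structure(list(
    status = if (all(reasons)) "full_proficient" else "in_training",
    day_reached = NA_integer_, reasons = reasons,
    block_fits = list(`0.2` = f20, `0.8` = f80)
  ), class = "proficiency_status")
}

#' Cohort learning summary
#'
#' Per-mouse days and trials to basic proficiency, per-lab medians and
#' quartiles, and the cumulative proportion trained by day as a
#' Kaplan-Meier (product-limit) estimate with non-learners censored at
#' their last training day.
#'
#' @param cohort A [simulate_cohort()] result, or a data frame with columns
#'   `lab_id`, `mouse_id`, `day_trained` (`NA` if never), `last_day`,
#'   `trials_to_trained`.
#' @return List with `per_mouse`, `per_lab`, and `km` (data frame of `day`
#'   and `cum_prop_trained`).
#' @export
training_summary <- function(cohort) {
  mice <- if (is.data.frame(cohort)) cohort else cohort$mice
  trained <- !is.na(mice$day_trained)
  time <- ifelse(trained, mice$day_trained, mice$last_day)
  sf <- survival::survfit(survival::Surv(time, trained) ~ 1)
  km <- data.frame(day = sf$time, cum_prop_trained = 1 - sf$surv)
  per_lab <- do.call(rbind, lapply(split(mice, mice$lab_id), function(m) {
    q <- stats::quantile(m$day_trained, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(lab_id = m$lab_id[1], n_mice = nrow(m),
               n_trained = sum(!is.na(m$day_trained)),
               q25 = q[1], median = q[2], q75 = q[3], row.names = NULL)
  }))
  list(per_mouse = mice, per_lab = per_lab, km = km)
}
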