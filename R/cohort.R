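# Synthetic training cohorts: per-mouse learning trajectories, per-lab
# learning-speed distributions, lab-independent trained behaviour.

#' Construct a learning trajectory
#'
#' Visual weights grow with cumulative trials t as
#' s(t) = initial_scale + (1 - initial_scale) * (1 - exp(-t / rate)),
#' a saturating exponential towards the asymptotic (trained) weights.
#'
#' @param rate Trials to half... strictly, the exponential time constant tau
#'   in trials (> 0).
#' @param initial_scale Fraction of asymptotic visual weights at trial 0.
#' @param asymptote_params [psych_params()] describing trained behaviour.
#' @param w_rewarded,w_unrewarded,w_block History/block weights of the
#'   generative agent (defaults: published basic-task values; block weight
#'   applies to the full phase).
#' @return A `learning_trajectory` list with calibrated basic and full
#'   agents attached.
#' @export
learning_trajectory <- function(rate, initial_scale = 0.05,
                                asymptote_params = default_trained_curve(),
                                w_rewarded = 0.19, w_unrewarded = 0.33,
                                w_rewarded_full = 0.42,
                                w_unrewarded_full = 0.46, w_block = 0.40) {
  stopifnot(rate > 0, initial_scale >= 0, initial_scale < 1)
  cal <- calibrate_visual_weights(asymptote_params)
  structure(list(
    rate = rate, initial_scale = initial_scale,
    asymptote_params = asymptote_params,
    agent_basic = agent_params(cal$visual_weights, w_rewarded, w_unrewarded,
                               w_bias = cal$w_bias),
    agent_full = agent_params(cal$visual_weights, w_rewarded_full,
                              w_unrewarded_full, w_bias = cal$w_bias,
                              w_block = w_block)
  ), class = "learning_trajectory")
}

#' Learning scale at cumulative trial count t
#' @param trajectory A [learning_trajectory()].
#' @param t Cumulative completed trials.
#' @export
learning_scale <- function(trajectory, t) {
  trajectory$initial_scale +
    (1 - trajectory$initial_scale) * (1 - exp(-t / trajectory$rate))
}

#' Simulate a mouse's full training course
#'
#' One session per day: the stage advances via [advance_training_stage()],
#' the agent's visual weights are scaled by the learning curve at the
#' mouse's cumulative trial count, and basic proficiency (criteria 1a) is
#' checked after every session. Training stops at proficiency or after
#' `max_days`. With `continue_full = TRUE`, a trained mouse moves to the
#' full task (biased blocks, no debiasing, full-task history weights) until
#' full proficiency or `max_full_days`.
#'
#' @param trajectory A [learning_trajectory()].
#' @param max_days Basic-phase day limit (drop rule: 40).
#' @param continue_full Continue into the full task once trained.
#' @param max_full_days Full-phase day limit.
#' @param config A [task_config()].
#' @param dur_model,count_model Duration and trial-count models.
#' @return List with `sessions` (one trials table, `session_day` column),
#'   `summaries`, `day_trained`, `day_full`, `status`, `trials_to_trained`.
#' @export
simulate_training_course <- function(trajectory, max_days = 40,
                                     continue_full = FALSE,
                                     max_full_days = 20,
                                     config = task_config(),
                                     dur_model = duration_model(),
                                     count_model = session_count_model()) {
  stopifnot(max_days >= 1)
  history <- list()
  sessions <- list()
  t_cum <- 0
  day_trained <- NA_integer_
  trials_to_trained <- NA_real_
  day <- 0L
  while (day < max_days && is.na(day_trained)) {
    day <- day + 1L
    stage <- advance_training_stage(history)
    agent <- scale_agent(trajectory$agent_basic,
                         learning_scale(trajectory, t_cum + 1))
    schedule <- build_session_schedule("basic", 1, config)
    tr <- simulate_session(agent, stage, schedule, "basic", config = config,
                           dur_model = dur_model, count_model = count_model)
    tr$session_day <- day
    sessions[[day]] <- tr
    history[[day]] <- summarize_session(tr)
    t_cum <- t_cum + nrow(tr)
    st <- evaluate_basic_proficiency(history, "1a", day_limit = max_days)
    if (st$status == "trained_1a") {
      day_trained <- st$day_reached
      trials_to_trained <- t_cum
    }
  }
  status <- if (!is.na(day_trained)) "trained_1a"
    else if (day >= 40) "not_trained" else "in_training"

  day_full <- NA_integer_
  if (continue_full && !is.na(day_trained)) {
    fday <- 0L
    full_stage <- training_stage(5, gain = 4, reward_volume = 1.5,
                                 debias_active = FALSE)
    while (fday < max_full_days && is.na(day_full)) {
      fday <- fday + 1L
      day <- day + 1L
      agent <- scale_agent(trajectory$agent_full,
                           learning_scale(trajectory, t_cum + 1))
      n_target <- sample_session_count(count_model)
      schedule <- build_session_schedule("full", n_target, config)
      tr <- simulate_session(agent, full_stage, schedule, "full",
                             n_target = n_target, config = config,
                             dur_model = dur_model, count_model = count_model)
      tr$session_day <- day
      sessions[[day]] <- tr
      history[[day]] <- summarize_session(tr)
      t_cum <- t_cum + nrow(tr)
      if (fday >= 3) {
        st <- tryCatch(
          evaluate_full_proficiency(sessions[(day - 2):day]),
          error = function(e) NULL)
        if (!is.null(st) && st$status == "full_proficient") day_full <- day
      }
    }
    if (!is.na(day_full)) status <- "full_proficient"
  }

  list(sessions = do.call(rbind, sessions), summaries = history,
       day_trained = day_trained, day_full = day_full, status = status,
       trials_to_trained = trials_to_trained, last_day = day)
}

#' Default cohort configuration
#'
#' Seven labs of 20 mice (the published cohort had 140 mice across seven
#' labs in three countries; timezone groups of sizes 3/2/2). Lab identity
#' affects only the learning-rate distribution; trained behaviour is drawn
#' per mouse from one cross-lab distribution centred on the published
#' trained-state summaries (summed lapse 0.095, threshold 14.3, bias 0.3,
#' with the printed spreads).
#'
#' @param n_labs Number of labs (>= 2).
#' @param mice_per_lab Mice per lab (>= 2).
#' @param lab_tau_mean Per-lab mean learning time constants, in trials;
#'   recycled/truncated to `n_labs`.
#' @param tau_sdlog Within-lab log-scale spread of tau.
#' @param history_jitter_sd Per-mouse jitter (s.d.) on history weights.
#' @param asym_sd_scale Scale on the trained-state trait spreads (1 =
#'   the printed cohort s.d.; smaller values reduce trait-driven
#'   attrition, useful for controlled experiments on learning rates).
#' @param lab_effect_sd Lab-level shift (s.d. units of the trait spread)
#'   injected into trained-state behaviour; 0 = homogeneous (default).
#' @param max_days,continue_full,max_full_days Passed to
#'   [simulate_training_course()].
#' @param count_model Trials-per-session model.
#' @export
cohort_config <- function(n_labs = 7, mice_per_lab = 20,
                          lab_tau_mean = c(2500, 3500, 4500, 5500, 6500,
                                           8000, 10000),
                          tau_sdlog = 0.4,
                          history_jitter_sd = 0.05,
                          asym_sd_scale = 1,
                          lab_effect_sd = 0,
                          max_days = 40, continue_full = FALSE,
                          max_full_days = 20,
                          count_model = session_count_model()) {
  stopifnot(n_labs >= 2, mice_per_lab >= 2)
  lab_tau_mean <- rep_len(lab_tau_mean, n_labs)
  as.list(environment())
}

#' Timezone-group labels for the labs
#'
#' Fixed group sizes 3/2/2 for seven labs (three countries); for other lab
#' counts, groups of roughly equal size.
#' @param n_labs Number of labs.
#' @export
timezone_groups <- function(n_labs = 7) {
  sizes <- if (n_labs == 7) c(3, 2, 2) else
    diff(floor(seq(0, n_labs, length.out = 4)))
  rep(paste0("tz", seq_along(sizes)), times = sizes)
}

rtrunc_norm1 <- function(mean, sd, lo, hi)
  truncnorm::rtruncnorm(1, a = lo, b = hi, mean = mean, sd = sd)

#' Simulate a synthetic training cohort
#'
#' Per-mouse learning time constants are log-normal around the lab's mean;
#' trained-state psychometric targets are drawn from one cross-lab
#' distribution (no lab effect unless `lab_effect_sd > 0`, which injects a
#' lab-level mean shift into threshold and bias for sensitivity analyses).
#' All randomness flows through R's RNG: call `set.seed()` first (or use
#' `seed`) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A `cohort_data` list: `labs`, `mice` (per-mouse outcomes),
#'   `trials` (one table), `ground_truth` (per-mouse trajectories).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- data.frame(
    lab_id = sprintf("lab%d", seq_len(config$n_labs)),
    n_mice = config$mice_per_lab,
    learning_rate_mean = config$lab_tau_mean,
    timezone_group = timezone_groups(config$n_labs)
  )
  mice <- list(); trials <- list(); gt <- list()
  for (L in seq_len(config$n_labs)) {
    lab <- labs$lab_id[L]
    thr_shift <- config$lab_effect_sd * 3.8 * stats::rnorm(1)
    bias_shift_ <- config$lab_effect_sd * 8.4 * stats::rnorm(1)
    for (k in seq_len(config$mice_per_lab)) {
      mouse <- sprintf("%s_m%02d", lab, k)
      tau <- stats::rlnorm(1, log(config$lab_tau_mean[L]), config$tau_sdlog)
      ssc <- config$asym_sd_scale
      lapse_sum <- rtrunc_norm1(0.095, 0.036 * ssc, 0.01, 0.35)
      split <- stats::rbeta(1, 8, 8)
      target <- psych_params(
        gamma = min(lapse_sum * split, 0.45),
        lambda = min(lapse_sum * (1 - split), 0.45),
        mu = rtrunc_norm1(0.3 + bias_shift_, 8.4 * ssc, -25, 25),
        sigma = rtrunc_norm1(14.3 + thr_shift, 3.8 * ssc, 5, 40))
      traj <- learning_trajectory(
        rate = tau, asymptote_params = target,
        w_rewarded = 0.19 + stats::rnorm(1, 0, config$history_jitter_sd),
        w_unrewarded = 0.33 + stats::rnorm(1, 0, config$history_jitter_sd),
        w_rewarded_full = 0.42 + stats::rnorm(1, 0, config$history_jitter_sd),
        w_unrewarded_full = 0.46 + stats::rnorm(1, 0, config$history_jitter_sd))
      course <- simulate_training_course(
        traj, max_days = config$max_days,
        continue_full = config$continue_full,
        max_full_days = config$max_full_days,
        count_model = config$count_model)
      tr <- course$sessions
      tr$lab_id <- lab
      tr$mouse_id <- mouse
      trials[[mouse]] <- tr
      mice[[mouse]] <- data.frame(
        lab_id = lab, mouse_id = mouse, tau = tau,
        day_trained = course$day_trained, day_full = course$day_full,
        last_day = course$last_day, status = course$status,
        trials_to_trained = course$trials_to_trained)
      gt[[mouse]] <- traj
    }
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  structure(list(labs = labs, mice = do.call(rbind, mice),
                 trials = trials, ground_truth = gt),
            class = "cohort_data")
}
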