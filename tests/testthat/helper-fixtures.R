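# Shared fixtures, built in code and cached for the duration of the run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, expr, .fixture_env)
  get(name, .fixture_env)
}

# Three trained-stage sessions from the default agent, one "mouse".
trained_sessions <- function(variant, n_mice = 1, n_per_session = 700,
                             seed = 101) {
  set.seed(seed)
  agent <- default_agent_params(variant)
  stage <- training_stage(5, gain = 4, reward_volume = 1.5,
                          debias_active = (variant == "basic"))
  do.call(rbind, lapply(seq_len(n_mice), function(m) {
    do.call(rbind, lapply(1:3, function(day) {
      sch <- build_session_schedule(variant, n_per_session)
      tr <- simulate_session(agent, stage, sch, variant,
                             n_target = n_per_session)
      tr$session_day <- day
      tr$mouse_id <- sprintf("m%02d", m)
      tr$lab_id <- "lab1"
      tr
    }))
  }))
}

# Fast-learning homogeneous cohort: default trained-state distribution,
# small learning time constants so nearly every mouse trains quickly.
# Used by the classification and cross-lab tests (scaled down for runtime).
fast_cohort <- function() memo("fast_cohort", {
  set.seed(424)
  simulate_cohort(cohort_config(
    mice_per_lab = 16, lab_tau_mean = rep(1200, 7), tau_sdlog = 0.25,
    max_days = 18))
})

fast_features <- function() memo("fast_features", {
  suppressMessages(featurize_mice(fast_cohort(), "basic"))
})

# Complete trials table satisfying the I/O schema.
schema_trials <- function(n = 20, seed = 7) {
  set.seed(seed)
  data.frame(
    lab_id = "lab1", mouse_id = "m01", session_day = 1L,
    trial_index = seq_len(n),
    signed_contrast = sample(c(-100, -25, 0, 25, 100), n, replace = TRUE),
    block_p_left = 0.5,
    choice = sample(c(-1L, 1L), n, replace = TRUE),
    correct = sample(0:1, n, replace = TRUE),
    trial_duration_s = round(stats::runif(n, 0.2, 1.5), 3),
    is_repeat = 0L, stage_id = 5L
  )
}

# Session summary with given metrics (for criteria-engine unit tests).
mk_summary <- function(n_trials = 500, perf_easy = 0.95, gamma = 0.03,
                       lambda = 0.03, mu = 1, sigma = 14, rt_zero = 1,
                       stage_id = 5) {
  structure(list(n_trials = n_trials, perf_easy = perf_easy,
                 fit = psych_params(gamma, lambda, mu, sigma),
                 median_rt_zero = rt_zero, stage_id = stage_id),
            class = "session_summary")
}
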