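# Simulation-and-refit study: the package's main self-validation surface.

#' Simulate trained mice and refit the choice model
#'
#' For each synthetic mouse, simulates `n_sessions` trained-stage sessions
#' from the default generative agent of the given task variant, builds the
#' per-mouse design matrix (sessions stacked; history does not cross
#' session boundaries), fits the penalized choice model, and records the
#' recovered weights and the design's 2-norm condition number.
#'
#' @param variant `"basic"` or `"full"`.
#' @param n_mice Number of synthetic mice.
#' @param n_sessions Sessions per mouse.
#' @param n_trials Trials per session.
#' @param penalty_strength Passed to [fit_choice_glm()].
#' @param agent Generative agent; defaults to [default_agent_params()].
#' @return List with `weights` (mice x coefficients matrix),
#'   `condition_numbers`, and `agent` (the generative truth).
#' @export
simulate_refit_study <- function(variant = c("basic", "full"), n_mice = 20,
                                 n_sessions = 3, n_trials = 700,
                                 penalty_strength = 1e-6, agent = NULL) {
  variant <- match.arg(variant)
  if (is.null(agent)) agent <- default_agent_params(variant)
  stage <- training_stage(5, gain = 4, reward_volume = 1.5,
                          debias_active = (variant == "basic"))
  res <- lapply(seq_len(n_mice), function(m) {
    tr <- do.call(rbind, lapply(seq_len(n_sessions), function(day) {
      sch <- build_session_schedule(variant, n_trials)
      s <- simulate_session(agent, stage, sch, variant, n_target = n_trials)
      s$session_day <- day
      s
    }))
    tr$mouse_id <- sprintf("m%03d", m)
    tr$lab_id <- "sim"
    d <- build_design(tr, variant)
    fit <- fit_choice_glm(d, penalty_strength = penalty_strength)
    list(w = fit$weights, cn = fit$condition_number)
  })
  list(weights = do.call(rbind, lapply(res, `[[`, "w")),
       condition_numbers = vapply(res, `[[`, numeric(1), "cn"),
       agent = agent)
}
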