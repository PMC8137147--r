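# Generative choice agent: the trial-history logistic model used as the
# data-generating process, calibrated so that a trained, history-free agent
# reproduces a target erf psychometric curve.

#' Construct agent parameters for the logistic choice model
#'
#' The decision variable is z = sum_c W_c I_c + W_r r + W_u u + W_0 (+ W_b b)
#' and P(right) = 1 / (1 + exp(-z)). `visual_weights` must be named by
#' nonzero contrast magnitude (e.g. `"6.25"`).
#'
#' @param visual_weights Named numeric vector of per-contrast weights W_c.
#' @param w_rewarded Weight W_r on the previous rewarded choice.
#' @param w_unrewarded Weight W_u on the previous unrewarded choice.
#' @param w_bias Constant W_0.
#' @param w_block Block-prior weight W_b (full task; 0 for the basic task).
#' @return An `agent_params` list.
#' @export
agent_params <- function(visual_weights, w_rewarded, w_unrewarded,
                         w_bias = 0, w_block = 0) {
  stopifnot(length(visual_weights) >= 1, !is.null(names(visual_weights)),
            all(is.finite(c(visual_weights, w_rewarded, w_unrewarded,
                            w_bias, w_block))))
  structure(list(visual_weights = visual_weights, w_rewarded = w_rewarded,
                 w_unrewarded = w_unrewarded, w_bias = w_bias,
                 w_block = w_block), class = "agent_params")
}

#' Calibrate visual weights to a target psychometric curve
#'
#' For each nonzero magnitude c, W_c = (logit P(+c) - logit P(-c)) / 2 and
#' the bias weight is the average of (logit P(+c) + logit P(-c)) / 2 across
#' magnitudes, where P is the target curve. A history-free agent with these
#' weights reproduces the target curve exactly at the sampled contrasts.
#' 0% contrast gets no weight (it carries no visual signal).
#'
#' @param target A [psych_params()] target curve.
#' @param magnitudes Nonzero contrast magnitudes to calibrate.
#' @return List with `visual_weights` (named) and `w_bias`.
#' @export
calibrate_visual_weights <- function(target,
                                     magnitudes = c(6.25, 12.5, 25, 50, 100)) {
  stopifnot(target$gamma < 0.5, target$lambda < 0.5, all(magnitudes > 0))
  p_pos <- psych_eval(target, magnitudes)
  p_neg <- psych_eval(target, -magnitudes)
  if (any(p_pos %in% c(0, 1)) || any(p_neg %in% c(0, 1)))
    stop("target curve saturates at 0 or 1: infinite logit")
  lp <- stats::qlogis(p_pos)
  ln <- stats::qlogis(p_neg)
  w <- (lp - ln) / 2
  names(w) <- as.character(magnitudes)
  list(visual_weights = w, w_bias = mean((lp + ln) / 2))
}

#' Default target psychometric curve of a trained mouse
#'
#' Centred on the trained-state cohort summaries: summed lapse 0.095 split
#' evenly, threshold 14.3% contrast, bias 0.3% contrast.
#' @export
default_trained_curve <- function() psych_params(0.0475, 0.0475, 0.3, 14.3)

#' Default generative agent parameters
#'
#' Visual weights are calibrated from [default_trained_curve()]; history
#' weights are the published fitted values (basic: W_r = 0.19, W_u = 0.33;
#' full: W_r = 0.42, W_u = 0.46). The full-task block weight W_b = 0.40 was
#' calibrated once by simulation so that the 0%-contrast bias shift between
#' block types lands near the 28.5 percentage-point cohort average.
#'
#' @param variant `"basic"` or `"full"`.
#' @return An [agent_params()] object.
#' @export
default_agent_params <- function(variant = c("basic", "full")) {
  variant <- match.arg(variant)
  cal <- calibrate_visual_weights(default_trained_curve())
  if (variant == "basic")
    agent_params(cal$visual_weights, w_rewarded = 0.19, w_unrewarded = 0.33,
                 w_bias = cal$w_bias)
  else
    agent_params(cal$visual_weights, w_rewarded = 0.42, w_unrewarded = 0.46,
                 w_bias = cal$w_bias, w_block = 0.40)
}

#' Probability of a rightward choice for one trial
#'
#' @param agent An [agent_params()] object.
#' @param signed_contrast Signed contrast in percent.
#' @param prev Previous trial as a list with `choice` (+1/-1/0) and `correct`
#'   (0/1), or `NULL` (start of session: r = u = 0).
#' @param block_label +1 in 20:80 blocks, -1 in 80:20 blocks, 0 unbiased.
#' @return Probability in (0, 1).
#' @export
agent_choice_prob <- function(agent, signed_contrast, prev = NULL,
                              block_label = 0) {
  mag <- abs(signed_contrast)
  vis <- 0
  if (mag > 0) {
    w <- agent$visual_weights[as.character(mag)]
    if (is.na(w)) stop("no visual weight for contrast magnitude ", mag)
    vis <- unname(w) * sign(signed_contrast)
  }
  r <- u <- 0
  if (!is.null(prev) && prev$choice != 0) {
    if (prev$correct == 1) r <- prev$choice else u <- prev$choice
  }
  z <- vis + agent$w_rewarded * r + agent$w_unrewarded * u + agent$w_bias +
    agent$w_block * block_label
  1 / (1 + exp(-z))
}

#' Trial-duration model
#'
#' Log-normal with a configurable median and log-scale dispersion, floored at
#' 0.05 s. Defaults reproduce the published summary (median 468 ms, s.d.
#' about 220 ms).
#'
#' @param median_s Median duration in seconds.
#' @param sdlog Log-scale standard deviation.
#' @export
duration_model <- function(median_s = 0.468, sdlog = 0.42) {
  list(median_s = median_s, sdlog = sdlog)
}

#' Sample trial durations (stimulus onset to feedback)
#' @param n Number of draws.
#' @param model A [duration_model()].
#' @return Durations in seconds, all >= 0.05.
#' @export
sample_trial_duration <- function(n = 1, model = duration_model()) {
  if (model$sdlog == 0) return(pmax(rep(model$median_s, n), 0.05))
  pmax(stats::rlnorm(n, log(model$median_s), model$sdlog), 0.05)
}

#' Trials-per-session count model
#'
#' Empirical model: truncated normal with mean 719, s.d. 223, bounds
#' \[50, 1400\], matching the published per-session trial counts.
#'
#' @param mean_trials,sd_trials,min_trials,max_trials Truncated-normal
#'   parameters.
#' @export
session_count_model <- function(mean_trials = 719, sd_trials = 223,
                                min_trials = 50, max_trials = 1400) {
  as.list(environment())
}

sample_session_count <- function(model = session_count_model()) {
  round(truncnorm::rtruncnorm(1, a = model$min_trials, b = model$max_trials,
                              mean = model$mean_trials, sd = model$sd_trials))
}

#' Simulate one session of the task
#'
#' Runs the trial loop: stimulus sampling (with debiasing repeats when the
#' stage allows), Bernoulli choices from [agent_choice_prob()], reward
#' assignment (0%-contrast trials carry a hidden correct side drawn from the
#' block prior), duration sampling, and the session-ending rules. The session
#' stops at the drawn trial budget or when [should_end_session()] fires.
#'
#' @param agent An [agent_params()] object.
#' @param stage A [training_stage()].
#' @param schedule A [build_session_schedule()] result.
#' @param task_variant `"basic"` or `"full"`.
#' @param n_target Trial budget; drawn from `count_model` if `NULL`.
#' @param config A [task_config()].
#' @param dur_model A [duration_model()].
#' @param count_model A [session_count_model()].
#' @return Trials data frame (`trial_index`, `signed_contrast`,
#'   `block_p_left`, `choice`, `correct`, `trial_duration_s`, `is_repeat`,
#'   `stage_id`) with attribute `end_reason`.
#' @export
simulate_session <- function(agent, stage, schedule,
                             task_variant = c("basic", "full"),
                             n_target = NULL, config = task_config(),
                             dur_model = duration_model(),
                             count_model = session_count_model()) {
  task_variant <- match.arg(task_variant)
  if (is.null(n_target)) n_target <- sample_session_count(count_model)

  p_left <- expand_schedule(schedule, n_target)
  b_lab <- ifelse(p_left == 0.2, 1L, ifelse(p_left == 0.8, -1L, 0L))
  mags <- stage$contrast_magnitudes
  wprob <- contrast_weights(mags, task_variant)
  wv <- agent$visual_weights
  vis_w <- vapply(mags, function(m)
    if (m == 0) 0 else unname(wv[as.character(m)]), numeric(1))
  if (anyNA(vis_w)) stop("agent lacks visual weights for the active stage")

  quiescence <- sample_quiescence(n_target)
  durs <- sample_trial_duration(n_target, dur_model)
  # presampled uniforms for magnitude, side, choice, repeat gate, hidden side
  u_mag <- stats::runif(n_target)
  u_side <- stats::runif(n_target)
  u_choice <- stats::runif(n_target)
  u_rep <- stats::runif(n_target)
  cum_w <- cumsum(wprob)

  sc <- numeric(n_target); choice <- integer(n_target)
  correct <- integer(n_target); isrep <- integer(n_target)
  elapsed <- 0; baseline <- NA_real_
  r <- 0; u <- 0
  end_reason <- "target_reached"
  n_done <- 0L
  debias <- stage$debias_active && task_variant == "basic"

  for (i in seq_len(n_target)) {
    # stimulus: debias repeat or fresh draw
    if (debias && i > 1L && correct[i - 1L] == 0L &&
        abs(sc[i - 1L]) >= 50 && u_rep[i] < config$p_repeat) {
      sci <- sc[i - 1L]
      isrep[i] <- 1L
    } else {
      mag <- mags[which(u_mag[i] <= cum_w)[1L]]
      side <- if (u_side[i] < p_left[i]) -1 else 1
      sci <- mag * side
    }
    sc[i] <- sci
    mag_i <- abs(sci)
    vis <- if (mag_i > 0) vis_w[match(mag_i, mags)] * sign(sci) else 0
    z <- vis + agent$w_rewarded * r + agent$w_unrewarded * u +
      agent$w_bias + agent$w_block * b_lab[i]
    ch <- if (u_choice[i] < 1 / (1 + exp(-z))) 1L else -1L
    choice[i] <- ch
    correct_side <- if (mag_i > 0) sign(sci)
      else if (u_side[i] < p_left[i]) -1 else 1
    correct[i] <- as.integer(ch == correct_side)
    if (correct[i] == 1L) { r <- ch; u <- 0 } else { r <- 0; u <- ch }

    n_done <- i
    elapsed <- elapsed + quiescence[i] + durs[i] +
      if (correct[i] == 1L) config$iti_correct_s else config$iti_error_s
    if (i == config$baseline_window)
      baseline <- stats::median(durs[seq_len(i)])
    dec <- should_end_session(list(
      elapsed_s = elapsed, n_completed = n_done,
      baseline_duration_s = baseline,
      rolling_durations = durs[max(1L, i - config$rolling_window + 1L):i]
    ), config)
    if (dec$end) { end_reason <- dec$reason; break }
  }

  idx <- seq_len(n_done)
  out <- data.frame(
    trial_index = idx,
    signed_contrast = sc[idx],
    block_p_left = p_left[idx],
    choice = choice[idx],
    correct = correct[idx],
    trial_duration_s = durs[idx],
    is_repeat = isrep[idx],
    stage_id = stage$stage_id
  )
  attr(out, "end_reason") <- end_reason
  out
}

#' Scale an agent's visual weights by a learning factor
#' @param agent An [agent_params()] object.
#' @param s Scale in \[0, 1\] applied to the visual weights.
#' @keywords internal
scale_agent <- function(agent, s) {
  agent$visual_weights <- agent$visual_weights * s
  agent
}
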