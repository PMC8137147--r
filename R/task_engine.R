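# Trial-by-trial task protocol: stimulus staging, bias blocks, debiasing,
# quiescence, and session-ending rules. Everything here is agent-independent.

#' Contrast sets of the automated training stages
#'
#' Stage 0 starts with the two easiest contrasts; 25%, 12.5% and finally
#' \{6.25%, 0%\} are added as performance improves; 50% is then transiently
#' dropped to boost the proportion of hard trials, and re-included at the
#' trained stage.
#' @keywords internal
stage_contrast_sets <- list(
  c(50, 100),
  c(25, 50, 100),
  c(12.5, 25, 50, 100),
  c(0, 6.25, 12.5, 25, 50, 100),
  c(0, 6.25, 12.5, 25, 100),
  c(0, 6.25, 12.5, 25, 50, 100)
)

#' All stimulus contrast magnitudes used by the task (percent)
#' @export
contrast_levels <- function() c(0, 6.25, 12.5, 25, 50, 100)

#' Construct a training-stage descriptor
#'
#' @param stage_id Integer 0..5 indexing the staged contrast sets.
#' @param gain Wheel gain in degrees of visual angle per mm of wheel travel
#'   (8 early in training, 4 once a session exceeds 200 trials).
#' @param reward_volume Water reward in microlitres, between 1.5 and 3.
#' @param debias_active Whether incorrect easy trials trigger repeat trials.
#' @return A `training_stage` list with the stage's contrast magnitudes.
#' @export
training_stage <- function(stage_id, gain = 8, reward_volume = 3,
                           debias_active = TRUE) {
  stopifnot(stage_id %in% 0:5, gain %in% c(8, 4),
            reward_volume >= 1.5, reward_volume <= 3)
  structure(list(
    stage_id = as.integer(stage_id),
    contrast_magnitudes = stage_contrast_sets[[stage_id + 1L]],
    gain = gain,
    reward_volume = reward_volume,
    debias_active = isTRUE(debias_active)
  ), class = "training_stage")
}

#' Task protocol configuration
#'
#' Defaults encode the published protocol: biased-block lengths geometric with
#' mean parameter 1/60 truncated to \[20, 100\] (giving the printed average of
#' 51), 90 unbiased lead-in trials, sessions capped at 90 min, ended early
#' after 45 min with fewer than 400 trials or when responses slow to five
#' times baseline.
#'
#' @param p_geometric Success probability of the block-length geometric.
#' @param block_min,block_max Truncation bounds for biased-block lengths.
#' @param first_block_len Length of the unbiased lead-in block (full task).
#' @param p_repeat Probability that an incorrect easy trial is repeated.
#' @param session_max_min Hard session cap in minutes.
#' @param low_count_min,low_count_threshold End the session after this many
#'   minutes if fewer than this many trials were completed.
#' @param slowdown_factor Rolling-median trial duration relative to baseline
#'   at which the session ends.
#' @param baseline_window Number of initial trials defining baseline duration.
#' @param rolling_window Rolling window (trials) for the slowdown rule.
#' @param iti_correct_s,iti_error_s Inter-trial intervals (error trials incur
#'   a 2 s timeout).
#' @export
task_config <- function(p_geometric = 1 / 60, block_min = 20, block_max = 100,
                        first_block_len = 90, p_repeat = 0.9,
                        session_max_min = 90, low_count_min = 45,
                        low_count_threshold = 400, slowdown_factor = 5,
                        baseline_window = 20, rolling_window = 10,
                        iti_correct_s = 1, iti_error_s = 2) {
  as.list(environment())
}

#' Sample biased-block lengths from a truncated geometric distribution
#'
#' Lengths follow the geometric distribution on \{1, 2, ...\} conditioned on
#' lying in `[lo, hi]` (renormalised pmf, equivalent to rejection sampling --
#' not clipping, which would pile mass at `lo`). Sampling is by inversion of
#' the conditional CDF, exact and loop-free.
#'
#' @param n Number of lengths to draw.
#' @param p Geometric success probability in (0, 1).
#' @param lo,hi Inclusive truncation bounds (trial counts).
#' @return Integer vector of `n` block lengths in `[lo, hi]`.
#' @export
sample_block_lengths <- function(n, p = 1 / 60, lo = 20, hi = 100) {
  if (lo > hi) stop("`lo` must not exceed `hi`")
  if (p >= 1) {
    if (lo > 1) stop("infeasible support: geometric with p >= 1 has all mass at 1")
    return(rep(1L, n))
  }
  if (p <= 0) stop("`p` must be in (0, 1)")
  q <- 1 - p
  m <- hi - lo + 1          # support size after conditioning on k >= lo
  u <- stats::runif(n)
  # memorylessness: k = (lo - 1) + j with j ~ Geom(p) conditioned on j <= m
  j <- ceiling(log1p(-u * (1 - q^m)) / log(q))
  as.integer(lo - 1 + pmin(pmax(j, 1), m))
}

#' Exact pmf of the truncated geometric block-length distribution
#' @inheritParams sample_block_lengths
#' @return Probabilities for lengths `lo:hi`, summing to 1.
#' @export
block_length_pmf <- function(p = 1 / 60, lo = 20, hi = 100) {
  k <- lo:hi
  w <- (1 - p)^(k - 1) * p
  w / sum(w)
}

#' Build the block schedule for one session
#'
#' Full task: a 90-trial unbiased block, then strictly alternating 20:80 /
#' 80:20 blocks (stimulus-left probability 0.2 or 0.8) with truncated-
#' geometric lengths, extended until the cumulative length covers
#' `max_trials`; the side of the first biased block is chosen uniformly at
#' random. Basic task: a single unbiased block.
#'
#' @param task_variant `"basic"` or `"full"`.
#' @param max_trials Minimum number of trials the schedule must cover.
#' @param config A [task_config()] list.
#' @return Data frame with columns `p_left` and `length` (class
#'   `block_schedule`).
#' @export
build_session_schedule <- function(task_variant = c("full", "basic"),
                                   max_trials, config = task_config()) {
  task_variant <- match.arg(task_variant)
  stopifnot(max_trials >= 1)
  if (task_variant == "basic") {
    out <- data.frame(p_left = 0.5, length = Inf)
  } else {
    p_left <- numeric(0)
    len <- numeric(0)
    total <- min(config$first_block_len, max_trials)
    side <- sample(1:2, 1)                 # exact values; 1 - p accumulates
    sides <- c(0.2, 0.8)                   # floating-point error
    while (total < max_trials) {
      l <- sample_block_lengths(1, config$p_geometric,
                                config$block_min, config$block_max)
      p_left <- c(p_left, sides[side])
      len <- c(len, l)
      total <- total + l
      side <- 3L - side
    }
    out <- data.frame(p_left = c(0.5, p_left),
                      length = c(config$first_block_len, len))
  }
  class(out) <- c("block_schedule", "data.frame")
  out
}

#' Per-trial stimulus-left probabilities implied by a schedule
#' @param schedule A [build_session_schedule()] result.
#' @param n_trials Number of trials to expand to.
#' @keywords internal
expand_schedule <- function(schedule, n_trials) {
  len <- pmin(schedule$length, n_trials)
  p <- rep(schedule$p_left, times = len)
  if (length(p) < n_trials)           # single infinite/basic block
    p <- c(p, rep(schedule$p_left[nrow(schedule)], n_trials - length(p)))
  p[seq_len(n_trials)]
}

#' Contrast-magnitude sampling weights for a stage
#'
#' Basic task: uniform over signed stimuli, i.e. every nonzero magnitude has
#' weight 2 (left + right) and 0% has weight 1, so with the final six-contrast
#' set P(0%) = 1/11. Full task: the 0% weight is doubled so that P(0%) matches
#' each nonzero magnitude's total probability (1/6 with six magnitudes).
#' @keywords internal
contrast_weights <- function(magnitudes, task_variant) {
  if (length(magnitudes) == 0) stop("stage has an empty contrast set")
  w <- ifelse(magnitudes == 0, 1, 2)
  if (task_variant == "full") w[magnitudes == 0] <- 2
  w / sum(w)
}

#' Sample one trial's stimulus specification
#'
#' Draws contrast magnitude (per [contrast_weights()]), stimulus side
#' (Bernoulli with the block's stimulus-left probability), and the quiescence
#' period. If debiasing is active and the previous trial was an incorrect
#' easy trial (|contrast| >= 50), the previous stimulus is repeated with
#' probability `p_repeat`.
#'
#' @param stage A [training_stage()].
#' @param block_p_left Stimulus-left probability of the enclosing block.
#' @param prev Previous trial as a list with `signed_contrast` and `correct`,
#'   or `NULL` at the start of a session.
#' @param task_variant `"basic"` or `"full"`.
#' @param config A [task_config()] list.
#' @return List with `signed_contrast`, `p_left`, `is_repeat`, `quiescence_s`.
#' @export
sample_trial_stimulus <- function(stage, block_p_left, prev = NULL,
                                  task_variant = "basic",
                                  config = task_config()) {
  mags <- stage$contrast_magnitudes
  probs <- contrast_weights(mags, task_variant)
  is_repeat <- FALSE
  if (stage$debias_active && !is.null(prev) && prev$correct == 0 &&
      abs(prev$signed_contrast) >= 50 &&
      stats::runif(1) < config$p_repeat) {
    sc <- prev$signed_contrast
    is_repeat <- TRUE
  } else {
    mag <- sample(mags, 1, prob = probs)
    side <- if (stats::runif(1) < block_p_left) -1 else 1
    sc <- mag * side                   # 0% contrast stays 0 either side
  }
  list(signed_contrast = sc, p_left = block_p_left, is_repeat = is_repeat,
       quiescence_s = sample_quiescence(1))
}

#' Sample pre-trial quiescence periods
#'
#' Exponential with mean 0.55 s, rejected until within \[0.4, 0.7\] s (the
#' wheel must be held still for this long before stimulus onset).
#'
#' @param n Number of draws.
#' @return Numeric vector of durations in seconds.
#' @export
sample_quiescence <- function(n = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rexp(2 * (n - length(out)) + 8, rate = 1 / 0.55)
    out <- c(out, x[x >= 0.4 & x <= 0.7])
  }
  out[seq_len(n)]
}

#' Advance the automated training stage from session history
#'
#' Deterministic staging: each session with more than 200 completed trials
#' and easy-trial performance of at least 0.7 advances the contrast set by
#' one step (two steps when performance is at least 0.9, mirroring the
#' protocol's ability to introduce several contrasts on one day). The wheel
#' gain is halved (8 -> 4 deg/mm) after the first session with more than 200
#' trials, and the reward volume decreases from 3 uL in 0.25 uL decrements
#' per qualifying session down to 1.5 uL.
#'
#' @param history List of session summaries (each with `n_trials` and
#'   `perf_easy`), in chronological order; may be empty.
#' @return The [training_stage()] for the next session.
#' @export
advance_training_stage <- function(history) {
  stage_id <- 0L
  n_qualifying <- 0L
  for (s in history) {
    if (is.na(s$perf_easy) || s$n_trials <= 200) next
    n_qualifying <- n_qualifying + 1L
    if (s$perf_easy >= 0.9) stage_id <- stage_id + 2L
    else if (s$perf_easy >= 0.7) stage_id <- stage_id + 1L
    stage_id <- min(stage_id, 5L)
  }
  gain <- if (n_qualifying > 0) 4 else 8
  reward <- max(1.5, 3 - 0.25 * n_qualifying)
  training_stage(stage_id, gain = gain, reward_volume = reward)
}

#' Decide whether a session should end
#'
#' Three rules, in order of precedence: the 90-min hard cap (`"max_time"`);
#' 45 min elapsed with fewer than 400 completed trials (`"low_count"`); the
#' rolling median of the last 10 trial durations exceeding five times the
#' baseline duration (`"slow_responses"`). The slowdown rule is inactive
#' until both the baseline and a full rolling window exist.
#'
#' @param clock List with `elapsed_s`, `n_completed`, `baseline_duration_s`
#'   (may be `NA`), and `rolling_durations` (most recent trial durations).
#' @param config A [task_config()] list.
#' @return List with `end` (logical) and `reason` (`NA` if not ending).
#' @export
should_end_session <- function(clock, config = task_config()) {
  if (clock$elapsed_s >= config$session_max_min * 60)
    return(list(end = TRUE, reason = "max_time"))
  if (clock$elapsed_s >= config$low_count_min * 60 &&
      clock$n_completed < config$low_count_threshold)
    return(list(end = TRUE, reason = "low_count"))
  rd <- clock$rolling_durations
  if (!is.null(rd) && length(rd) >= config$rolling_window &&
      !is.na(clock$baseline_duration_s)) {
    recent <- utils::tail(rd, config$rolling_window)
    if (stats::median(recent) > config$slowdown_factor * clock$baseline_duration_s)
      return(list(end = TRUE, reason = "slow_responses"))
  }
  list(end = FALSE, reason = NA_character_)
}
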