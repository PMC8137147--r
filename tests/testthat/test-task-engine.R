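# Task protocol: block lengths, schedules, stimulus sampling, quiescence,
# staging, session-ending rules.

trunc_geom_mean <- function(p, lo, hi) {
  # closed form for the conditional mean, cross-checked against the pmf
  q <- 1 - p
  m <- hi - lo + 1
  (lo - 1) + 1 / p - m * q^m / (1 - q^m)
}

test_that("block-length sampler matches the renormalized truncated geometric", {
  # closed form agrees with brute-force pmf summation (independent oracle)
  pmf <- block_length_pmf(1 / 60, 20, 100)
  expect_equal(sum(pmf), 1)
  expect_equal(sum((20:100) * pmf), trunc_geom_mean(1 / 60, 20, 100),
               tolerance = 1e-12)
  expect_equal(trunc_geom_mean(1 / 60, 20, 100), 51.08, tolerance = 1e-3)

  set.seed(1)
  x <- sample_block_lengths(1e5, 1 / 60, 20, 100)
  expect_true(all(x >= 20 & x <= 100))
  expect_equal(mean(x), trunc_geom_mean(1 / 60, 20, 100), tolerance = 0.01)

  # chi-square goodness of fit against the exact pmf
  obs <- tabulate(x - 19, nbins = 81)
  gof <- suppressWarnings(chisq.test(obs, p = pmf))
  expect_gt(gof$p.value, 0.01)

  # renormalized-pmf semantics: P(20) = 0.5 exactly when p = 0.5
  pmf5 <- block_length_pmf(0.5, 20, 100)
  expect_equal(pmf5[1], 0.5, tolerance = 1e-10)
  set.seed(2)
  expect_equal(mean(sample_block_lengths(2e4, 0.5, 20, 100) == 20), 0.5,
               tolerance = 0.02)
})

test_that("block-length sampler rejects infeasible arguments", {
  expect_error(sample_block_lengths(5, 0.5, lo = 30, hi = 20), "lo")
  expect_error(sample_block_lengths(5, 1, lo = 20, hi = 100), "infeasible")
  expect_error(sample_block_lengths(5, 0, lo = 20, hi = 100), "p")
})

test_that("session schedules have the protocol's block structure", {
  set.seed(3)
  for (i in 1:10) {
    sch <- build_session_schedule("full", 700)
    expect_equal(sch$p_left[1], 0.5)
    expect_equal(sch$length[1], 90)
    biased <- sch$p_left[-1]
    expect_true(all(biased %in% c(0.2, 0.8)))
    if (length(biased) > 1)                     # strict alternation
      expect_true(all(biased[-1] != biased[-length(biased)]))
    expect_true(all(sch$length[-1] >= 20 & sch$length[-1] <= 100))
    expect_gte(sum(sch$length), 700)
  }
  basic <- build_session_schedule("basic", 700)
  expect_equal(nrow(basic), 1)
  expect_equal(basic$p_left, 0.5)
})

test_that("stimulus frequencies follow the stated weights", {
  stage <- training_stage(5)
  # full task: 0% doubled -> 1/6; basic: signed-uniform -> 1/11
  wf <- contrast_weights(stage$contrast_magnitudes, "full")
  expect_equal(wf[stage$contrast_magnitudes == 0], 1 / 6)
  wb <- contrast_weights(stage$contrast_magnitudes, "basic")
  expect_equal(wb[stage$contrast_magnitudes == 0], 1 / 11)

  set.seed(4)
  draws <- replicate(8000, sample_trial_stimulus(stage, 0.8, NULL, "basic")$
                       signed_contrast)
  p0 <- mean(draws == 0)
  expect_equal(p0, 1 / 11, tolerance = 3 * sqrt((1 / 11) * (10 / 11) / 8000) /
                 (1 / 11))
  # side frequency tracks the block prior among nonzero stimuli
  frac_left <- mean(draws[draws != 0] < 0)
  expect_equal(frac_left, 0.8, tolerance = 0.03)
})

test_that("debiasing repeats incorrect easy trials", {
  stage <- training_stage(0)
  prev <- list(signed_contrast = -100, correct = 0)
  set.seed(5)
  reps <- replicate(2000, {
    s <- sample_trial_stimulus(stage, 0.5, prev, "basic")
    c(s$is_repeat, s$signed_contrast)
  })
  expect_equal(mean(reps[1, ]), 0.9, tolerance = 0.03)
  expect_true(all(reps[2, reps[1, ] == 1] == -100))
  # correct previous trials never trigger repeats
  prev_ok <- list(signed_contrast = -100, correct = 1)
  s <- sample_trial_stimulus(stage, 0.5, prev_ok, "basic")
  expect_false(s$is_repeat)
})

test_that("quiescence draws are bounded with the truncated-exponential mean", {
  set.seed(6)
  q <- sample_quiescence(1e5)
  expect_true(all(q >= 0.4 & q <= 0.7))
  # E[X | 0.4 <= X <= 0.7] for Exp(mean 0.55), by closed form
  mu <- 0.4 + 0.55 - 0.3 * exp(-0.3 / 0.55) / (1 - exp(-0.3 / 0.55))
  expect_equal(mean(q), mu, tolerance = 0.005)
})

test_that("stage progression is monotone with gain and reward schedules", {
  hist <- list()
  ids <- integer(0)
  perf <- c(0.5, 0.75, 0.75, 0.95, 0.95, 0.95)
  for (i in seq_along(perf)) {
    st <- advance_training_stage(hist)
    ids <- c(ids, st$stage_id)
    hist[[i]] <- list(n_trials = 250, perf_easy = perf[i])
  }
  expect_true(all(diff(ids) >= 0))
  expect_equal(ids[1], 0L)
  st <- advance_training_stage(hist)
  expect_equal(st$stage_id, 5L)
  expect_equal(st$gain, 4)                 # halved after a >200-trial session
  expect_equal(st$reward_volume, 1.5)      # floored at 1.5 uL

  # low-trial sessions never advance anything
  st0 <- advance_training_stage(list(list(n_trials = 150, perf_easy = 0.99)))
  expect_equal(st0$stage_id, 0L)
  expect_equal(st0$gain, 8)
  expect_equal(st0$reward_volume, 3)

  # ordered contrast introduction: 25 before 12.5 before {6.25, 0}
  expect_true(25 %in% training_stage(1)$contrast_magnitudes)
  expect_false(12.5 %in% training_stage(1)$contrast_magnitudes)
  expect_true(all(c(6.25, 0) %in% training_stage(3)$contrast_magnitudes))
  expect_false(50 %in% training_stage(4)$contrast_magnitudes)
  expect_true(50 %in% training_stage(5)$contrast_magnitudes)
})

test_that("session-ending rules fire in order and are pure", {
  clock <- function(min_elapsed, n, base = NA, roll = NULL)
    list(elapsed_s = min_elapsed * 60, n_completed = n,
         baseline_duration_s = base, rolling_durations = roll)
  expect_equal(should_end_session(clock(90, 1000))$reason, "max_time")
  expect_equal(should_end_session(clock(46, 350))$reason, "low_count")
  expect_false(should_end_session(clock(46, 450))$end)
  slow <- clock(10, 200, base = 0.5, roll = rep(3, 10))
  expect_equal(should_end_session(slow)$reason, "slow_responses")
  ok <- clock(10, 200, base = 0.5, roll = rep(1, 10))
  expect_false(should_end_session(ok)$end)          # 1.0 < 2.5
  # inactive without a baseline or full window
  expect_false(should_end_session(clock(10, 5, base = NA, roll = rep(3, 10)))$end)
  expect_false(should_end_session(clock(10, 5, base = 0.5, roll = rep(3, 4)))$end)
  # purity: identical clocks give identical decisions
  expect_identical(should_end_session(slow), should_end_session(slow))
})

test_that("simulated biased blocks reach their stimulus-side frequency", {
  set.seed(7)
  agent <- default_agent_params("full")
  stage <- training_stage(5, gain = 4, reward_volume = 1.5,
                          debias_active = FALSE)
  sch <- build_session_schedule("full", 1200)
  tr <- simulate_session(agent, stage, sch, "full", n_target = 1200)
  nz <- tr[tr$signed_contrast != 0, ]
  for (p in c(0.2, 0.8)) {
    blk <- nz[nz$block_p_left == p, ]
    fl <- mean(blk$signed_contrast < 0)
    expect_equal(fl, p, tolerance = 3 * sqrt(p * (1 - p) / nrow(blk)) + 0.01)
  }
  # full-task zero-contrast frequency ~ 1/6 (binomial tolerance)
  expect_lt(abs(mean(tr$signed_contrast == 0) - 1 / 6),
            3 * sqrt((1 / 6) * (5 / 6) / nrow(tr)) + 0.005)
})
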