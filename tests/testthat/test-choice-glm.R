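# Design matrix construction, penalized logistic fitting, diagnostics.

mini_trials <- function(signed_contrast, choice, correct,
                        block_p_left = 0.5) {
  n <- length(signed_contrast)
  data.frame(lab_id = "lab1", mouse_id = "m01", session_day = 1L,
             trial_index = seq_len(n), signed_contrast = signed_contrast,
             block_p_left = block_p_left, choice = choice, correct = correct,
             trial_duration_s = 0.5, is_repeat = 0L, stage_id = 5L)
}

test_that("design encodings match the published conventions", {
  tr <- mini_trials(c(-25, 100, 0, -6.25),
                    choice = c(-1, 1, -1, 1),
                    correct = c(1, 1, 0, 0))
  d <- build_design(tr, "basic")
  X <- d$design
  expect_equal(unname(X[1, "c25"]), -1)          # stimulus -25% -> I_25 = -1
  expect_true(all(X[1, paste0("c", c(6.25, 12.5, 50, 100))] == 0))
  expect_equal(unname(X[3, paste0("c", c(6.25, 12.5, 25, 50, 100))]),
               rep(0, 5))                        # 0% contrast: all-zero I_c
  # first trial: no history
  expect_equal(unname(X[1, c("rewarded", "unrewarded")]), c(0, 0))
  # trial 2 follows a rewarded leftward choice -> r = -1, u = 0
  expect_equal(unname(X[2, c("rewarded", "unrewarded")]), c(-1, 0))
  # trial 4 follows an unrewarded leftward choice -> r = 0, u = -1
  expect_equal(unname(X[4, c("rewarded", "unrewarded")]), c(0, -1))
  expect_equal(d$response, c(0, 1, 0, 1))
  expect_true(all(X[, "intercept"] == 1))
  # full variant appends the block label (+1 in 20:80 blocks)
  trf <- mini_trials(c(25, -25), c(1, -1), c(1, 1),
                     block_p_left = c(0.2, 0.8))
  Xf <- build_design(trf, "full")$design
  expect_equal(unname(Xf[, "block"]), c(1, -1))
  expect_error(build_design(mini_trials(30, 1, 1), "basic"), "magnitude")
})

test_that("history resets at session boundaries and after no-responses", {
  tr <- rbind(mini_trials(c(100, 50), c(1, 1), c(1, 1)),
              mini_trials(c(100, 50, 25), c(1, 0, 1), c(1, 0, 0)))
  tr$session_day <- c(1L, 1L, 2L, 2L, 2L)
  tr$trial_index <- c(1L, 2L, 1L, 2L, 3L)
  X <- build_design(tr, "basic")$design
  # first trial of session 2 has no history despite session 1's last trial
  expect_equal(unname(X[3, c("rewarded", "unrewarded")]), c(0, 0))
  # the no-response trial is dropped but zeroes its successor's history
  expect_equal(nrow(X), 4)
  expect_equal(unname(X[4, c("rewarded", "unrewarded")]), c(0, 0))
})

test_that("design encoding is invertible for nonzero-contrast trials", {
  set.seed(30)
  tr <- trained_sessions("basic", n_per_session = 400)
  d <- build_design(tr, "basic")
  mags <- c(6.25, 12.5, 25, 50, 100)
  icols <- d$design[, paste0("c", mags)]
  decoded <- icols %*% mags
  kept <- tr[tr$choice != 0, ]
  nz <- kept$signed_contrast != 0
  expect_equal(drop(decoded)[nz], kept$signed_contrast[nz])
})

test_that("condition number follows singular-value arithmetic", {
  expect_equal(glm_condition_number(diag(4)), 1)
  X <- cbind(c(2, 0), c(0, 1))
  expect_equal(glm_condition_number(X), 2)
  set.seed(31)
  M <- matrix(rnorm(60), 20, 3)
  expect_equal(glm_condition_number(M[sample(20), ]),
               glm_condition_number(M))           # row-permutation invariant
  expect_warning(cn <- glm_condition_number(cbind(1:4, 2 * (1:4))), "rank")
  expect_equal(cn, Inf)
})

test_that("penalized fit recovers generative weights within 3 SE", {
  set.seed(32)
  tr <- trained_sessions("full", n_per_session = 700, seed = 321)
  fit <- fit_choice_glm(build_design(tr, "full"), penalty_strength = 1e-6)
  truth <- default_agent_params("full")
  w_true <- c(truth$visual_weights, rewarded = truth$w_rewarded,
              unrewarded = truth$w_unrewarded, block = truth$w_block,
              intercept = truth$w_bias)
  names(w_true)[1:5] <- paste0("c", c(6.25, 12.5, 25, 50, 100))
  se <- sqrt(diag(fit$covariance))
  for (nm in names(w_true))
    expect_lt(abs(fit$weights[nm] - w_true[nm]), 3 * se[nm] + 1e-8)
  expect_false(fit$diverged)
  expect_gte(fit$condition_number, 1)
})

test_that("tiny-data optimum matches an exhaustive grid oracle", {
  # single-predictor model: penalized NLL minimised by brute force
  X <- cbind(c100 = c(1, 1, 1, -1, -1, 1), intercept = 1)
  y <- c(1, 1, 0, 0, 0, 1)
  lam_per <- 0.05
  grid <- as.matrix(expand.grid(w = seq(-3, 3, by = 0.01),
                                b = seq(-3, 3, by = 0.01)))
  pen_nll <- function(w, b) {
    eta <- X[, 1] * w + b
    sum(log1p(exp(eta))) - sum(y * eta) + lam_per * nrow(X) * abs(w)
  }
  vals <- mapply(pen_nll, grid[, 1], grid[, 2])
  best <- grid[which.min(vals), ]
  fit <- fit_choice_glm(X, y, penalty_strength = lam_per)
  expect_equal(unname(fit$weights["c100"]), unname(best["w"]),
               tolerance = 0.02)
  expect_equal(unname(fit$weights["intercept"]), unname(best["b"]),
               tolerance = 0.02)
})

test_that("L1 shrinkage is monotone in the one-predictor case", {
  set.seed(33)
  X <- cbind(c100 = sample(c(-1, 1), 200, replace = TRUE))
  y <- as.integer(runif(200) < plogis(1.5 * X[, 1]))
  w_hat <- sapply(c(0, 0.005, 0.02, 0.08),
                  function(l) abs(fit_choice_glm(X, y, l)$weights["c100"]))
  expect_true(all(diff(w_hat) <= 1e-6))
})

test_that("degenerate designs are flagged", {
  X <- cbind(c100 = rep(0, 4), intercept = 1)
  expect_error(fit_choice_glm(X, c(0, 1, 0, 1)), "c100")
  # intercept-only with balanced choices: weight near zero
  fit <- fit_choice_glm(cbind(intercept = rep(1, 100)),
                        rep(c(0, 1), 50), penalty_strength = 0)
  expect_equal(unname(fit$weights), 0, tolerance = 1e-4)
  # perfectly separable data with (near) zero penalty diverges and is flagged
  Xs <- cbind(c100 = c(rep(1, 20), rep(-1, 20)), intercept = 1)
  ys <- c(rep(1, 20), rep(0, 20))
  fit_s <- fit_choice_glm(Xs, ys, penalty_strength = 1e-12)
  expect_true(fit_s$diverged)
})

test_that("block-frozen full fits equal basic fits on identical trials", {
  set.seed(34)
  tr <- trained_sessions("basic", n_per_session = 300, seed = 77)
  db <- build_design(tr, "basic")
  df <- build_design(tr, "full")     # basic trials: block column all zero...
  # ... so freezing W_b at 0 = dropping the column
  Xf <- df$design[, colnames(df$design) != "block"]
  fb <- fit_choice_glm(db$design, db$response, 1e-5)
  ff <- fit_choice_glm(Xf, df$response, 1e-5)
  expect_equal(fb$weights, ff$weights, tolerance = 1e-6)
})

test_that("predictive accuracy behaves at the extremes", {
  set.seed(35)
  # deterministic agent: |z| huge -> accuracy 1 under CV
  big <- agent_params(c(`6.25` = 25, `12.5` = 25, `25` = 25, `50` = 25,
                        `100` = 25), 0, 0)
  stage <- training_stage(5, gain = 4, reward_volume = 1.5)
  tr <- simulate_session(big, stage, build_session_schedule("basic", 1),
                         "basic", n_target = 600)
  tr$session_day <- 1
  tr <- tr[tr$signed_contrast != 0, ]
  expect_equal(glm_predictive_accuracy(tr, "basic", k = 5), 1,
               tolerance = 0.01)
  # pure-noise choices: accuracy ~ 0.5
  coin <- mini_trials(rep(0, 400), sample(c(-1, 1), 400, replace = TRUE),
                      rbinom(400, 1, 0.5))
  coin$trial_index <- 1:400
  acc <- glm_predictive_accuracy(coin, "basic", k = 5)
  expect_lt(abs(acc - 0.5), 0.12)
  # in-sample mode runs
  expect_gte(glm_predictive_accuracy(tr, "basic", k = 0), 0.99)
})

test_that("Laplace bands collapse, cover, and shrink with data", {
  set.seed(36)
  tr <- trained_sessions("basic", n_per_session = 500, seed = 88)
  fit <- fit_choice_glm(build_design(tr, "basic"), penalty_strength = 1e-5)
  curves <- glm_posterior_curves(fit, tr, "basic", n_samples = 400)
  expect_true(all(curves$lower <= curves$predicted + 1e-9))
  expect_true(all(curves$upper >= curves$predicted - 1e-9))
  # zero covariance: bands collapse onto the point prediction
  fit0 <- fit
  fit0$covariance <- fit$covariance * 0
  c0 <- glm_posterior_curves(fit0, tr, "basic", n_samples = 50)
  expect_equal(c0$lower, c0$predicted, tolerance = 1e-9)
  expect_equal(c0$upper, c0$predicted, tolerance = 1e-9)
  # ten-fold data: narrower bands (Fisher-information scaling)
  tr_big <- trained_sessions("basic", n_mice = 1, n_per_session = 5000,
                             seed = 88)
  fit_big <- fit_choice_glm(build_design(tr_big, "basic"),
                            penalty_strength = 1e-5)
  cb <- glm_posterior_curves(fit_big, tr_big, "basic", n_samples = 400)
  shared <- intersect(curves$signed_contrast, cb$signed_contrast)
  w_small <- with(curves[curves$signed_contrast %in% shared, ],
                  mean(upper - lower))
  w_big <- with(cb[cb$signed_contrast %in% shared, ], mean(upper - lower))
  expect_lt(w_big, w_small)
})
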