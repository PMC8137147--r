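# Four-parameter erf psychometric model: evaluation, maximum-likelihood
# fitting, and block-wise bias shifts.

#' Gauss error function
#' @param x Numeric vector.
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Construct psychometric parameters
#'
#' @param gamma Left lapse rate (lower asymptote), in \[0, 0.5\].
#' @param lambda Right lapse rate (`1 -` upper asymptote), in \[0, 0.5\].
#' @param mu Response bias, in percent contrast.
#' @param sigma Contrast threshold (curve width), in percent contrast, > 0.
#' @return A `psych_params` list.
#' @export
psych_params <- function(gamma, lambda, mu, sigma) {
  stopifnot(gamma >= 0, gamma <= 0.5, lambda >= 0, lambda <= 0.5,
            gamma + lambda < 1)
  if (sigma <= 0) stop("`sigma` must be positive")
  structure(list(gamma = gamma, lambda = lambda, mu = mu, sigma = sigma),
            class = "psych_params")
}

#' Evaluate the psychometric curve
#'
#' P(rightward choice) = gamma + (1 - gamma - lambda) *
#' (erf((c - mu) / sigma) + 1) / 2, which runs from `gamma` at strongly-left
#' stimuli to `1 - lambda` at strongly-right stimuli and is non-decreasing in
#' contrast.
#'
#' @param params A [psych_params()] object.
#' @param signed_contrast Signed contrast(s) in percent (negative = left).
#' @return Probability of a rightward choice, vectorised over contrast.
#' @export
psych_eval <- function(params, signed_contrast) {
  if (params$sigma <= 0) stop("`sigma` must be positive")
  params$gamma + (1 - params$gamma - params$lambda) *
    (erf((signed_contrast - params$mu) / params$sigma) + 1) / 2
}

#' Aggregate a trials table into choice counts per signed contrast
#'
#' No-response trials (choice 0) count towards `n_total` but not `n_right`.
#'
#' @param trials A trials table (see [read_trials_table()]).
#' @return Data frame with `signed_contrast`, `n_right`, `n_total`.
#' @export
aggregate_choices <- function(trials) {
  sc <- sort(unique(trials$signed_contrast))
  data.frame(
    signed_contrast = sc,
    n_right = vapply(sc, function(c)
      sum(trials$choice[trials$signed_contrast == c] == 1), numeric(1)),
    n_total = vapply(sc, function(c)
      sum(trials$signed_contrast == c), numeric(1))
  )
}

psych_nll <- function(theta, agg) {
  p <- theta[1] + (1 - theta[1] - theta[2]) *
    (erf((agg$signed_contrast - theta[3]) / theta[4]) + 1) / 2
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(stats::dbinom(agg$n_right, agg$n_total, p, log = TRUE))
}

#' Fit the psychometric curve by maximum likelihood
#'
#' Binomial likelihood maximised over box constraints (lapses in \[0, 0.5\],
#' bias in \[-100, 100\], threshold in \[0.5, 200\]) with multi-start
#' L-BFGS-B from jittered data-driven initial points; the best restart wins.
#'
#' @param agg Aggregated choices: data frame with `signed_contrast`,
#'   `n_right`, `n_total` (e.g. from [aggregate_choices()]), or a trials
#'   table, which is aggregated first.
#' @param n_restarts Number of optimiser restarts (>= 1).
#' @param jitter_sd Relative jitter applied to the starting point.
#' @return A `psych_fit` list: `params`, `nll`, `n_trials`, `converged`,
#'   `n_restarts_used`, `boundary` (TRUE if the optimum sits on the box).
#' @export
fit_psychometric <- function(agg, n_restarts = 5, jitter_sd = 0.25) {
  if (!is.null(agg$choice)) agg <- aggregate_choices(agg)
  if (length(unique(agg$signed_contrast)) < 2)
    stop("need at least 2 distinct contrasts to fit a psychometric curve")
  stopifnot(all(agg$n_total >= 1), n_restarts >= 1)

  lower <- c(0, 0, -100, 0.5)
  upper <- c(0.5, 0.5, 100, 200)
  f <- agg$n_right / agg$n_total
  ord <- order(agg$signed_contrast)
  f_lo <- f[ord][1]; f_hi <- f[ord][length(f)]
  # bias starts at 0: with easy-only contrast sets the likelihood is flat in
  # mu over a wide region, and the first (unjittered) restart wins ties
  start0 <- c(
    min(max(f_lo, 0.01), 0.45),
    min(max(1 - f_hi, 0.01), 0.45),
    0,
    max(diff(range(agg$signed_contrast)) / 8, 2)
  )
  best <- NULL
  used <- 0L
  for (r in seq_len(n_restarts)) {
    used <- used + 1L
    s <- start0
    if (r > 1) {
      s <- s * exp(stats::rnorm(4, 0, jitter_sd))
      s[3] <- start0[3] + stats::rnorm(1, 0, 10)
    }
    s <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(s, psych_nll, agg = agg, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed in all restarts")
  th <- best$par
  on_box <- any(abs(th - lower) < 1e-6) || any(abs(th - upper) < 1e-6)
  structure(list(
    params = psych_params(th[1], th[2], th[3], th[4]),
    nll = best$value,
    n_trials = sum(agg$n_total),
    converged = best$convergence == 0 || on_box,
    n_restarts_used = used,
    boundary = on_box
  ), class = "psych_fit")
}

#' Per-contrast bias shift between block types
#'
#' The shift at contrast c is the rightward-choice fraction in 20:80 blocks
#' (right more likely) minus the fraction in 80:20 blocks, in percentage
#' points. Computed from raw choice fractions, as in the block-wise analysis
#' of trained mice.
#'
#' @param f_2080,f_8020 Data frames with `signed_contrast` and
#'   `fraction_right` on an identical contrast grid.
#' @return Data frame with `signed_contrast` and `shift` (percentage points).
#' @export
bias_shift <- function(f_2080, f_8020) {
  if (!identical(f_2080$signed_contrast, f_8020$signed_contrast))
    stop("contrast grids of the two blocks do not match")
  data.frame(signed_contrast = f_2080$signed_contrast,
             shift = 100 * (f_2080$fraction_right - f_8020$fraction_right))
}

#' Rightward-choice fraction per contrast for one block type
#' @param trials Trials table.
#' @param p_left Block stimulus-left probability selecting the block type.
#' @return Data frame with `signed_contrast`, `fraction_right`, `n`.
#' @export
choice_fractions <- function(trials, p_left = NULL) {
  if (!is.null(p_left)) trials <- trials[trials$block_p_left == p_left, ]
  agg <- aggregate_choices(trials)
  data.frame(signed_contrast = agg$signed_contrast,
             fraction_right = agg$n_right / agg$n_total, n = agg$n_total)
}
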