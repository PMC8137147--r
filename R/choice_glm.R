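# Trial-history logistic choice model: design matrix, penalized maximum
# likelihood, and diagnostics (condition number, predictive accuracy,
# Laplace confidence bands).

glm_magnitudes <- c(6.25, 12.5, 25, 50, 100)

#' Build the choice-model design matrix
#'
#' One row per responded trial (no-response trials are dropped but still
#' reset the history encodings of their successor to 0). Columns: signed
#' per-contrast indicators I_c for c in \{6.25, 12.5, 25, 50, 100\} (+1
#' stimulus right, -1 left, 0 absent; 0%-contrast trials are all-zero), the
#' previous-rewarded encoding r (+1 previous rewarded rightward choice, -1
#' leftward, 0 if unrewarded or no predecessor), the symmetric
#' previous-unrewarded encoding u, the block label b (+1 in 20:80 blocks,
#' -1 in 80:20, 0 unbiased; full variant only), and an intercept. History
#' never crosses a session boundary.
#'
#' @param trials Trials table, ordered within sessions.
#' @param variant `"basic"` or `"full"`.
#' @return List with `design` (matrix) and `response` (1 = rightward
#'   choice).
#' @export
build_design <- function(trials, variant = c("basic", "full")) {
  variant <- match.arg(variant)
  mag <- abs(trials$signed_contrast)
  if (!all(mag %in% c(0, glm_magnitudes)))
    stop("unknown contrast magnitude in trials table")
  key <- if (!is.null(trials$mouse_id))
    paste(trials$lab_id, trials$mouse_id, trials$session_day)
  else if (!is.null(trials$session_day)) as.character(trials$session_day)
  else rep("s1", nrow(trials))

  n <- nrow(trials)
  first <- !duplicated(key)
  prev_choice <- c(0L, trials$choice[-n])
  prev_correct <- c(0L, trials$correct[-n])
  prev_choice[first] <- 0L
  r <- ifelse(prev_correct == 1, prev_choice, 0L)
  u <- ifelse(prev_correct == 0, prev_choice, 0L)

  icols <- sapply(glm_magnitudes, function(m)
    ifelse(mag == m, sign(trials$signed_contrast), 0))
  colnames(icols) <- paste0("c", glm_magnitudes)
  X <- cbind(icols, rewarded = r, unrewarded = u)
  if (variant == "full") {
    b <- ifelse(trials$block_p_left == 0.2, 1,
                ifelse(trials$block_p_left == 0.8, -1, 0))
    X <- cbind(X, block = b)
  }
  X <- cbind(X, intercept = 1)
  keep <- trials$choice != 0
  list(design = X[keep, , drop = FALSE],
       response = as.integer(trials$choice[keep] == 1))
}

glm_nll_core <- function(w, X, y) {
  eta <- drop(X %*% w)
  sum(ifelse(eta > 30, eta, log1p(exp(eta)))) - sum(y * eta)
}

#' Fit the choice model by penalized maximum likelihood
#'
#' Minimises the Bernoulli negative log-likelihood plus an L1 penalty of
#' `penalty_strength * n_trials * sum(|w|)` over the non-intercept weights
#' (smoothed |w| = sqrt(w^2 + 1e-12) so a quasi-Newton optimiser applies;
#' the default strength is small and serves only as separability
#' protection). The covariance is the inverse Hessian of the unpenalized
#' likelihood at the optimum.
#'
#' @param design,response From [build_design()], or pass a list from it as
#'   `design` with `response` missing.
#' @param penalty_strength L1 strength per trial (default 1e-4).
#' @return A `glm_fit` list: `weights`, `covariance`, `nll` (unpenalized),
#'   `condition_number`, `n_trials`, `diverged`.
#' @export
fit_choice_glm <- function(design, response = NULL, penalty_strength = 1e-4) {
  if (is.list(design) && is.null(response)) {
    response <- design$response
    design <- design$design
  }
  X <- as.matrix(design)
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  zero_cols <- colnames(X)[colSums(X != 0) == 0]
  if (length(zero_cols))
    stop("singular design: all-zero column(s): ",
         paste(zero_cols, collapse = ", "))
  lam <- penalty_strength * nrow(X)
  pen <- colnames(X) != "intercept"
  sabs <- function(w) sqrt(w^2 + 1e-12)
  fn <- function(w) glm_nll_core(w, X, y) + lam * sum(sabs(w[pen]))
  gr <- function(w) {
    p <- stats::plogis(drop(X %*% w))
    g <- drop(crossprod(X, p - y))
    g[pen] <- g[pen] + lam * w[pen] / sabs(w[pen])
    g
  }
  fit <- stats::optim(rep(0, ncol(X)), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- fit$par
  names(w) <- colnames(X)
  p <- stats::plogis(drop(X %*% w))
  H <- crossprod(X * sqrt(p * (1 - p)))
  covar <- tryCatch(solve(H), error = function(e) {
    warning("singular Hessian; covariance via pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    d <- ifelse(ev$values > 1e-10, 1 / ev$values, 0)
    ev$vectors %*% (d * t(ev$vectors))
  })
  covar <- (covar + t(covar)) / 2
  dimnames(covar) <- list(colnames(X), colnames(X))
  structure(list(
    weights = w, covariance = covar, nll = glm_nll_core(w, X, y),
    condition_number = glm_condition_number(X), n_trials = nrow(X),
    diverged = any(abs(w) > 15), penalty_strength = penalty_strength
  ), class = "glm_fit")
}

#' 2-norm condition number of a design matrix
#'
#' Ratio of the largest to the smallest singular value; `Inf` (with a
#' warning) for rank-deficient designs.
#' @param design Numeric matrix.
#' @export
glm_condition_number <- function(design) {
  d <- svd(as.matrix(design), nu = 0, nv = 0)$d
  if (min(d) < max(d) * 1e-12) {
    warning("rank-deficient design")
    return(Inf)
  }
  max(d) / min(d)
}

#' Cross-validated predictive accuracy of the choice model
#'
#' Folds are contiguous blocks of trials (respecting trial order); each
#' fold is predicted from a model fitted to the remaining folds, with the
#' predicted choice = (p >= 0.5). `k = 0` gives in-sample accuracy.
#'
#' @param trials Trials table.
#' @param variant `"basic"` or `"full"`.
#' @param k Number of folds (default 5); 0 for in-sample.
#' @param penalty_strength Passed to [fit_choice_glm()].
#' @return Fraction of correctly predicted choices.
#' @export
glm_predictive_accuracy <- function(trials, variant = "basic", k = 5,
                                    penalty_strength = 1e-4) {
  d <- build_design(trials, variant)
  X <- d$design; y <- d$response
  # predictors absent from the data carry no information: weight 0
  X <- X[, colSums(X != 0) > 0, drop = FALSE]
  n <- nrow(X)
  if (k == 0) {
    fit <- fit_choice_glm(X, y, penalty_strength)
    return(mean((stats::plogis(drop(X %*% fit$weights)) >= 0.5) == y))
  }
  fold <- ceiling(seq_len(n) / (n / k))
  correct <- logical(n)
  for (f in unique(fold)) {
    te <- fold == f
    # predictors absent from a training fold carry weight 0 for that fold
    keep <- colSums(X[!te, , drop = FALSE] != 0) > 0
    fit <- fit_choice_glm(X[!te, keep, drop = FALSE], y[!te],
                          penalty_strength)
    correct[te] <- (stats::plogis(drop(X[te, keep, drop = FALSE] %*%
                                         fit$weights)) >= 0.5) == y[te]
  }
  mean(correct)
}

#' Laplace confidence bands for per-contrast choice fractions
#'
#' Draws weight vectors from a multivariate Gaussian centred on the fitted
#' weights with the fit's inverse-Hessian covariance; for each draw,
#' computes the model's mean predicted rightward-choice fraction per signed
#' contrast over the supplied trials, and returns pointwise 2.5%/97.5%
#' quantiles. A non-positive-semidefinite covariance is repaired by
#' clipping negative eigenvalues (with a warning).
#'
#' @param fit A [fit_choice_glm()] result.
#' @param trials Trials table the fit refers to.
#' @param variant `"basic"` or `"full"`.
#' @param n_samples Number of Gaussian samples (default 10000).
#' @return Data frame: `signed_contrast`, `predicted`, `lower`, `upper`.
#' @export
glm_posterior_curves <- function(fit, trials, variant = "basic",
                                 n_samples = 10000) {
  d <- build_design(trials, variant)
  X <- d$design
  sc <- trials$signed_contrast[trials$choice != 0]
  ev <- eigen(fit$covariance, symmetric = TRUE)
  if (any(ev$values < -1e-8))
    warning("covariance not PSD; clipping negative eigenvalues")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), ncol(X))
  Z <- matrix(stats::rnorm(n_samples * ncol(X)), ncol(X), n_samples)
  W <- fit$weights + L %*% Z                     # ncol(X) x n_samples
  P <- stats::plogis(X %*% W)                    # n_trials x n_samples
  grid <- sort(unique(sc))
  agg <- rowsum(P, group = sc) / as.vector(table(sc))
  point <- rowsum(stats::plogis(drop(X %*% fit$weights)), group = sc) /
    as.vector(table(sc))
  data.frame(
    signed_contrast = grid,
    predicted = drop(point),
    lower = apply(agg, 1, stats::quantile, probs = 0.025),
    upper = apply(agg, 1, stats::quantile, probs = 0.975)
  )
}
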