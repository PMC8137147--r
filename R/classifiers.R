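# In-package classifiers for the lab-membership analysis: Gaussian naive
# Bayes, L2-regularised softmax (multinomial logistic) regression, and a
# random forest (C++ backend). Each exposes fit/predict through a common
# internal interface so the classification procedure is classifier-agnostic.

#' Fit a classifier
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param y Factor (or coercible) class labels.
#' @param method `"naive_bayes"`, `"random_forest"`, or `"logistic"`.
#' @param ... Method options: `n_tree` (default 100) and `mtry` for the
#'   forest; `lambda` (L2 strength, default 1) for the logistic.
#' @return A `wt_classifier` object with a [predict_classifier()] method.
#' @export
fit_classifier <- function(x, y,
                           method = c("naive_bayes", "random_forest",
                                      "logistic"), ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- factor(y)
  model <- switch(method,
    naive_bayes = nb_fit(x, y),
    random_forest = rf_fit(x, y, ...),
    logistic = softmax_fit(x, y, ...))
  structure(list(method = method, model = model, levels = levels(y)),
            class = "wt_classifier")
}

#' Predict class labels from a fitted classifier
#' @param object A [fit_classifier()] result.
#' @param x Feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(object, x) {
  x <- as.matrix(x)
  idx <- switch(object$method,
    naive_bayes = nb_predict(object$model, x),
    random_forest = rf_predict_cpp(object$model$trees, x,
                                   length(object$levels)) + 1L,
    logistic = softmax_predict(object$model, x))
  object$levels[idx]
}

# ---- Gaussian naive Bayes ---------------------------------------------------

nb_fit <- function(x, y) {
  classes <- levels(y)
  mu <- s2 <- matrix(0, length(classes), ncol(x))
  for (k in seq_along(classes)) {
    xk <- x[y == classes[k], , drop = FALSE]
    mu[k, ] <- colMeans(xk)
    v <- apply(xk, 2, stats::var)
    s2[k, ] <- ifelse(is.na(v) | v < 1e-9, 1e-9, v)
  }
  # variance floor relative to overall spread, as in common implementations
  s2 <- s2 + 1e-9 * max(apply(x, 2, stats::var), 1e-9)
  list(mu = mu, s2 = s2, log_prior = log(as.vector(table(y)) / length(y)))
}

nb_predict <- function(model, x) {
  n <- nrow(x); K <- nrow(model$mu)
  ll <- matrix(model$log_prior, n, K, byrow = TRUE)
  for (k in seq_len(K)) {
    ll[, k] <- ll[, k] + rowSums(
      -0.5 * log(2 * pi * matrix(model$s2[k, ], n, ncol(x), byrow = TRUE)) -
        0.5 * sweep(x, 2, model$mu[k, ])^2 /
          matrix(model$s2[k, ], n, ncol(x), byrow = TRUE))
  }
  max.col(ll, ties.method = "first")
}

# ---- L2 softmax (multinomial logistic) regression ---------------------------

softmax_fit <- function(x, y, lambda = 1) {
  K <- nlevels(y); d <- ncol(x)
  X1 <- cbind(x, 1)
  yi <- as.integer(y)
  nll <- function(wv) {
    W <- matrix(wv, d + 1, K)
    eta <- X1 %*% W
    eta <- eta - apply(eta, 1, max)
    lse <- log(rowSums(exp(eta)))
    -sum(eta[cbind(seq_along(yi), yi)] - lse) +
      0.5 * lambda * sum(W[seq_len(d), ]^2)
  }
  grad <- function(wv) {
    W <- matrix(wv, d + 1, K)
    eta <- X1 %*% W
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta) / rowSums(exp(eta))
    Y <- matrix(0, nrow(x), K)
    Y[cbind(seq_along(yi), yi)] <- 1
    G <- crossprod(X1, P - Y)
    G[seq_len(d), ] <- G[seq_len(d), ] + lambda * W[seq_len(d), ]
    as.vector(G)
  }
  fit <- stats::optim(rep(0, (d + 1) * K), nll, grad, method = "BFGS",
                      control = list(maxit = 300))
  list(W = matrix(fit$par, d + 1, K))
}

softmax_predict <- function(model, x) {
  max.col(cbind(x, 1) %*% model$W, ties.method = "first")
}

# ---- Random forest (C++ backend) --------------------------------------------

rf_fit <- function(x, y, n_tree = 100, mtry = NULL, min_node = 1) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  list(trees = rf_train_cpp(x, as.integer(y) - 1L, nlevels(y),
                            as.integer(n_tree), as.integer(mtry),
                            as.integer(min_node)))
}
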