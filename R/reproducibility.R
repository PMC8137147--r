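# Cross-laboratory reproducibility assessment: per-mouse featurization,
# the subsample / leave-one-out / shuffle-null classification procedure,
# cross-lab statistical tests with FDR control, and the slow-learner
# predictor.

#' Featurize mice from their proficiency sessions
#'
#' Basic variant: easy-trial performance, contrast threshold and bias from
#' the pooled three sessions at which each mouse achieved basic proficiency
#' (3 columns). Full variant: threshold, left lapse, right lapse and bias
#' fitted separately within 20:80 and 80:20 blocks of the three
#' full-proficiency sessions (8 columns). Mice lacking the required
#' sessions are excluded (with a message).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param variant `"basic"` or `"full"`.
#' @return A data frame (`feature_table`): `lab_id`, `mouse_id`,
#'   `timezone_group`, and the feature columns.
#' @export
featurize_mice <- function(cohort, variant = c("basic", "full")) {
  variant <- match.arg(variant)
  tz <- stats::setNames(cohort$labs$timezone_group, cohort$labs$lab_id)
  rows <- lapply(seq_len(nrow(cohort$mice)), function(i) {
    m <- cohort$mice[i, ]
    day_done <- if (variant == "basic") m$day_trained else m$day_full
    if (is.na(day_done)) return(NULL)
    tr <- cohort$trials[cohort$trials$mouse_id == m$mouse_id &
                          cohort$trials$session_day %in%
                            (day_done - 2):day_done, ]
    base <- data.frame(lab_id = m$lab_id, mouse_id = m$mouse_id,
                       timezone_group = unname(tz[m$lab_id]))
    if (variant == "basic") {
      fit <- fit_psychometric(tr)$params
      easy <- abs(tr$signed_contrast) >= 50
      cbind(base, data.frame(perf_easy = mean(tr$correct[easy]),
                             threshold = fit$sigma, bias = fit$mu))
    } else {
      f20 <- fit_psychometric(tr[tr$block_p_left == 0.2, ])$params
      f80 <- fit_psychometric(tr[tr$block_p_left == 0.8, ])$params
      cbind(base, data.frame(
        threshold_2080 = f20$sigma, lapse_left_2080 = f20$gamma,
        lapse_right_2080 = f20$lambda, bias_2080 = f20$mu,
        threshold_8020 = f80$sigma, lapse_left_8020 = f80$gamma,
        lapse_right_8020 = f80$lambda, bias_8020 = f80$mu))
    }
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " mice lacked proficiency sessions and were excluded")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(features)
  setdiff(colnames(features), c("lab_id", "mouse_id", "timezone_group"))

loo_accuracy <- function(x, y, classifier, standardize = TRUE, ...) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sd_ <- apply(xtr, 2, stats::sd)
      sd_[sd_ < 1e-12] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sd_, "/")
    }
    fit <- fit_classifier(xtr, y[-i], classifier, ...)
    pred[i] <- predict_classifier(fit, xte)
  }
  pred
}

#' Classify laboratory membership with a shuffle null
#'
#' Repeats the published procedure: per repeat, subsample `n_per_lab` mice
#' from each lab, classify lab membership by leave-one-out cross-validation
#' over the pooled subsample (accuracy = correctly classified / total), and
#' average the confusion matrix. `mode = "shuffle"` permutes lab labels
#' within each subsample before classification (the null distribution);
#' `mode = "positive_control"` appends the timezone group (one-hot) as
#' features. Optionally features are z-scored using training-fold
#' statistics.
#'
#' @param features A [featurize_mice()] table.
#' @param classifier `"naive_bayes"`, `"random_forest"`, or `"logistic"`.
#' @param n_per_lab Mice subsampled per lab (default 8).
#' @param n_repeats Number of subsample repeats (default 2000).
#' @param mode `"data"`, `"shuffle"`, or `"positive_control"`.
#' @param standardize z-score features within each training fold
#'   (default FALSE: the published procedure ran default-configuration
#'   classifiers on raw features).
#' @param ... Passed to [fit_classifier()].
#' @return A `classification_report`: `accuracies`, `mean_accuracy`,
#'   `confusion_matrix` (row-normalised), `classifier_name`, `mode`.
#' @export
classify_labs <- function(features,
                          classifier = c("naive_bayes", "random_forest",
                                         "logistic"),
                          n_per_lab = 8, n_repeats = 2000,
                          mode = c("data", "shuffle", "positive_control"),
                          standardize = FALSE, ...) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  labs <- sort(unique(features$lab_id))
  counts <- table(features$lab_id)
  if (any(counts < n_per_lab))
    stop("lab(s) with fewer than n_per_lab mice: ",
         paste(names(counts)[counts < n_per_lab], collapse = ", "))
  cols <- feature_columns(features)
  xall <- as.matrix(features[, cols, drop = FALSE])
  if (mode == "positive_control") {
    tzf <- factor(features$timezone_group)
    onehot <- stats::model.matrix(~ tzf - 1)
    colnames(onehot) <- paste0("tz_", levels(tzf))
    xall <- cbind(xall, onehot)
  }
  acc <- numeric(n_repeats)
  K <- length(labs)
  conf <- matrix(0, K, K, dimnames = list(true = labs, predicted = labs))
  for (rep_i in seq_len(n_repeats)) {
    idx <- unlist(lapply(labs, function(l)
      sample(which(features$lab_id == l), n_per_lab)))
    y <- features$lab_id[idx]
    if (mode == "shuffle") y <- sample(y)
    pred <- loo_accuracy(xall[idx, , drop = FALSE], y, classifier,
                         standardize = standardize, ...)
    acc[rep_i] <- mean(pred == y)
    for (j in seq_along(y))
      conf[y[j], pred[j]] <- conf[y[j], pred[j]] + 1
  }
  conf <- conf / rowSums(conf)
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 confusion_matrix = conf, classifier_name = classifier,
                 mode = mode, n_per_lab = n_per_lab),
            class = "classification_report")
}

#' Cross-lab statistical tests with FDR correction
#'
#' For each metric: Kruskal-Wallis rank test (median differences),
#' Brown-Forsythe/Levene test on absolute deviations from group medians
#' (variance differences), and one-way ANOVA. p-values are
#' Benjamini-Hochberg adjusted across the metric family, separately per
#' test. Optionally, paired block-wise metrics are compared with a Wilcoxon
#' signed-rank test.
#'
#' @param metrics Named list; each element is a named list/split of numeric
#'   vectors, one per lab.
#' @param paired Optional named list of two-column matrices/data frames for
#'   Wilcoxon signed-rank tests (block type A vs B per mouse).
#' @return List with `by_lab` (data frame of statistics and raw/adjusted
#'   p-values per metric) and `paired` (Wilcoxon results or `NULL`).
#' @export
compare_labs_tests <- function(metrics, paired = NULL) {
  one <- function(groups) {
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) < 2) stop("need at least 2 labs with >= 2 values")
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    if (stats::var(x) == 0)   # all values tied: rank statistic is 0
      kw <- list(statistic = 0, p.value = 1)
    else kw <- stats::kruskal.test(x, g)
    z <- unlist(lapply(groups, function(v) abs(v - stats::median(v))),
                use.names = FALSE)
    lev <- stats::anova(stats::lm(z ~ g))
    av <- stats::anova(stats::lm(x ~ g))
    c(kw_stat = unname(kw$statistic), kw_p = kw$p.value,
      levene_stat = lev$`F value`[1], levene_p = lev$`Pr(>F)`[1],
      anova_F = av$`F value`[1], anova_p = av$`Pr(>F)`[1])
  }
  res <- t(vapply(metrics, one, numeric(6)))
  out <- data.frame(metric = rownames(res), res, row.names = NULL)
  out$kw_p_adj <- stats::p.adjust(out$kw_p, "BH")
  out$levene_p_adj <- stats::p.adjust(out$levene_p, "BH")
  out$anova_p_adj <- stats::p.adjust(out$anova_p, "BH")
  pw <- NULL
  if (!is.null(paired)) {
    pw <- do.call(rbind, lapply(names(paired), function(nm) {
      m <- as.matrix(paired[[nm]])
      w <- stats::wilcox.test(m[, 1], m[, 2], paired = TRUE, exact = FALSE)
      data.frame(metric = nm, wilcoxon_V = unname(w$statistic),
                 wilcoxon_p = w$p.value)
    }))
    pw$wilcoxon_p_adj <- stats::p.adjust(pw$wilcoxon_p, "BH")
  }
  list(by_lab = out, paired = pw)
}

#' Predict slow learners from early-training performance
#'
#' Labels mice in the slowest quartile of learning speed (largest
#' days-to-proficiency) and trains a random forest on the session-to-session
#' changes in easy-trial performance over the first five sessions, with
#' leave-one-out cross-validation. Reports the bottom-quartile detection
#' accuracy (chance 25% = the base rate) and the rate at which top-quartile
#' (fastest) mice are misclassified as slow.
#'
#' @param perf_easy Matrix (mice x 5 sessions) of easy-trial performance.
#' @param days_to_proficiency Numeric vector, one per mouse (`NA` allowed:
#'   treated as slowest).
#' @param n_tree Forest size.
#' @return List with `recall_bottom`, `top_as_bottom`, `quartile`,
#'   `predicted_slow`.
#' @export
predict_slow_learners <- function(perf_easy, days_to_proficiency,
                                  n_tree = 200) {
  perf_easy <- as.matrix(perf_easy)
  n <- nrow(perf_easy)
  stopifnot(ncol(perf_easy) >= 5, length(days_to_proficiency) == n)
  if (n < 8) stop("need at least 8 mice with 5 sessions each")
  days <- ifelse(is.na(days_to_proficiency), Inf, days_to_proficiency)
  quart <- ceiling(4 * rank(days, ties.method = "first") / n)
  if (sum(quart == 4) < 2 || sum(quart == 1) < 2)
    stop("fewer than 2 mice per extreme quartile")
  x <- t(apply(perf_easy[, 1:5], 1, diff))
  y <- factor(ifelse(quart == 4, "slow", "other"), c("other", "slow"))
  pred <- loo_accuracy(x, y, "random_forest", standardize = FALSE,
                       n_tree = n_tree)
  list(recall_bottom = mean(pred[quart == 4] == "slow"),
       top_as_bottom = mean(pred[quart == 1] == "slow"),
       quartile = quart, predicted_slow = pred == "slow")
}
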