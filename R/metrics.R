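# Evaluation metrics: AUROC, prevalence-calibrated AUPRC, absolute
# calibration error, bootstrap inference, scaling slopes, reclassification.

check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic, so it equals the probability that a
#' random positive outscores a random negative, counting ties as 1/2.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  check_binary(labels)
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# (recall, calibrated precision) pairs over descending unique thresholds
prc_curve_calibrated <- function(labels, scores, pi) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- tp[last] / n1
  fpr <- fp[last] / n0
  prec <- pi * tpr / (pi * tpr + (1 - pi) * fpr)
  prec[is.nan(prec)] <- 1 # threshold above all scores: define precision 1
  list(recall = tpr, precision = prec)
}

#' Calibrated area under the precision-recall curve
#'
#' Precision at each threshold is recomputed from (TPR, FPR) at a fixed
#' reference prevalence `pi`:
#' `prec = pi * TPR / (pi * TPR + (1 - pi) * FPR)`. With `pi` held at the
#' in-distribution prevalence the metric is invariant to prevalence change
#' in later evaluation periods. The area is a right-continuous step
#' integral over recall across unique score thresholds (average-precision
#' style). Setting `pi` to the sample prevalence recovers the standard
#' AUPRC under the same integration rule.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores.
#' @param reference_prevalence reference outcome prevalence in (0, 1).
#' @return calibrated AUPRC in \[0, 1\].
#' @export
auprc_c <- function(labels, scores, reference_prevalence) {
  check_binary(labels)
  if (reference_prevalence <= 0 || reference_prevalence >= 1) {
    stop("reference prevalence must lie in (0, 1)")
  }
  curve <- prc_curve_calibrated(labels, scores, reference_prevalence)
  dr <- diff(c(0, curve$recall))
  sum(dr * curve$precision)
}

#' Absolute calibration error
#'
#' Fits a logistic recalibration curve `c(p) = sigmoid(a + b * logit(p))`
#' to the observed outcomes by maximum likelihood and reports the mean
#' absolute gap between the recalibration curve and the predicted
#' probabilities: `mean(|c(p_i) - p_i|)`. Zero iff the recalibration curve
#' reproduces the predictions on every observed probability.
#'
#' @param labels binary 0/1 vector.
#' @param probabilities predicted probabilities (clipped to (0, 1)).
#' @return non-negative calibration error.
#' @export
ace <- function(labels, probabilities) {
  check_binary(labels)
  p <- clip_probs(probabilities)
  lp <- qlogis(p)
  fit <- suppressWarnings(
    stats::glm(labels ~ lp, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)))
  # perfect separation drives deviance to 0 with a 'non-converged' flag;
  # the recalibration curve then reproduces the outcomes exactly and the
  # error is still well-defined
  if (!fit$converged && fit$deviance > 1e-6) {
    stop("logistic recalibration did not converge (deviance ",
         format(fit$deviance), ")")
  }
  chat <- stats::fitted(fit)
  mean(abs(chat - p))
}

#' Bootstrap summary of a metric
#'
#' Patient-level resampling with replacement; the point estimate is
#' computed on the original sample and the 95% CI is the percentile
#' interval over `n_boot` resamples. Resamples that lose one of the two
#' classes are redrawn (bounded retries).
#'
#' @param metric_fn function(labels, scores, ...) -> scalar.
#' @param labels binary 0/1 vector.
#' @param scores numeric scores.
#' @param n_boot number of bootstrap samples (default 1000).
#' @param seed integer seed.
#' @param ... passed through to `metric_fn`.
#' @param name metric name to record.
#' @return a `metric_estimate` list: name, point, boot_median, ci_low,
#'   ci_high, n_boot, seed.
#' @export
bootstrap_summary <- function(metric_fn, labels, scores, n_boot = 1000L,
                              seed = 1L, ..., name = "metric") {
  check_binary(labels)
  n <- length(labels)
  point <- metric_fn(labels, scores, ...)
  set.seed(derive_seed(seed, paste0("boot-", name)))
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- resample_both_classes(labels, n)
    vals[b] <- metric_fn(labels[idx], scores[idx], ...)
  }
  qs <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(
    list(name = name, point = point, boot_median = qs[2], ci_low = qs[1],
         ci_high = qs[3], n_boot = n_boot, seed = seed),
    class = "metric_estimate"
  )
}

resample_both_classes <- function(labels, n, max_retry = 100L) {
  for (r in seq_len(max_retry)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) == 2) return(idx)
  }
  stop("could not draw a bootstrap resample containing both classes")
}

#' Paired bootstrap comparison of two models
#'
#' Resamples the same patient rows for both score vectors and summarizes
#' the distribution of metric differences (model A minus model B). The
#' difference is significant when the 95% CI excludes zero.
#'
#' @inheritParams bootstrap_summary
#' @param scores_a,scores_b score vectors for the two models, aligned with
#'   `labels`.
#' @return a `metric_estimate` for the difference, with a `significant`
#'   field.
#' @export
bootstrap_paired_diff <- function(metric_fn, labels, scores_a, scores_b,
                                  n_boot = 1000L, seed = 1L, ...,
                                  name = "metric_diff") {
  check_binary(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n <- length(labels)
  point <- metric_fn(labels, scores_a, ...) - metric_fn(labels, scores_b, ...)
  set.seed(derive_seed(seed, paste0("boot-", name)))
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- resample_both_classes(labels, n)
    vals[b] <- metric_fn(labels[idx], scores_a[idx], ...) -
      metric_fn(labels[idx], scores_b[idx], ...)
  }
  qs <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(
    list(name = name, point = point, boot_median = qs[2], ci_low = qs[1],
         ci_high = qs[3], n_boot = n_boot, seed = seed,
         significant = qs[1] > 0 || qs[3] < 0),
    class = "metric_estimate"
  )
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (boot median %.4f, 95%% CI %.4f..%.4f, B=%d)\n",
              x$name, x$point, x$boot_median, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Scaling slope of performance against pretraining set size
#'
#' Ordinary least squares of performance on log10(size).
#'
#' @param pretrain_sizes numeric sizes (at least two distinct values).
#' @param performances aligned performance values.
#' @return the OLS slope.
#' @export
scaling_slope <- function(pretrain_sizes, performances) {
  if (length(unique(pretrain_sizes)) < 2) {
    stop("scaling slope needs at least two distinct sizes")
  }
  x <- log10(pretrain_sizes)
  unname(stats::coef(stats::lm(performances ~ x))[2])
}

#' Reclassification of patients between two risk models
#'
#' At each threshold t, classify with `1[p >= t]`; report the fraction of
#' patients the base model got wrong and the new model gets right
#' (`correct_frac`) and the reverse (`incorrect_frac`).
#'
#' @param labels binary 0/1 vector.
#' @param p_base,p_new probability vectors for the base and new model.
#' @param thresholds risk thresholds in (0, 1).
#' @return data.frame with threshold, correct_frac, incorrect_frac.
#' @export
reclassification <- function(labels, p_base, p_new,
                             thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(p_base) == length(labels),
            length(p_new) == length(labels))
  n <- length(labels)
  res <- lapply(thresholds, function(t) {
    base_right <- as.integer(p_base >= t) == labels
    new_right <- as.integer(p_new >= t) == labels
    data.frame(threshold = t,
               correct_frac = sum(!base_right & new_right) / n,
               incorrect_frac = sum(base_right & !new_right) / n)
  })
  do.call(rbind, res)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (>= 3 points, non-constant).
#' @return correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("inputs must be non-constant")
  stats::cor(x, y)
}
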