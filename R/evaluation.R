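#' Leave-one-out cross-validation of the full pipeline
#'
#' For each patient in turn, the variance filter, the rank-sum feature
#' ranking, any internal hyperparameter tuning and the classifier fit are
#' computed on the other n-1 patients only, and the held-out patient's
#' probability of coeliac disease is predicted. Replicate aggregation and
#' the wavelet transform are deterministic per-sample operations and are
#' computed once up front; everything that sees class labels or pools
#' information across samples is refitted inside every fold, so the held-out
#' patient can never influence the features or model used to predict it.
#'
#' @param cohort list of [faims_sample()] objects, at least two patients per
#'   class.
#' @param config a [pipeline_config()].
#' @param nested if `TRUE` (the default and the only statistically valid
#'   choice), feature selection is nested inside the CV loop. `FALSE`
#'   deliberately fits the variance filter and rank-sum selection on all
#'   samples before the loop; this leaks the held-out labels into feature
#'   selection and exists only as a diagnostic to demonstrate (and test) the
#'   optimistic bias that nesting prevents.
#' @return A data frame of class `cv_predictions` with columns
#'   `patient_id`, `label`, `prob_cd` (one row per patient), and attribute
#'   `"fold_features"`: the per-fold selected coefficient indices.
#' @export
run_loo_cv <- function(cohort, config = pipeline_config(), nested = TRUE) {
  labels <- cohort_labels(cohort)
  fd_check_label(labels)
  if (sum(labels == "CD") < 2L || sum(labels == "D-IBS") < 2L) {
    stop("need at least two patients per class", call. = FALSE)
  }
  X <- cohort_feature_matrix(cohort, config$wavelet)
  n <- nrow(X)
  leaky_sel <- if (!nested) {
    mask <- fit_variance_filter(X, config$variance_value,
                                mode = config$variance_mode)
    select_top_k(X, labels, config$k, mask)
  }
  probs <- numeric(n)
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2L) {
      stop("a class is absent from the training fold for patient ",
           cohort[[i]]$patient_id, call. = FALSE)
    }
    sel <- if (nested) {
      mask <- fit_variance_filter(X[tr, , drop = FALSE],
                                  config$variance_value,
                                  mode = config$variance_mode)
      select_top_k(X[tr, , drop = FALSE], labels[tr], config$k, mask)
    } else {
      leaky_sel
    }
    keep <- sel$keep
    fold_features[[i]] <- keep
    spec <- config$classifier
    spec$seed <- fd_subseed(config$seed, i)
    model <- fit_classifier(spec, X[tr, keep, drop = FALSE], labels[tr])
    probs[i] <- predict_probability(model, X[i, keep, drop = FALSE])
    fd_log("fold %d/%d: %d features selected", i, n, length(keep))
  }
  out <- data.frame(patient_id = cohort_ids(cohort), label = labels,
                    prob_cd = probs, stringsAsFactors = FALSE)
  attr(out, "fold_features") <- fold_features
  class(out) <- c("cv_predictions", "data.frame")
  out
}

check_predictions <- function(predictions) {
  stopifnot(all(c("label", "prob_cd") %in% names(predictions)))
  fd_check_label(predictions$label)
  if (length(unique(predictions$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(predictions)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen coeliac
#' patient receives a higher predicted probability than a randomly chosen
#' control, with ties counted 1/2 — identical to the normalized rank-sum
#' statistic U / (n1 n2).
#'
#' @param predictions data frame with columns `label` and `prob_cd`.
#' @return AUC in \[0,1\].
#' @export
auc_score <- function(predictions) {
  check_predictions(predictions)
  is_case <- predictions$label == "CD"
  r <- rank(predictions$prob_cd)
  n1 <- sum(is_case); n2 <- sum(!is_case)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores from +Inf down,
#' classifying as coeliac when `prob_cd >= threshold`. Returns the staircase
#' from (0,0) to (1,1); tied scores move diagonally, so the trapezoidal area
#' under these points equals [auc_score()] exactly.
#'
#' @param predictions data frame with columns `label` and `prob_cd`.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, both rates
#'   non-decreasing down the rows.
#' @export
roc_points <- function(predictions) {
  check_predictions(predictions)
  is_case <- predictions$label == "CD"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  thr <- sort(unique(predictions$prob_cd), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(is_case & predictions$prob_cd >= t), 0)
  fp <- vapply(thr, function(t) sum(!is_case & predictions$prob_cd >= t), 0)
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n2),
             tpr = c(0, tp / n1))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Choose the operating threshold by Youden's J
#'
#' Scans the ROC thresholds and returns the one maximizing
#' J = sensitivity + specificity - 1, the standard formalization of "a
#' threshold that gives good values for both". Ties in J are broken toward
#' the smaller threshold.
#'
#' @param predictions data frame with columns `label` and `prob_cd`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`,
#'   and the confusion counts `tp`, `fn`, `tn`, `fp` at that threshold.
#' @export
choose_threshold <- function(predictions) {
  check_predictions(predictions)
  roc <- roc_points(predictions)
  j <- roc$tpr - roc$fpr
  # ties toward the smaller threshold: scan is threshold-descending, so the
  # last maximal row wins
  best <- max(which(j == max(j)))
  thr <- roc$threshold[best]
  is_case <- predictions$label == "CD"
  pred_pos <- predictions$prob_cd >= thr
  list(threshold = thr,
       sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best],
       youden_j = j[best],
       tp = sum(pred_pos & is_case), fn = sum(!pred_pos & is_case),
       tn = sum(!pred_pos & !is_case), fp = sum(pred_pos & !is_case))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval from Beta distribution quantiles:
#' lower = qbeta(a/2, s, n-s+1), upper = qbeta(1-a/2, s+1, n-s), with the
#' conventional boundary values 0 and 1 when the count is at an extreme.
#' This is the interval that reproduces printed sensitivity/specificity
#' bounds such as 23/27 -> (0.66, 0.96) and 17/20 -> (0.62, 0.97) at the
#' 95% level.
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param level confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' round(binomial_ci(23, 27), 2)  # 0.66 0.96
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    stop("need 0 <= successes <= trials with trials >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  a <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(a / 2, successes,
                                            trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - a / 2, successes + 1,
                                                 trials - successes)
  c(lower = lower, upper = upper)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval over class-stratified bootstrap resamples of the
#' held-out predictions: cases and controls are resampled separately so
#' every resample contains both classes. Deterministic for a given seed.
#'
#' @param predictions data frame with columns `label` and `prob_cd`.
#' @param method interval method; `"bootstrap"` (stratified percentile) is
#'   the only one implemented.
#' @param reps number of bootstrap resamples (>= 100; default 2000).
#' @param level confidence level, default 0.95.
#' @param seed integer RNG seed.
#' @return Numeric `c(lower, upper)`.
#' @export
auc_confidence_interval <- function(predictions, method = "bootstrap",
                                    reps = 2000, level = 0.95, seed = 1L) {
  method <- match.arg(method)
  check_predictions(predictions)
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  is_case <- predictions$label == "CD"
  cases <- predictions$prob_cd[is_case]
  ctrls <- predictions$prob_cd[!is_case]
  n1 <- length(cases); n2 <- length(ctrls)
  set.seed(seed)
  stats <- vapply(seq_len(reps), function(b) {
    pc <- sample(cases, n1, replace = TRUE)
    pd <- sample(ctrls, n2, replace = TRUE)
    r <- rank(c(pc, pd))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }, 0)
  a <- 1 - level
  ci <- as.numeric(quantile(stats, probs = c(a / 2, 1 - a / 2), type = 7))
  c(lower = ci[1L], upper = ci[2L])
}

#' Pearson correlation of predicted probability with a clinical covariate
#'
#' Optionally excludes patients whose covariate exceeds a cutoff (e.g.
#' anti-TTG titres above 60 kU/L) before computing the correlation; any
#' exclusion is logged. Pairs with missing values are dropped.
#'
#' @param predictions data frame with column `prob_cd`.
#' @param covariate numeric vector aligned with the rows of `predictions`.
#' @param exclude_above optional cutoff; rows with `covariate > cutoff` are
#'   removed first.
#' @return Pearson r in \[-1,1\].
#' @export
correlate_probability <- function(predictions, covariate,
                                  exclude_above = NULL) {
  stopifnot(length(covariate) == nrow(predictions))
  keep <- is.finite(covariate) & is.finite(predictions$prob_cd)
  if (!is.null(exclude_above)) {
    excl <- keep & covariate > exclude_above
    if (any(excl)) {
      fd_log("excluding %d point(s) with covariate > %g", sum(excl),
             exclude_above)
    }
    keep <- keep & !excl
  }
  x <- covariate[keep]; y <- predictions$prob_cd[keep]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0) stop("covariate is constant; correlation undefined",
                       call. = FALSE)
  if (sd(y) == 0) stop("probabilities are constant; correlation undefined",
                       call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Evaluate held-out predictions: AUC, threshold, and exact intervals
#'
#' Combines the ROC machinery into the reported metric set: AUC with a
#' stratified-bootstrap percentile interval, the Youden-optimal threshold,
#' and sensitivity/specificity at that threshold with exact Clopper-Pearson
#' intervals.
#'
#' @param predictions data frame from [run_loo_cv()].
#' @param level confidence level (default 0.95).
#' @param boot_reps bootstrap resamples for the AUC interval.
#' @param seed RNG seed for the bootstrap.
#' @return List of class `roc_result` with elements `auc`, `auc_ci`,
#'   `threshold`, `sensitivity`, `sensitivity_ci`, `specificity`,
#'   `specificity_ci`, `roc` (the curve points), `n_cases`, `n_controls`.
#' @export
evaluate_predictions <- function(predictions, level = 0.95, boot_reps = 2000,
                                 seed = 1L) {
  check_predictions(predictions)
  thr <- choose_threshold(predictions)
  res <- list(
    auc = auc_score(predictions),
    auc_ci = auc_confidence_interval(predictions, reps = boot_reps,
                                     level = level, seed = seed),
    threshold = thr$threshold,
    sensitivity = thr$sensitivity,
    sensitivity_ci = binomial_ci(thr$tp, thr$tp + thr$fn, level),
    specificity = thr$specificity,
    specificity_ci = binomial_ci(thr$tn, thr$tn + thr$fp, level),
    roc = roc_points(predictions),
    n_cases = sum(predictions$label == "CD"),
    n_controls = sum(predictions$label == "D-IBS"))
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  fmt_ci <- function(ci) sprintf("(%.2f-%.2f)", ci[1L], ci[2L])
  cat(sprintf("AUC         %.2f %s\n", x$auc, fmt_ci(x$auc_ci)))
  cat(sprintf("Sensitivity %.2f %s at threshold %.3g\n", x$sensitivity,
              fmt_ci(x$sensitivity_ci), x$threshold))
  cat(sprintf("Specificity %.2f %s\n", x$specificity,
              fmt_ci(x$specificity_ci)))
  cat(sprintf("%d cases vs %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Reporting bundle for a completed cross-validation run
#'
#' Assembles the descriptive outputs of a run: a heatmap matrix of the
#' selected wavelet features (rows = patients sorted by class, columns =
#' the feature set selected in the first CV fold, mirroring a
#' single-fold selected-feature display), a probability-by-group
#' box-and-whisker summary (quartiles; whiskers show the data range
#' truncated to at most twice the interquartile range beyond the box), and
#' a probability-by-Marsh-score cross-tabulation over the bins 0-0.2,
#' 0.2-0.4, 0.4-0.6, 0.6-0.8, 0.8-1 (upper bin right-closed).
#'
#' @param predictions data frame from [run_loo_cv()] (with the
#'   `fold_features` attribute).
#' @param cohort the cohort the predictions came from.
#' @param config the [pipeline_config()] used.
#' @return List of class `faims_report` with elements `heatmap` (numeric
#'   matrix with patient rownames, feature-index colnames), `group_summary`
#'   (data frame, one row per class), `crosstab` (Marsh score by probability
#'   bin contingency table).
#' @export
report <- function(predictions, cohort, config = pipeline_config()) {
  check_predictions(predictions)
  stopifnot(nrow(predictions) == length(cohort))
  X <- cohort_feature_matrix(cohort, config$wavelet)
  folds <- attr(predictions, "fold_features")
  feats <- if (!is.null(folds)) folds[[1L]] else seq_len(min(ncol(X), 30L))
  ord <- order(match(predictions$label, FD_LABELS), predictions$patient_id)
  heat <- X[ord, feats, drop = FALSE]
  rownames(heat) <- predictions$patient_id[ord]
  colnames(heat) <- paste0("w", feats)

  group_summary <- do.call(rbind, lapply(FD_LABELS, function(lab) {
    p <- predictions$prob_cd[predictions$label == lab]
    q <- quantile(p, c(0.25, 0.5, 0.75), type = 7)
    iqr <- q[3L] - q[1L]
    data.frame(label = lab, n = length(p),
               q1 = q[1L], median = q[2L], q3 = q[3L],
               whisker_low = max(min(p), q[1L] - 2 * iqr),
               whisker_high = min(max(p), q[3L] + 2 * iqr),
               row.names = NULL)
  }))

  bins <- cut(predictions$prob_cd, breaks = seq(0, 1, by = 0.2),
              right = FALSE, include.lowest = TRUE,
              labels = c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1"))
  marsh <- vapply(cohort, `[[`, "", "marsh")
  marsh <- factor(marsh, levels = c("I", "II", "IIIa", "IIIb", "IIIc"))
  crosstab <- table(marsh = marsh, probability = bins, useNA = "no")

  structure(list(heatmap = heat, group_summary = group_summary,
                 crosstab = crosstab),
            class = "faims_report")
}

#' Write a report bundle to a directory
#'
#' Emits `heatmap.tsv` (selected-feature matrix), `group_summary.csv`,
#' `crosstab.csv`, and if `metrics` is supplied, `metrics.json`.
#'
#' @param rep a [report()] bundle.
#' @param dir output directory (created if absent).
#' @param metrics optional `roc_result` from [evaluate_predictions()].
#' @return `dir`, invisibly.
#' @export
write_report <- function(rep, dir, metrics = NULL) {
  stopifnot(inherits(rep, "faims_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(rep$heatmap, file.path(dir, "heatmap.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.csv(rep$group_summary, file.path(dir, "group_summary.csv"),
            row.names = FALSE)
  write.csv(as.data.frame.matrix(rep$crosstab),
            file.path(dir, "crosstab.csv"))
  if (!is.null(metrics)) {
    jsonlite::write_json(
      list(auc = metrics$auc, auc_ci = unname(metrics$auc_ci),
           threshold = metrics$threshold,
           sensitivity = metrics$sensitivity,
           sensitivity_ci = unname(metrics$sensitivity_ci),
           specificity = metrics$specificity,
           specificity_ci = unname(metrics$specificity_ci)),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  fd_log("wrote report bundle under %s", dir)
  invisible(dir)
}
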