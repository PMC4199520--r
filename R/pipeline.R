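#' Aggregate a sample's replicate scans into one raw feature vector
#'
#' Each replicate is flattened row-major (positive-polarity matrix first,
#' then negative) and the replicates are averaged element-wise, yielding one
#' vector per patient. Averaging at the patient level keeps all downstream
#' cross-validation patient-wise: replicates of one patient can never
#' straddle a training/test split.
#'
#' @param sample a [faims_sample()].
#' @return A raw [feature_vector()] of length
#'   `prod(dim positive) + prod(dim negative)`.
#' @export
aggregate_replicates <- function(sample) {
  stopifnot(inherits(sample, "faims_sample"))
  flatten <- function(rep) {
    c(as.vector(t(rep$positive$current)), as.vector(t(rep$negative$current)))
  }
  vecs <- lapply(sample$replicates, flatten)
  n <- lengths(vecs)
  if (length(unique(n)) != 1L) {
    stop("replicate shape mismatch for patient ", sample$patient_id,
         call. = FALSE)
  }
  feature_vector(Reduce(`+`, vecs) / length(vecs), "raw")
}

# column-wise unbiased (n-1) variance of a numeric matrix, no copies
col_variances <- function(X) {
  n <- nrow(X)
  if (n < 2L) stop("variance undefined for fewer than 2 rows", call. = FALSE)
  mu <- colMeans(X)
  colSums(X^2) / (n - 1) - mu^2 * n / (n - 1)
}

#' Variance filter over wavelet coefficients
#'
#' Keeps the coefficients whose sample variance across the training rows is
#' at or above a cutoff; low-variance coefficients are treated as noise-
#' dominated and dropped. The cutoff may be absolute or a variance quantile
#' computed on the same training rows (e.g. mode `"quantile"`, value 0.95
#' keeps the top 5% of coefficients by variance). Must only ever be fitted
#' on training rows of a cross-validation fold.
#'
#' @param train a numeric matrix, one row per training sample, one column
#'   per coefficient.
#' @param threshold cutoff value; interpretation set by `mode`.
#' @param mode `"absolute"` (variance cutoff in squared signal units) or
#'   `"quantile"` (threshold is the variance quantile in \[0,1) below which
#'   coefficients are dropped).
#' @return A logical keep-mask of length `ncol(train)`, with the fitted
#'   absolute cutoff in attribute `"cutoff"` and the per-column variances in
#'   attribute `"variances"`.
#' @export
fit_variance_filter <- function(train, threshold,
                                mode = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  if (nrow(train) < 2L) {
    stop("variance filter needs at least 2 training samples", call. = FALSE)
  }
  v <- col_variances(train)
  cutoff <- switch(mode,
    absolute = threshold,
    quantile = {
      if (threshold < 0 || threshold >= 1) {
        stop("quantile threshold must be in [0, 1)", call. = FALSE)
      }
      as.numeric(quantile(v, probs = threshold, type = 7))
    })
  mask <- v >= cutoff
  structure(mask, cutoff = cutoff, variances = v)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midrank tie handling. The statistic is the
#' Mann-Whitney U of `x` relative to `y`. The p-value is exact (from the
#' exact null distribution of U) when the pooled sample size is at most 12
#' and there are no ties, and otherwise uses the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples from the two groups, each non-empty.
#' @return List with elements `statistic` (U), `p.value`, and `exact`
#'   (logical, whether the exact branch was used).
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(c(x, y)))) stop("inputs must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  if (exact) {
    # U follows the exact Wilcoxon null distribution over all C(n1+n2, n1)
    # equally likely rank assignments
    p_lo <- pwilcox(U, n1, n2)
    p_hi <- if (U >= 1) 1 - pwilcox(U - 1, n1, n2) else 1
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    tie_counts <- table(c(x, y))
    sigma2 <- (n1 * n2 / 12) *
      (n1 + n2 + 1 - sum(tie_counts^3 - tie_counts) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p.value = 1, exact = FALSE))
    z <- U - mu
    z <- z - sign(z) * 0.5  # continuity correction
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p.value = p, exact = exact)
}

# vectorized two-sided rank-sum p-values per column (normal approximation
# with tie/continuity correction; used for fold-level feature ranking where
# group sizes always exceed the exact-branch regime)
rank_sum_pvalues <- function(X, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  apply(X, 2L, function(col) {
    rank_sum_test(col[is_case], col[!is_case])$p.value
  })
}

#' Select the most class-informative features by rank-sum p-value
#'
#' Ranks the variance-masked coefficients by two-sided Wilcoxon rank-sum
#' p-value between the two classes and keeps the `k` smallest. Ties in p are
#' broken by ascending coefficient index, so selection is deterministic.
#' Like the variance filter, this must only see training rows; inside
#' cross-validation it is refitted within every fold.
#'
#' @param train numeric training matrix (rows = samples).
#' @param labels class label per row (`"CD"` / `"D-IBS"`).
#' @param k number of features to keep; if fewer masked features are
#'   available, all are kept with a warning.
#' @param mask logical variance keep-mask from [fit_variance_filter()]
#'   (default: keep all columns).
#' @return A list of class `selection_model`: `keep` (selected column
#'   indices, p-ascending), `pvalues` (per masked feature), `mask`, `k`.
#' @export
select_top_k <- function(train, labels, k, mask = NULL) {
  train <- as.matrix(train)
  fd_check_label(labels)
  if (length(labels) != nrow(train)) {
    stop("labels must match training rows", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, ncol(train))
  cand <- which(mask)
  if (length(cand) == 0L) stop("variance mask keeps no features", call. = FALSE)
  is_case <- labels == "CD"
  if (!any(is_case) || all(is_case)) {
    stop("both classes must be present to rank features", call. = FALSE)
  }
  p <- rank_sum_pvalues(train[, cand, drop = FALSE], is_case)
  if (k > length(cand)) {
    warning("k = ", k, " exceeds ", length(cand),
            " available features; keeping all", call. = FALSE)
    k <- length(cand)
  }
  ord <- order(p, cand)  # ties broken by ascending coefficient index
  structure(list(keep = cand[ord[seq_len(k)]],
                 pvalues = setNames(p, cand), mask = mask, k = k),
            class = "selection_model")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the feature pipeline and classifier so a whole
#' cross-validated analysis is reproducible from one object.
#'
#' @param wavelet a [wavelet_config()].
#' @param variance_mode,variance_value variance-filter mode and value (see
#'   [fit_variance_filter()]); the default keeps the top 5% of coefficients
#'   by training-fold variance.
#' @param k number of rank-sum-selected features (default 30).
#' @param classifier a [classifier_spec()].
#' @param seed integer seed controlling classifier fitting randomness
#'   (internal CV folds, tree bootstraps).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelet = wavelet_config(),
                            variance_mode = "quantile",
                            variance_value = 0.95,
                            k = 30,
                            classifier = classifier_spec(),
                            seed = 1L) {
  structure(list(wavelet = wavelet, variance_mode = variance_mode,
                 variance_value = variance_value, k = as.integer(k),
                 classifier = classifier, seed = as.integer(seed)),
            class = "pipeline_config")
}

# cohort -> per-patient wavelet coefficient matrix (one row per patient).
# Aggregation and the (deterministic, per-sample) transform are safely
# computed once outside the CV loop; everything label-aware is not.
cohort_feature_matrix <- function(cohort, wavelet = wavelet_config()) {
  rows <- lapply(cohort, function(s) {
    dwt_forward(aggregate_replicates(s), wavelet)$values
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1L) {
    stop("samples disagree on grid shape", call. = FALSE)
  }
  do.call(rbind, rows)
}
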