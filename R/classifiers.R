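#' Classifier specification
#'
#' One uniform contract over the three classifier families used for the
#' discrimination task. Hyperparameters not supplied fall back to defaults:
#' elastic-net mixing `alpha = 0.5` with the penalty strength chosen by
#' internal 5-fold cross-validation on the training fold; 500 trees for the
#' random forest; a linear-kernel SVM with `cost = 1`.
#'
#' @param kind `"sparse_logistic"` (elastic-net-penalized logistic
#'   regression), `"random_forest"`, or `"svm"`.
#' @param alpha elastic-net mixing parameter in \[0,1\] (sparse_logistic).
#' @param lambda optional fixed penalty strength; `NULL` (default) tunes it
#'   by internal cross-validation inside the training fold.
#' @param weights `"balanced"` (default) weights observations inversely to
#'   their class frequency in the sparse logistic fit, so the no-information
#'   (intercept-only) prediction is 0.5 rather than the training-fold base
#'   rate. Under leave-one-out CV the base rate mechanically anti-correlates
#'   with the held-out label, so unbalanced fits (`"none"`) make a null
#'   cohort score an AUC far below 0.5 instead of 0.5.
#' @param ntree number of trees (random_forest).
#' @param kernel,cost SVM kernel and regularization constant.
#' @param seed integer seed for the stochastic parts (internal CV fold
#'   assignment, tree bootstraps).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("sparse_logistic", "random_forest", "svm"),
                            alpha = 0.5, lambda = NULL, ntree = 500,
                            kernel = "linear", cost = 1,
                            weights = c("balanced", "none"), seed = 1L) {
  kind <- match.arg(kind)
  weights <- match.arg(weights)
  structure(list(kind = kind, alpha = alpha, lambda = lambda,
                 ntree = as.integer(ntree), kernel = kernel, cost = cost,
                 weights = weights, seed = as.integer(seed)),
            class = "classifier_spec")
}

# silence glmnet's advisory warning about small class counts in internal CV
# folds; small training folds are routine under leave-one-out at pilot scale
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("dangerous ground|fewer than|grouped=FALSE", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Fit a classifier to a training fold
#'
#' Trains the model named by `spec` on a feature matrix with class labels,
#' encoding coeliac disease as the positive class (probability 1). All
#' internal tuning (the elastic-net penalty path and its cross-validation)
#' happens strictly within the rows supplied here, so nothing outside the
#' training fold can influence the fit. Fits are deterministic given
#' `spec$seed`.
#'
#' @param spec a [classifier_spec()].
#' @param features numeric matrix, samples in rows.
#' @param labels `"CD"` / `"D-IBS"` per row; both classes must be present.
#' @return An object of class `trained_model`. For `sparse_logistic` the
#'   element `coefficients` exposes the fitted coefficient vector
#'   (intercept first) for sparsity inspection.
#' @export
fit_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  fd_check_label(labels)
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (!all(is.finite(features))) {
    stop("features must be finite", call. = FALSE)
  }
  y <- factor(labels, levels = c("D-IBS", "CD"))  # CD = positive class
  fit <- switch(spec$kind,
    sparse_logistic = {
      # glmnet needs >= 2 columns; duplicate a single feature if needed
      x <- if (ncol(features) == 1L) cbind(features, features) else features
      w <- if (identical(spec$weights, "balanced")) {
        as.numeric(length(y) / (2 * table(y)[y]))
      } else {
        rep(1, length(y))
      }
      m_min <- min(table(y))
      if (is.null(spec$lambda) && m_min >= 3L) {
        set.seed(spec$seed)
        # class-stratified internal folds: every internal training split
        # keeps at least two members of each class. Folds are derived from a
        # label-independent permutation, so relabelling the classes leaves
        # the fold assignment unchanged (this is what makes label swap map
        # probabilities exactly to their complement).
        nfolds <- min(5L, m_min)
        perm <- sample(length(y))
        foldid <- integer(length(y))
        for (lev in levels(y)) {
          idx <- which(y == lev)
          foldid[idx[order(match(idx, perm))]] <-
            rep_len(seq_len(nfolds), length(idx))
        }
        cv <- quiet_glmnet(
          glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                            alpha = spec$alpha, foldid = foldid,
                            nlambda = 50))
        list(model = cv$glmnet.fit, lambda = cv$lambda.min)
      } else if (is.null(spec$lambda)) {
        # too few samples per class for internal CV: moderate fixed penalty
        m <- quiet_glmnet(glmnet::glmnet(x, y, family = "binomial",
                                         weights = w, alpha = spec$alpha))
        list(model = m, lambda = 0.1)
      } else {
        m <- quiet_glmnet(glmnet::glmnet(x, y, family = "binomial",
                                         weights = w, alpha = spec$alpha))
        list(model = m, lambda = spec$lambda)
      }
    },
    random_forest = {
      set.seed(spec$seed)
      list(model = randomForest::randomForest(features, y,
                                              ntree = spec$ntree))
    },
    svm = {
      list(model = e1071::svm(features, y, kernel = spec$kernel,
                              cost = spec$cost, scale = ncol(features) > 1L))
    })
  out <- structure(
    list(spec = spec, fit = fit, n_features = ncol(features)),
    class = "trained_model")
  if (spec$kind == "sparse_logistic") {
    beta <- as.numeric(stats::coef(fit$model, s = fit$lambda))
    if (ncol(features) == 1L) beta <- beta[1:2]  # undo column duplication
    out$coefficients <- beta
  }
  out
}

#' Predict the probability of coeliac disease
#'
#' Applies a [fit_classifier()] model to one or more feature vectors and
#' returns the predicted probability of the positive (coeliac) class, always
#' in \[0,1\]. For the SVM the score is the signed distance from the
#' separating hyperplane mapped through the logistic function: a monotone
#' transform of the margin, so ROC ranking is that of the margin itself.
#'
#' @param model a `trained_model`.
#' @param features numeric vector (one sample) or matrix (samples in rows)
#'   with the same number of features the model was trained on.
#' @return Numeric vector of probabilities in \[0,1\].
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature count mismatch: model expects ", model$n_features,
         ", got ", ncol(features), call. = FALSE)
  }
  p <- switch(model$spec$kind,
    sparse_logistic = {
      x <- if (ncol(features) == 1L) cbind(features, features) else features
      as.numeric(predict(model$fit$model, newx = x, s = model$fit$lambda,
                         type = "response"))
    },
    random_forest = {
      as.numeric(predict(model$fit$model, features, type = "prob")[, "CD"])
    },
    svm = {
      pr <- predict(model$fit$model, features, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 names the column "A/B": positive margin favours class A
      margin <- if (grepl("^CD/", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
      as.numeric(plogis(margin))
    })
  pmin(1, pmax(0, p))
}
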