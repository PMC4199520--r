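# well-separated 2-D clusters: any sane classifier separates them
separable_toy <- function(n = 12, gap = 6, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, mean = gap), ncol = 2),
             matrix(rnorm(2 * n, mean = 0), ncol = 2))
  list(x = x, y = rep(c("CD", "D-IBS"), each = n))
}

test_that("all three classifiers separate a noiseless toy problem", {
  toy <- separable_toy()
  for (kind in c("sparse_logistic", "random_forest", "svm")) {
    m <- fit_classifier(classifier_spec(kind, seed = 2), toy$x, toy$y)
    p <- predict_probability(m, toy$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(p[toy$y == "CD"] > 0.5), info = kind)
    expect_true(all(p[toy$y == "D-IBS"] < 0.5), info = kind)
    preds <- data.frame(label = toy$y, prob_cd = p)
    expect_equal(auc_score(preds), 1.0, info = kind)
  }
})

test_that("an overwhelming penalty collapses to the intercept-only model", {
  toy <- separable_toy()
  # unweighted fit: intercept-only predicts the training prevalence
  y_unbal <- c(toy$y, rep("CD", 8))
  x_unbal <- rbind(toy$x, toy$x[1:8, ])
  m <- fit_classifier(classifier_spec(lambda = 1e6, weights = "none"),
                      x_unbal, y_unbal)
  expect_true(all(abs(m$coefficients[-1]) < 1e-8))
  expect_equal(predict_probability(m, c(0, 0)), mean(y_unbal == "CD"),
               tolerance = 1e-6)
  # balanced weights move the no-information prediction to 0.5
  mb <- fit_classifier(classifier_spec(lambda = 1e6), x_unbal, y_unbal)
  expect_equal(predict_probability(mb, c(0, 0)), 0.5, tolerance = 1e-6)
})

test_that("fits are deterministic for a fixed seed", {
  set.seed(77)
  x <- matrix(rnorm(200), ncol = 5)
  y <- rep(c("CD", "D-IBS"), each = 20)
  x[y == "CD", 1] <- x[y == "CD", 1] + 1
  for (kind in c("sparse_logistic", "random_forest", "svm")) {
    m1 <- fit_classifier(classifier_spec(kind, seed = 9), x, y)
    m2 <- fit_classifier(classifier_spec(kind, seed = 9), x, y)
    expect_identical(predict_probability(m1, x), predict_probability(m2, x),
                     info = kind)
  }
})

test_that("swapping class labels flips probabilities", {
  set.seed(31)
  x <- matrix(rnorm(120), ncol = 3)
  y <- rep(c("CD", "D-IBS"), each = 20)
  x[y == "CD", 2] <- x[y == "CD", 2] + 1.5
  y_flip <- ifelse(y == "CD", "D-IBS", "CD")
  xt <- matrix(rnorm(30), ncol = 3)

  m <- fit_classifier(classifier_spec("sparse_logistic", seed = 4), x, y)
  mf <- fit_classifier(classifier_spec("sparse_logistic", seed = 4), x, y_flip)
  expect_equal(predict_probability(m, xt), 1 - predict_probability(mf, xt),
               tolerance = 1e-6)

  # deterministic margin model: near-exact complement
  m <- fit_classifier(classifier_spec("svm", seed = 4), x, y)
  mf <- fit_classifier(classifier_spec("svm", seed = 4), x, y_flip)
  expect_lt(max(abs(predict_probability(m, xt) -
                      (1 - predict_probability(mf, xt)))), 0.01)

  # vote-based model: symmetric up to bootstrap noise of the ensemble
  m <- fit_classifier(classifier_spec("random_forest", ntree = 1000,
                                      seed = 4), x, y)
  mf <- fit_classifier(classifier_spec("random_forest", ntree = 1000,
                                       seed = 4), x, y_flip)
  dev <- abs(predict_probability(m, xt) - (1 - predict_probability(mf, xt)))
  expect_lt(mean(dev), 0.05)
  expect_lt(max(dev), 0.1)
})

test_that("single-feature logistic probability is monotone in the feature", {
  set.seed(8)
  x <- matrix(c(rnorm(15, 2), rnorm(15, -2)), ncol = 1)
  y <- rep(c("CD", "D-IBS"), each = 15)
  m <- fit_classifier(classifier_spec(lambda = 0.01), x, y)
  grid <- matrix(seq(-4, 4, length.out = 30), ncol = 1)
  p <- predict_probability(m, grid)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("contract violations are rejected", {
  toy <- separable_toy()
  expect_error(fit_classifier(classifier_spec(), toy$x, rep("CD", nrow(toy$x))),
               "both classes")
  expect_error(fit_classifier(classifier_spec(), toy$x,
                              rep("weird", nrow(toy$x))), "labels")
  m <- fit_classifier(classifier_spec(), toy$x, toy$y)
  expect_error(predict_probability(m, matrix(0, 1, 5)), "feature count")
})
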