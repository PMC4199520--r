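toy_preds <- data.frame(
  patient_id = c("a", "b", "c", "d"),
  label = c("CD", "CD", "D-IBS", "D-IBS"),
  prob_cd = c(0.9, 0.6, 0.7, 0.2))

test_that("AUC matches pairwise enumeration and handles ties at 1/2", {
  expect_equal(auc_score(toy_preds), 3 / 4)
  expect_equal(auc_score(toy_preds), pairwise_auc(toy_preds$label,
                                                  toy_preds$prob_cd))

  perfect <- data.frame(label = rep(c("CD", "D-IBS"), each = 3),
                        prob_cd = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(auc_score(perfect), 1.0)

  flat <- data.frame(label = rep(c("CD", "D-IBS"), each = 3),
                     prob_cd = rep(0.4, 6))
  expect_equal(auc_score(flat), 0.5)

  expect_error(auc_score(data.frame(label = rep("CD", 3),
                                    prob_cd = runif(3))), "both classes")
})

test_that("ROC points form the hand-enumerated staircase for the toy set", {
  roc <- roc_points(toy_preds)
  expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(roc$threshold[-1], c(0.9, 0.7, 0.6, 0.2))
  # endpoints and monotonicity
  expect_equal(unlist(roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # a perfect classifier passes through (0, 1)
  perfect <- data.frame(label = rep(c("CD", "D-IBS"), each = 2),
                        prob_cd = c(0.9, 0.8, 0.3, 0.1))
  rocp <- roc_points(perfect)
  expect_true(any(rocp$fpr == 0 & rocp$tpr == 1))
})

test_that("trapezoidal area under roc_points equals auc_score exactly", {
  set.seed(40)
  for (i in 1:50) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    p <- round(runif(n1 + n2), sample(1:3, 1))  # ties likely
    preds <- data.frame(label = rep(c("CD", "D-IBS"), c(n1, n2)), prob_cd = p)
    roc <- roc_points(preds)
    expect_equal(trapezoid_area(roc$fpr, roc$tpr), auc_score(preds),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    p <- round(runif(n1 + n2), 2)
    preds <- data.frame(label = rep(c("CD", "D-IBS"), c(n1, n2)), prob_cd = p)
    ref <- pROC::auc(pROC::roc(response = preds$label, predictor = preds$prob_cd,
                               levels = c("D-IBS", "CD"), direction = "<",
                               quiet = TRUE))
    expect_equal(auc_score(preds), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Youden threshold maximizes J with ties toward smaller threshold", {
  got <- choose_threshold(toy_preds)
  expect_equal(got$threshold, 0.6)
  expect_equal(got$sensitivity, 1.0)
  expect_equal(got$specificity, 0.5)
  expect_equal(got$youden_j, 0.5)
  expect_equal(got[c("tp", "fn", "tn", "fp")],
               list(tp = 2L, fn = 0L, tn = 1L, fp = 1L))

  perfect <- data.frame(label = rep(c("CD", "D-IBS"), each = 2),
                        prob_cd = c(0.9, 0.8, 0.3, 0.1))
  gp <- choose_threshold(perfect)
  expect_equal(gp$sensitivity, 1.0)
  expect_equal(gp$specificity, 1.0)

  flat <- data.frame(label = rep(c("CD", "D-IBS"), each = 3),
                     prob_cd = rep(0.4, 6))
  gf <- choose_threshold(flat)
  expect_equal(gf$youden_j, 0)
  expect_equal(gf$threshold, 0.4)  # smallest scanned threshold
})

test_that("Clopper-Pearson interval matches Beta quantiles and binom.test", {
  # the two printed-table reconstructions
  expect_equal(round(binomial_ci(23, 27), 2), c(lower = 0.66, upper = 0.96))
  expect_equal(round(binomial_ci(17, 20), 2), c(lower = 0.62, upper = 0.97))

  # closed-form boundary: all successes
  for (n in c(1, 5, 20)) {
    ci <- binomial_ci(n, n)
    expect_equal(ci[["upper"]], 1.0)
    expect_equal(ci[["lower"]], 0.025^(1 / n), tolerance = 1e-12)
  }
  expect_equal(binomial_ci(0, 10)[["lower"]], 0)

  # independent oracle: stats::binom.test implements the same exact interval
  set.seed(14)
  for (i in 1:25) {
    n <- sample(1:60, 1); s <- sample(0:n, 1)
    expect_equal(unname(binomial_ci(s, n)),
                 as.numeric(binom.test(s, n)$conf.int), tolerance = 1e-12)
  }

  expect_error(binomial_ci(5, 4), "successes")
  expect_error(binomial_ci(-1, 4), "successes")
  expect_error(binomial_ci(2, 4, level = 1.2), "level")
})

test_that("bootstrap AUC interval is deterministic, ordered and sane", {
  set.seed(50)
  preds <- data.frame(label = rep(c("CD", "D-IBS"), c(20, 15)),
                      prob_cd = c(rnorm(20, 0.65, 0.15), rnorm(15, 0.4, 0.15)))
  preds$prob_cd <- pmin(1, pmax(0, preds$prob_cd))
  ci1 <- auc_confidence_interval(preds, reps = 300, seed = 7)
  ci2 <- auc_confidence_interval(preds, reps = 300, seed = 7)
  expect_identical(ci1, ci2)
  a <- auc_score(preds)
  expect_true(ci1[["lower"]] <= a && a <= ci1[["upper"]])

  wide <- data.frame(label = rep(c("CD", "D-IBS"), each = 10),
                     prob_cd = rep(c(0.99, 0.01), each = 10))
  expect_equal(auc_confidence_interval(wide, reps = 200)[["upper"]], 1.0)
  expect_error(auc_confidence_interval(preds, reps = 50), "reps")
})

test_that("bootstrap interval covers a known true AUC at roughly 95%", {
  # score model with analytically known AUC: cases N(1,1) vs controls N(0,1)
  # => true AUC = pnorm(1 / sqrt(2))
  true_auc <- pnorm(1 / sqrt(2))
  set.seed(60)
  covered <- 0
  reps <- 200
  for (b in seq_len(reps)) {
    p <- plogis(c(rnorm(27, 1), rnorm(20, 0)))
    preds <- data.frame(label = rep(c("CD", "D-IBS"), c(27, 20)), prob_cd = p)
    ci <- auc_confidence_interval(preds, reps = 400, seed = b)
    covered <- covered + (ci[["lower"]] <= true_auc &&
                            true_auc <= ci[["upper"]])
  }
  expect_gte(covered / reps, 0.90)
  expect_lte(covered / reps, 0.99)
})

test_that("probability-covariate correlation matches hand computations", {
  preds <- data.frame(label = c("CD", "CD", "D-IBS"), prob_cd = c(2, 1, 3))
  expect_equal(correlate_probability(preds, c(1, 2, 3)), 0.5)
  expect_equal(correlate_probability(preds, preds$prob_cd), 1)
  expect_equal(correlate_probability(preds, -preds$prob_cd), -1)

  # exclusion rule drops high-titre outliers before correlating
  preds4 <- data.frame(label = rep(c("CD", "D-IBS"), 2),
                       prob_cd = c(0.8, 0.2, 0.6, 0.4))
  cov4 <- c(10, 2, 8, 70)
  expect_equal(correlate_probability(preds4, cov4, exclude_above = 60),
               cor(cov4[1:3], preds4$prob_cd[1:3]))

  expect_error(correlate_probability(preds, c(1, 1, 1)), "constant")
  expect_error(correlate_probability(preds[1:2, ], c(1, 2)), "3 paired")
})

test_that("evaluation bundle keeps every interval ordered around its estimate", {
  set.seed(70)
  preds <- data.frame(label = rep(c("CD", "D-IBS"), c(27, 20)),
                      prob_cd = plogis(c(rnorm(27, 1.5), rnorm(20, -0.5))))
  m <- evaluate_predictions(preds, boot_reps = 300, seed = 3)
  expect_true(m$auc_ci[["lower"]] <= m$auc && m$auc <= m$auc_ci[["upper"]])
  expect_true(m$sensitivity_ci[["lower"]] <= m$sensitivity)
  expect_true(m$sensitivity <= m$sensitivity_ci[["upper"]])
  expect_true(m$specificity_ci[["lower"]] <= m$specificity)
  expect_true(m$specificity <= m$specificity_ci[["upper"]])
  expect_true(all(unlist(m[c("auc_ci", "sensitivity_ci",
                             "specificity_ci")]) >= 0))
  expect_true(all(unlist(m[c("auc_ci", "sensitivity_ci",
                             "specificity_ci")]) <= 1))
})

test_that("report bundle has class-sorted heatmap, box stats and Table-style bins", {
  co <- mini_cohort(seed = 33, n_cd = 5, n_ibs = 4, n_df = 4, n_cv = 16)
  cfg <- pipeline_config(k = 5, seed = 33)
  preds <- run_loo_cv(co, cfg)
  rep_ <- report(preds, co, cfg)

  expect_identical(nrow(rep_$heatmap), 9L)
  expect_identical(ncol(rep_$heatmap), 5L)
  # rows sorted CD block first
  ids_cd <- preds$patient_id[preds$label == "CD"]
  expect_identical(rownames(rep_$heatmap)[1:5], sort(ids_cd))

  gs <- rep_$group_summary
  expect_identical(gs$label, c("CD", "D-IBS"))
  expect_true(all(gs$whisker_low <= gs$q1 & gs$q1 <= gs$median))
  expect_true(all(gs$median <= gs$q3 & gs$q3 <= gs$whisker_high))
  expect_true(all(gs$whisker_low >= gs$q1 - 2 * (gs$q3 - gs$q1) - 1e-12))
  expect_true(all(gs$whisker_high <= gs$q3 + 2 * (gs$q3 - gs$q1) + 1e-12))

  expect_identical(colnames(rep_$crosstab),
                   c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1"))
  # marsh is only assigned to coeliac patients in the generator
  expect_identical(sum(rep_$crosstab), sum(!is.na(vapply(co, `[[`, "",
                                                         "marsh"))))

  # all probabilities in one bin concentrates the crosstab mass there
  preds1 <- preds; preds1$prob_cd <- rep(0.95, 9)
  rep1 <- report(preds1, co, cfg)
  expect_equal(sum(rep1$crosstab[, "0.8-1"]), sum(rep1$crosstab))
  # the upper bin is closed: probability exactly 1 still lands in 0.8-1
  preds2 <- preds; preds2$prob_cd <- rep(1, 9)
  rep2 <- report(preds2, co, cfg)
  expect_equal(sum(rep2$crosstab[, "0.8-1"]), sum(rep2$crosstab))

  d <- withr::local_tempdir()
  write_report(rep_, d, metrics = evaluate_predictions(preds, boot_reps = 200))
  expect_true(all(file.exists(file.path(d, c("heatmap.tsv", "crosstab.csv",
                                             "group_summary.csv",
                                             "metrics.json")))))
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_named(js, c("auc", "auc_ci", "threshold", "sensitivity",
                     "sensitivity_ci", "specificity", "specificity_ci"))
})
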