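test_that("30CST labelling respects the cutoff and its boundary", {
  expect_equal(label_30cst(13), "fit")
  expect_equal(label_30cst(11), "not_fit")
  expect_equal(label_30cst(12), "not_fit")  # boundary: not above cutoff
  expect_equal(label_30cst(12, label_rule(boundary_fit = TRUE)), "fit")
  expect_error(label_30cst(-1), ">= 0")

  tab <- data.frame(sex = c("f", "m"), age_min = c(60, 60),
                    age_max = c(100, 100), cutoff = c(10, 12))
  rule <- label_rule("adjusted", table = tab)
  expect_equal(label_30cst(11, rule, age = 70, sex = "f"), "fit")
  expect_equal(label_30cst(11, rule, age = 70, sex = "m"), "not_fit")
  expect_error(label_30cst(11, rule, age = 30, sex = "m"), "no cutoff")
})

test_that("published confusion matrix reproduces the printed metrics", {
  m <- metrics_from_confusion(confusion_counts(tp = 29, fn = 5,
                                               tn = 45, fp = 2))
  expect_equal(round(100 * attr(m, "accuracy"), 3), 91.358)
  expect_equal(round(m["not_fit", "tp_rate"], 3), 0.853)
  expect_equal(round(m["not_fit", "fp_rate"], 3), 0.043)
  expect_equal(round(m["not_fit", "precision"], 3), 0.935)
  expect_equal(round(m["not_fit", "f_measure"], 3), 0.892)
  expect_equal(round(m["not_fit", "mcc"], 3), 0.823)
  expect_equal(round(m["fit", "precision"], 3), 0.900)
  expect_equal(round(m["fit", "tp_rate"], 3), 0.957)
  expect_equal(round(m["weighted", "tp_rate"], 3), 0.914)
})

test_that("metrics match an independent oracle on random matrices", {
  set.seed(51)
  for (i in 1:50) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    cm <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    m <- metrics_from_confusion(cm)
    o <- oracle_metrics(cells[1], cells[2], cells[3], cells[4])
    expect_equal(attr(m, "accuracy"), o$accuracy, tolerance = 1e-12)
    expect_equal(m["not_fit", "precision"], o$precision_notfit,
                 tolerance = 1e-12)
    expect_equal(m["not_fit", "recall"], o$recall_notfit,
                 tolerance = 1e-12)
    expect_equal(m["not_fit", "mcc"], o$mcc, tolerance = 1e-12)
    # weighted TP rate is accuracy, for any matrix
    expect_equal(m["weighted", "tp_rate"], o$accuracy,
                 tolerance = 1e-12)
    # MCC is symmetric under swapping class roles
    m2 <- metrics_from_confusion(
      confusion_counts(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(m2["not_fit", "mcc"], m["not_fit", "mcc"],
                 tolerance = 1e-12)
  }
})

test_that("perfect and empty confusion matrices behave", {
  m <- metrics_from_confusion(confusion_counts(10, 0, 10, 0))
  expect_equal(attr(m, "accuracy"), 1)
  expect_equal(m["not_fit", "mcc"], 1)
  expect_error(metrics_from_confusion(confusion_counts(0, 0, 0, 0)),
               "empty")
})

test_that("step-interval screening rule uses the inclusive threshold", {
  expect_equal(step_rule_classify(6.17), "fit")
  expect_equal(step_rule_classify(6.18), "not_fit")
  expect_equal(step_rule_classify(4.0), "fit")
  expect_true(is.na(step_rule_classify(NA_real_)))
})

test_that("information gain handles perfect, useless and missing features", {
  y <- rep(c("fit", "not_fit"), each = 8)
  perfect <- rep(c(0, 1), each = 8)
  expect_equal(as.numeric(information_gain(perfect, y)), 1)
  expect_equal(as.numeric(information_gain(rep(3.3, 16), y)), 0)
  expect_equal(as.numeric(information_gain(perfect, rep("fit", 16))), 0)
  # informative missingness is credited via the missing bin
  x_miss <- c(rep(NA_real_, 8), rep(1, 8))
  expect_equal(as.numeric(information_gain(x_miss, y)), 1)
})

test_that("information gain equals exhaustive cut-point search", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    y <- sample(c("fit", "not_fit"), n, replace = TRUE)
    x <- sample(round(rnorm(n), 1))   # duplicated values likely
    x[sample(n, size = sample(0:3, 1))] <- NA
    if (length(unique(y)) < 2) y[1] <- setdiff(c("fit", "not_fit"), y[2])
    expect_equal(as.numeric(information_gain(x, y)),
                 oracle_info_gain(x, y), tolerance = 1e-12)
    h_y <- -sum((table(y) / n) * log2(table(y) / n))
    expect_gte(as.numeric(information_gain(x, y)), 0)
    expect_lte(as.numeric(information_gain(x, y)), h_y + 1e-12)
  }
})

test_that("an 8-instance table with one misclassifying cut is scored right", {
  # feature separates all but one instance; best split leaves 1/8 impure
  x <- c(1, 2, 3, 4, 5, 6, 7, 3.5)
  y <- c(rep("fit", 4), rep("not_fit", 4))
  expect_equal(as.numeric(information_gain(x, y)), oracle_info_gain(x, y),
               tolerance = 1e-12)
})

test_that("Hedges' g closed-form cases and sign convention", {
  tab <- data.frame(label = rep(c("not_fit", "fit"), each = 3),
                    step_avg = c(1, 2, 3, 2, 3, 4))
  for (f in setdiff(feature_names(), "step_avg")) tab[[f]] <- NA_real_
  es <- effect_sizes(tab)
  g <- es$g[es$feature == "step_avg"]
  expect_equal(g, -0.8, tolerance = 1e-12)  # J = 1 - 3/15, diff -1, sp 1

  tab2 <- tab; tab2$step_avg <- c(1, 2, 3, 1, 2, 3)
  es2 <- effect_sizes(tab2)
  expect_equal(es2$g[es2$feature == "step_avg"], 0)
  expect_equal(es2$p[es2$feature == "step_avg"], 1)

  tab3 <- tab; tab3$step_avg <- rep(5, 6)  # degenerate: zero variance
  es3 <- effect_sizes(tab3)
  expect_equal(es3$g[es3$feature == "step_avg"], 0)
  expect_equal(es3$flag[es3$feature == "step_avg"], "zero_var")

  # flipping one group's deviations flips the sign of g
  tab4 <- tab; tab4$step_avg <- c(-1, -2, -3, 2, 3, 4)
  es4 <- effect_sizes(tab4)
  expect_equal(sign(es4$g[es4$feature == "step_avg"]), -1)
  expect_true(es$flag[es$feature == "com_avg_up_x"] == "too_few")
})

test_that("cross-validation is deterministic and aces separable data", {
  set.seed(71)
  n <- 30
  tab <- data.frame(player_id = sprintf("p%02d", 1:n),
                    label = rep(c("fit", "not_fit"), each = n / 2))
  for (f in feature_names()) tab[[f]] <- rnorm(n)
  tab$step_avg <- ifelse(tab$label == "fit", rnorm(n, 4, 0.3),
                         rnorm(n, 8, 0.3))
  cv <- crossval(tab, classifier = "stump", k = 10, seed = 5)
  expect_equal(cv$accuracy, 1)
  cv2 <- crossval(tab, classifier = "stump", k = 10, seed = 5)
  expect_identical(cv$confusion, cv2$confusion)
  expect_identical(cv$predictions, cv2$predictions)
  # the stump discovers step_avg and a cut between the group means
  feats <- vapply(cv$folds, function(f) f$feature, "")
  cuts <- vapply(cv$folds, function(f) f$cutpoint, 0)
  expect_true(all(feats == "step_avg"))
  expect_true(all(cuts > 4 & cuts < 8))

  expect_error(crossval(tab[1:5, ], k = 10), "fewer instances")
})

test_that("all four classifier specs run through the CV harness", {
  cohort <- simulate_cohort(8, 8, seed = 13)
  tab <- feature_table(cohort)
  for (clf in c("stump", "tree", "lmt", "logistic")) {
    cv <- crossval(tab, classifier = clf, k = 4, seed = 2)
    expect_s3_class(cv, "ebb_cv")
    expect_gte(cv$accuracy, 0.5)
  }
})

test_that("missing features are imputed from training folds only", {
  cohort <- simulate_cohort(6, 6, seed = 17)
  tab <- feature_table(cohort)
  tab$step_avg[c(1, 7)] <- NA  # knock out one per class
  cv <- crossval(tab, classifier = "stump", k = 3, seed = 4)
  expect_equal(nrow(cv$predictions), nrow(tab))
  expect_false(anyNA(cv$predictions$pred))
})
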