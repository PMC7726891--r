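test_that("directional stats use mask-size denominators and sample sd", {
  cm <- do.call(rbind, rep(list(c(0.05, 0.8)), 3))
  st <- directional_com_stats(cm, direction_masks(cm))
  expect_equal(unname(st["com_avg_up_x"]), 0.05)
  expect_equal(unname(st["com_avg_up_y"]), 0.8)
  expect_equal(unname(st["com_std_up_x"]), 0)
  expect_true(is.na(st["com_avg_right_x"]))  # empty mask -> missing

  cm2 <- rbind(c(0, 0.8), c(0, 0.9))
  st2 <- directional_com_stats(cm2, direction_masks(cm2))
  expect_equal(unname(st2["com_avg_up_y"]), 0.85)
  expect_equal(unname(st2["com_std_up_y"]), sd(c(0.8, 0.9)))
})

test_that("balance features are conditional means with 0 fallback", {
  cm <- cbind(x = c(0, 0, 0), y = c(0.2, 0.4, -0.3))
  b <- balance_features(cm)
  expect_equal(unname(b["balance_up"]), 0.3)
  expect_equal(unname(b["balance_down"]), -0.3)
  expect_equal(unname(b["balance_right"]), 0)

  expect_true(all(balance_features(matrix(0, 5, 2)) == 0))

  cm2 <- cbind(x = c(0.5, 0.5), y = c(0, 0))
  b2 <- balance_features(cm2)
  expect_equal(unname(b2["balance_right"]), 0.5)
  expect_equal(unname(b2["balance_left"]), 0)
  # literal variant divides by the total sample count instead
  b2l <- balance_features(cm2, table1_literal = TRUE)
  expect_equal(unname(b2l["balance_right"]), 0.5)  # both samples qualify
  cm3 <- cbind(x = c(0.5, 0.5, 0, 0), y = 0)
  expect_equal(unname(balance_features(cm3,
                                       table1_literal = TRUE)["balance_right"]),
               0.25)
})

test_that("global com stats match direct computation", {
  cm <- matrix(rep(c(0.1, -0.2), each = 4), ncol = 2)
  g <- global_com_stats(cm)
  expect_equal(unname(g[c("avg_x", "avg_y")]), c(0.1, -0.2))
  expect_equal(unname(g[c("max_x", "min_x", "std_x")]), c(0.1, 0.1, 0))

  cm2 <- cbind(x = c(-1, 1), y = c(0, 0))
  g2 <- global_com_stats(cm2)
  expect_equal(unname(g2[c("avg_x", "max_x", "min_x")]), c(0, 1, -1))
  expect_equal(unname(g2["std_x"]), sqrt(2))
  expect_error(global_com_stats(matrix(numeric(0), ncol = 2)),
               "non-empty")
})

test_that("instability features count exceedances normalised by n_com", {
  z <- instability_features(rep(0, 30))
  expect_true(all(z == 0))

  f <- instability_features(c(0, 0.6, 0.6, 0.6))
  expect_equal(unname(f["if_threshold_0.5"]), 0.75)
  expect_equal(unname(f["if_threshold_1"]), 0)

  # constant if = 0.1 for 100 samples: if_sum(t) = min(t + 1, 25) * 0.1,
  # so the sum first exceeds 2 at 0-based t = 20 (truncated window of 21
  # values), leaving 80 of 100 qualifying samples
  f2 <- instability_features(rep(0.1, 100))
  expect_equal(unname(f2["if_sum_avg"]),
               mean(oracle_if_sum(rep(0.1, 100), 25)))
  expect_equal(unname(f2["if_sum_max"]), 2.5)
  expect_equal(unname(f2["if_sum_over_2"]), 0.80)
  # time normalisation divides by seconds (n / 20) instead
  f2t <- instability_features(rep(0.1, 100), ifsum_time_norm = TRUE)
  expect_equal(unname(f2t["if_sum_over_2"]), 80 / 5)
})

test_that("step timing uses interval denominators; degenerate cases", {
  s <- step_timing_features(c(2, 4, 7))
  expect_equal(unname(s["step_avg"]), 2.5)
  expect_equal(unname(s["step_std"]), sd(c(2, 3)))

  s2 <- step_timing_features(c(3, 6))
  expect_equal(unname(s2["step_avg"]), 3)
  expect_equal(unname(s2["step_std"]), 0)  # single interval, flagged
  expect_true(isTRUE(attr(s2, "qc_single_interval")))

  expect_true(all(is.na(step_timing_features(c(5)))))
  expect_true(all(is.na(step_timing_features(numeric(0)))))

  # literal variant: telescoped sum over the step count
  s3 <- step_timing_features(c(2, 4, 7), table1_literal = TRUE)
  expect_equal(unname(s3["step_avg"]), (7 - 2) / 3)
})

test_that("extracted vector matches brute-force oracle on random series", {
  for (seed in 1:20) {
    cm <- random_com_series(300, seed)
    got <- extract_features(cm)
    want <- oracle_features(cm)
    expect_equal(unclass(got)[feature_names()],
                 want[feature_names()], tolerance = 1e-10)
  }
})

test_that("threshold-count features are monotone and within [0, 1]", {
  for (seed in 21:30) {
    cm <- random_com_series(250, seed)
    f <- extract_features(cm)
    thr <- f[paste0("if_threshold_", c("0.5", "1", "1.5", "2"))]
    ovr <- f[paste0("if_sum_over_", c("0.5", "1", "1.5", "2"))]
    expect_true(all(diff(thr) <= 1e-12))
    expect_true(all(diff(ovr) <= 1e-12))
    expect_true(all(thr >= 0 & thr <= 1))
    expect_true(all(ovr >= 0 & ovr <= 1))
    expect_true(f["min_x"] <= f["avg_x"] && f["avg_x"] <= f["max_x"])
    expect_true(f["min_y"] <= f["avg_y"] && f["avg_y"] <= f["max_y"])
    expect_true(all(f[c("std_x", "std_y")] >= 0))
  }
})

test_that("order-insensitive features survive permutation; timing does not", {
  cm <- random_com_series(300, 99)
  set.seed(100)
  perm <- cm[sample(nrow(cm)), ]
  a <- extract_features(cm); b <- extract_features(perm)
  stable <- c("balance_up", "balance_down", "balance_right",
              "balance_left", "avg_x", "avg_y", "max_x", "max_y",
              "min_x", "min_y", "std_x", "std_y")
  expect_equal(unclass(a)[stable], unclass(b)[stable],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a[["if_avg"]], b[["if_avg"]])))
})

test_that("extraction is deterministic and a static stance is trivial", {
  cm <- random_com_series(200, 7)
  expect_identical(extract_features(cm), extract_features(cm))

  static <- matrix(0, nrow = 60, ncol = 2)
  f <- extract_features(static)
  expect_true(is.na(f[["step_avg"]]) && is.na(f[["step_std"]]))
  numeric_part <- f[setdiff(feature_names(),
                            c("step_avg", "step_std",
                              paste0("com_avg_",
                                     rep(c("up", "down", "left", "right"),
                                         each = 2), "_", c("x", "y")),
                              paste0("com_std_",
                                     rep(c("up", "down", "left", "right"),
                                         each = 2), "_", c("x", "y"))))]
  expect_true(all(numeric_part == 0))
})

test_that("feature_table binds playthroughs with ids and labels", {
  cohort <- simulate_cohort(2, 1, seed = 5)
  tab <- feature_table(cohort)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$label, c("fit", "fit", "not_fit"))
  expect_equal(names(tab), c("player_id", "label", feature_names()))
})
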