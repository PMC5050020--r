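test_that("normalization divides by the pooled average control cell", {
  rec <- data.frame(experiment_id = "e1", line_id = c("c1", "p1"),
                    group = c("control", "case"), value = c(10, 18),
                    n_cells = c(100, 100))
  n <- normalize_to_control(rec)
  expect_equal(n$norm_value, c(1, 1.8))

  same <- data.frame(experiment_id = "e1", line_id = letters[1:4],
                     group = c("control", "control", "case", "case"),
                     value = 7, n_cells = c(10, 20, 30, 40))
  expect_equal(normalize_to_control(same)$norm_value, rep(1, 4))

  expect_error(normalize_to_control(
    data.frame(experiment_id = "e1", line_id = "p", group = "case",
               value = 1, n_cells = 5)), "no control")
})

test_that("weighted normalization equals brute-force pooling of control cells", {
  set.seed(3)
  # two control lines with unequal cell counts; per-cell values simulated
  cells_a <- rpois(80, 6); cells_b <- rpois(30, 9)
  rec <- data.frame(
    experiment_id = "e1", line_id = c("a", "b", "p"),
    group = c("control", "control", "case"),
    value = c(mean(cells_a), mean(cells_b), 14),
    n_cells = c(length(cells_a), length(cells_b), 50))
  pooled_mean <- mean(c(cells_a, cells_b))  # brute force over all cells
  n <- normalize_to_control(rec)
  expect_equal(n$norm_value[3], 14 / pooled_mean)
  # weighted control values average to 1 by construction
  ctrl <- n[n$group == "control", ]
  expect_equal(weighted.mean(ctrl$norm_value, ctrl$n_cells), 1)
})

test_that("normalization is invariant to per-experiment scaling", {
  rec <- data.frame(experiment_id = rep(c("e1", "e2"), each = 3),
                    line_id = rep(c("c1", "c2", "p1"), 2),
                    group = rep(c("control", "control", "case"), 2),
                    value = c(4, 6, 9, 40, 60, 90),
                    n_cells = rep(c(50, 150, 100), 2))
  n <- normalize_to_control(rec)
  expect_equal(n$norm_value[1:3], n$norm_value[4:6])
})

test_that("group comparison handles degenerate and swapped inputs", {
  rec <- data.frame(group = rep(c("case", "control"), each = 3),
                    norm_value = c(2, 2, 2, 1, 1, 1))
  cmp <- compare_groups(rec)
  expect_equal(cmp$fold_change, 2)
  expect_lt(cmp$p_value, 0.05)

  same <- data.frame(group = rep(c("case", "control"), each = 3),
                     norm_value = rep(1.3, 6))
  cmp0 <- compare_groups(same)
  expect_equal(cmp0$fold_change, 1)
  expect_equal(cmp0$p_value, 1)

  set.seed(9)
  rec2 <- data.frame(group = rep(c("case", "control"), c(6, 5)),
                     norm_value = c(rnorm(6, 2), rnorm(5, 1)))
  a <- compare_groups(rec2)
  swapped <- rec2
  swapped$group <- ifelse(rec2$group == "case", "control", "case")
  b <- compare_groups(swapped)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$fold_change, 1 / b$fold_change)
  expect_equal(a$p_value, b$p_value)

  expect_warning(cmp_small <- compare_groups(
    data.frame(group = c("case", "control", "control"),
               norm_value = c(1, 2, 3))), "fewer than 2")
  expect_true(is.na(cmp_small$p_value))
})

test_that("t-test p-values agree with a permutation oracle on small fixtures", {
  set.seed(21)
  x <- rnorm(8, 1.35, 0.4); y <- rnorm(8, 1.0, 0.4)
  cmp <- compare_groups(data.frame(group = rep(c("case", "control"), each = 8),
                                   norm_value = c(x, y)))
  p_perm <- perm_test_oracle(x, y, n_perm = 10000, seed = 2)
  expect_equal(cmp$p_value, p_perm, tolerance = 0.04)
})

test_that("simulated fold change 1.8 is recovered across seeds", {
  folds <- vapply(1:100, function(seed) {
    set.seed(seed)
    rec <- data.frame(
      group = rep(c("case", "control"), c(16, 12)),
      norm_value = c(rnorm(16, 1.8, 1.8 * 0.25), rnorm(12, 1, 0.25)))
    compare_groups(rec)$fold_change
  }, numeric(1))
  expect_equal(mean(folds), 1.8, tolerance = 0.10)
})

test_that("significance stars follow the published thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 5e-4, 5e-5, NA)),
               c("", "*", "**", "***", "****", ""))
})

test_that("RNAse arithmetic reproduces reductions and the implied ratio", {
  expect_equal(round(implied_untreated_ratio(112, 125, 76, 27), 1), 2.7)

  unt <- data.frame(line_id = c("c", "p"), group = c("control", "case"),
                    value = c(171.2, 466.7))
  trt <- data.frame(line_id = c("c", "p"), group = c("control", "case"),
                    value = c(125, 112))
  r <- rnase_comparison(unt, trt)
  expect_equal(unname(r$reduction_pct["control"]), 27, tolerance = 0.01)
  expect_equal(unname(r$reduction_pct["case"]), 76, tolerance = 0.01)
  expect_equal(round(r$implied_untreated_ratio, 1), 2.7)
  expect_equal(r$untreated_ratio, r$implied_untreated_ratio, tolerance = 1e-6)

  nochange <- rnase_comparison(unt, unt)
  expect_equal(unname(nochange$reduction_pct), c(0, 0))
  expect_error(rnase_comparison(
    data.frame(line_id = "c", group = "control", value = 0),
    data.frame(line_id = "c", group = "control", value = 0)), "undefined")
})
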