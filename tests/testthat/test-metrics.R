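test_that("error metrics reproduce hand-computed examples", {
  y <- c(2, 5, 7, 9)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(5, 3), 2)

  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_equal(r_squared(c(1, 9), c(0, 10)), 1 - 2 / 50)
  expect_error(r_squared(c(1, 2), c(5, 5)),
               class = "intakeval_degenerate_error")

  expect_equal(mean_error(y, y), 0)
  expect_equal(mean_error(c(1, 2), c(0, 0)), 1.5)
  expect_equal(mean_error(0, 1), -1)  # underestimation is negative

  expect_equal(mean_abs_error(y, y), 0)
  expect_equal(mean_abs_error(c(0, 10), c(10, 0)), 10)
  expect_equal(mean_abs_error(1, 2), 1)

  expect_error(rmse(numeric(0), numeric(0)),
               class = "intakeval_validation_error")
  expect_error(rmse(1:3, 1:2), class = "intakeval_validation_error")
})

test_that("Spearman midrank correlation matches counting oracle and cor.test", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_rho(1:5, c(10, 8, 6, 4, 2))$rho, -1)

  x <- c(1, 1, 2); y <- c(1, 2, 3)
  got <- spearman_rho(x, y)
  ora <- naive_spearman(x, y)
  expect_equal(got$rho, ora$rho, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    s <- random_series(sample(5:30, 1), integer_scale = (i %% 2 == 0))
    if (var(s$x) == 0 || var(s$y) == 0) next
    got <- spearman_rho(s$x, s$y)
    ct <- suppressWarnings(cor.test(s$x, s$y, method = "spearman",
                                    exact = FALSE))
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_rho(c(3, 3, 3), 1:3),
               class = "intakeval_degenerate_error")
})

test_that("paired t test matches the textbook formula and t.test", {
  expect_equal(paired_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               list(t = 0, p = 1))
  got <- paired_t_test(c(1, 0, 1, 0), c(0, 1, 0, 1))  # d = 1,-1,1,-1
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)

  x <- c(2, 3, 4, 6); y <- c(1, 2, 3, 4)  # d = 1,1,1,2
  got <- paired_t_test(x, y)
  ora <- naive_paired_t(x, y)
  expect_equal(got$t, ora$t, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)

  expect_error(paired_t_test(c(2, 3), c(1, 2)),
               class = "intakeval_degenerate_error")
})

test_that("Friedman test handles order, ties, and degeneracy", {
  # identical values in every block: no information
  all_tied <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(friedman_rank_test(all_tied)$chisq, 0)
  expect_equal(friedman_rank_test(all_tied)$p, 1)

  # k = 3, n = 5, same strict ordering in every block -> 2n = 10
  ordered <- matrix(rep(c(1, 2, 3), each = 5), nrow = 5)
  expect_equal(friedman_rank_test(ordered)$chisq, 10)

  # tied 3x3 toy against the independent midrank construction
  toy <- matrix(c(1, 1, 2,
                  3, 3, 3,
                  2, 1, 1), nrow = 3, byrow = TRUE)
  got <- friedman_rank_test(toy)
  ora <- naive_friedman(toy)
  expect_equal(got$chisq, ora$chisq, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)

  # cross-check against stats::friedman.test on untied data
  set.seed(3)
  m <- matrix(rnorm(30), nrow = 10)
  ft <- friedman.test(m)
  got <- friedman_rank_test(m)
  expect_equal(got$chisq, unname(ft$statistic), tolerance = 1e-10)
  expect_equal(got$p, ft$p.value, tolerance = 1e-10)

  expect_error(friedman_rank_test(matrix(1:3, nrow = 1)),
               class = "intakeval_validation_error")
})

test_that("Bland-Altman limits follow mean diff +/- 1.96 sample SD", {
  const <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(const$mean_diff, 2)
  expect_equal(const$loa_lower, 2)
  expect_equal(const$loa_upper, 2)

  got <- bland_altman(c(0, 2), c(1, 1))  # d = -1, 1
  expect_equal(got$mean_diff, 0)
  expect_equal(got$loa_upper, 1.96 * sqrt(2))
  expect_equal(got$loa_lower, -1.96 * sqrt(2))

  same <- bland_altman(1:4, 1:4)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_error(bland_altman(1, 1), class = "intakeval_validation_error")
})

test_that("limits of agreement cover about 95% of normal differences", {
  set.seed(99)
  n <- 10000
  y <- rnorm(n, 50, 10)
  x <- y + rnorm(n, 2, 3)
  ba <- bland_altman(x, y)
  d <- x - y
  coverage <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_true(abs(coverage - 0.95) < 0.01)
})

test_that("confusion matrix conserves counts and embeds the MAE", {
  est <- c(9L, 10L, 2L)
  act <- c(10L, 10L, 0L)
  cm <- confusion_matrix11(est, act)
  expect_equal(cm$counts["10", "9"], 1L, ignore_attr = TRUE)
  expect_equal(cm$counts["10", "10"], 1L, ignore_attr = TRUE)
  expect_equal(cm$counts["0", "2"], 1L, ignore_attr = TRUE)
  expect_equal(sum(cm$counts), 3L)
  expect_equal(cm$mae, 1.0)

  perfect <- confusion_matrix11(0:10, 0:10)
  expect_equal(unname(diag(perfect$counts)), rep(1L, 11))
  expect_equal(perfect$mae, 0)

  expect_error(confusion_matrix11(c(1.5, 2), c(1, 2)),
               class = "intakeval_validation_error")

  set.seed(21)
  for (i in 1:10) {
    s <- random_series(sample(3:40, 1), integer_scale = TRUE)
    cm <- confusion_matrix11(s$x, s$y)
    expect_equal(sum(cm$counts), length(s$x))
    expect_identical(cm$mae, mean_abs_error(s$x, s$y))
  }
})

test_that("rmse >= mae >= |me| on random series and perfect agreement is exact", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_series(sample(2:30, 1), integer_scale = (i %% 3 == 0))
    expect_gte(rmse(s$x, s$y) + 1e-12, mean_abs_error(s$x, s$y))
    expect_gte(mean_abs_error(s$x, s$y) + 1e-12, abs(mean_error(s$x, s$y)))
    if (var(s$y) > 0) {
      expect_equal(r_squared(s$y, s$y), 1)
      expect_equal(rmse(s$y, s$y), 0)
    }
  }
})
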