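makeCalls <- function(values, integers, status = "control") {
  data.frame(combined_value = values, integer_call = integers,
             status = rep_len(status, length(values)),
             stringsAsFactors = FALSE)
}

test_that("per-class statistics use the n-1 SD and normalise by the integer", {
  df <- makeCalls(c(2, 2, 2, 1.1, 0.9), c(2L, 2L, 2L, 1L, 1L))
  s <- classStatistics(df, minForProbability = 2L)
  c2 <- s[s$integer_cn == 2, ]
  expect_equal(c2$mean, 2)
  expect_equal(c2$sd, 0)
  c1 <- s[s$integer_cn == 1, ]
  expect_equal(c1$sd, sd(c(1.1, 0.9)))
  expect_equal(c1$normalised_sd, sd(c(1.1, 0.9)) / 1)

  # a 4-sample class vs the default 5-sample probability minimum
  df2 <- makeCalls(c(rnorm(4, 3, 0.1), rnorm(10, 2, 0.1)),
                   c(rep(3L, 4), rep(2L, 10)))
  s2 <- classStatistics(df2)
  expect_true(is.na(s2$probability_of_error[s2$integer_cn == 3]))
  expect_false(is.na(s2$probability_of_error[s2$integer_cn == 2]))

  # singleton class: mean reported, sd omitted
  df3 <- makeCalls(c(5.1, 2, 2.1, 1.9), c(5L, 2L, 2L, 2L))
  s3 <- classStatistics(df3)
  expect_true(is.na(s3$sd[s3$integer_cn == 5]))
  expect_equal(s3$mean[s3$integer_cn == 5], 5.1)

  # class 0 is flagged one-sided
  s4 <- classStatistics(makeCalls(c(-0.03, 0.02, 0.01, 2, 2, 2),
                                  c(0L, 0L, 0L, 2L, 2L, 2L)))
  expect_true(s4$one_sided[s4$integer_cn == 0])
  expect_false(any(s4$one_sided[s4$integer_cn > 0]))
})

test_that("dataset-level normalised SD divides by the integer call", {
  expect_equal(datasetPrecision(makeCalls(c(1, 2, 3), c(1L, 2L, 3L)))$overall,
               0)
  expect_equal(datasetPrecision(makeCalls(c(1.1, 0.9), c(1L, 1L)))$overall,
               sd(c(1.1, 0.9)))
  # class 0 and unresolved samples are excluded
  df <- makeCalls(c(1.1, 0.9, -0.02, 2.0), c(1L, 1L, 0L, NA))
  expect_equal(datasetPrecision(df)$overall, sd(c(1.1, 0.9)))
  # per-cohort split follows the status labels
  df2 <- makeCalls(c(1.1, 0.9, 2.2, 1.8), c(1L, 1L, 2L, 2L),
                   status = c("case", "case", "control", "control"))
  p <- datasetPrecision(df2)
  expect_equal(unname(p$per_cohort["case"]), sd(c(1.1, 0.9)))
  expect_equal(unname(p$per_cohort["control"]), sd(c(1.1, 0.9)))
})

test_that("misclassification probability follows the Gaussian boundaries", {
  # symmetric centred class: 2 * Phi(-0.5 / sigma)
  for (s in c(0.05, 0.1, 0.2)) {
    expect_equal(misclassProbability(3, s, 3L), 2 * pnorm(-0.5 / s),
                 tolerance = 1e-12)
  }
  # class 0 has only the upper boundary
  expect_equal(misclassProbability(-0.033, 0.068, 0L),
               1 - pnorm((0.5 + 0.033) / 0.068), tolerance = 1e-12)
  # monotone in sd at fixed mean, and in |mean - n| at fixed sd
  p_sd <- misclassProbability(2, c(0.05, 0.1, 0.2, 0.4), 2L)
  expect_true(all(diff(p_sd) > 0))
  p_mu <- misclassProbability(c(2, 2.1, 2.2, 2.3), 0.15, 2L)
  expect_true(all(diff(p_mu) > 0))
  # degenerate distribution
  expect_warning(p0 <- misclassProbability(2, 0, 2L), "degenerate")
  expect_equal(p0, 0)
})

test_that("closed-form misassignment matches a Monte-Carlo draw", {
  set.seed(31)
  for (par in list(c(2.021, 0.142, 2), c(4.977, 0.346, 5))) {
    n <- 2e5
    x <- rnorm(n, par[1], par[2])
    emp <- mean(x < par[3] - 0.5 | x >= par[3] + 0.5)
    p <- misclassProbability(par[1], par[2], par[3])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("KS normality check accepts normal classes and rejects uniform", {
  set.seed(77)
  accepted <- vapply(1:50, function(i) {
    df <- makeCalls(rnorm(150, 2, 0.14), rep(2L, 150))
    normalityCheck(df, 2L)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(accepted), 0.9)

  rejected <- vapply(1:30, function(i) {
    df <- makeCalls(runif(500, 1.5, 2.5), rep(2L, 500))
    normalityCheck(df, 2L)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.5)

  # degenerate and undersized classes are skipped, not tested
  expect_equal(normalityCheck(makeCalls(rep(2, 20), rep(2L, 20)), 2L)$skipped,
               "degenerate (constant) values")
  expect_equal(normalityCheck(makeCalls(rnorm(5, 2), rep(2L, 5)), 2L)$skipped,
               "too few samples")

  # Q-Q coordinates are sorted and cover the sample
  qq <- normalityCheck(makeCalls(rnorm(30, 2, 0.1), rep(2L, 30)), 2L)$qq
  expect_equal(nrow(qq), 30)
  expect_identical(qq$sample, sort(qq$sample))
})
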