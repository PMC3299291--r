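test_that("prediction scoring satisfies its defining identities", {
  set.seed(8)
  y <- runif(12, 0, 100)
  p <- y + rnorm(12, 0, 5)
  pt <- score_predictions(y, p)
  expect_equal(pt$rmse^2, mean(pt$table$sq_error), tolerance = 1e-9)
  expect_equal(pt$max_sq_error, max(pt$table$sq_error))
  expect_equal(pt$mean_clinical, mean(y))
  # invariant under row permutation
  o <- sample(12)
  expect_equal(score_predictions(y[o], p[o])$rmse, pt$rmse)
  # perfect predictions
  perfect <- score_predictions(y, y)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$max_sq_error, 0)
  expect_error(score_predictions(y, p[-1]), "lengths differ")
})

test_that("tau is computed from inversion counts with its boundary values", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_tau(x, x)$tau, 1)
  expect_equal(kendall_tau(x, -x)$tau, -1)
  expect_equal(kendall_tau(sort(x), rev(sort(x)))$tau, -1)
  k <- kendall_tau(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(k$discordant, 4L)
  expect_equal(k$tau, 1 - 4 * 4 / (8 * 7))
  expect_equal(k$method, "exact_enumeration")
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  expect_error(kendall_tau(1:2, 2:1), ">= 3")
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(9)
    y <- rnorm(9)
    base <- kendall_tau(x, y)
    expect_equal(kendall_tau(exp(x), y)$tau, base$tau)
    expect_equal(kendall_tau(x, y^3 + 5 * y)$tau, base$tau)
    expect_equal(kendall_tau(rank(x), rank(y))$tau, base$tau)
    expect_equal(kendall_tau(exp(x), y)$p_two_sided, base$p_two_sided)
  }
})

test_that("exact p agrees with full permutation enumeration and cor.test", {
  # worked case: n = 8, 4 inversions -> 2 * #{perms with <= 4 inversions} / 8!
  counts <- mrtdqspr:::inversion_count_distribution(8)
  expect_equal(sum(counts), factorial(8))
  k <- kendall_tau(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(k$p_two_sided, 2 * sum(counts[1:5]) / factorial(8))

  set.seed(7)
  for (n in 4:8) {
    x <- rnorm(n)
    y <- rnorm(n)
    k <- kendall_tau(x, y)
    expect_equal(k$p_two_sided, kendall_p_bruteforce(x, y))
    ct <- cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(k$tau, unname(ct$estimate))
    expect_equal(k$p_two_sided, ct$p.value, tolerance = 1e-12)
  }
})

test_that("large samples and ties fall back as documented", {
  set.seed(11)
  x <- rnorm(30)
  y <- x + rnorm(30, 0, 2)
  k <- kendall_tau(x, y)
  expect_equal(k$method, "normal_approx")
  z <- 3 * k$tau * sqrt(30 * 29) / sqrt(2 * 65)
  expect_equal(k$p_two_sided, 2 * pnorm(-abs(z)))

  expect_warning(kt <- kendall_tau(c(1, 1, 2, 3, 4), c(2, 1, 3, 5, 4)),
                 "ties")
  expect_equal(kt$tau,
               cor(c(1, 1, 2, 3, 4), c(2, 1, 3, 5, 4), method = "kendall"))
})

test_that("Bland-Altman agreement has the documented geometry", {
  set.seed(3)
  y <- runif(10, 0, 50)
  p <- y + rnorm(10, 2, 6)
  ba <- bland_altman(y, p)
  expect_equal(ba$bias, mean(y - p))
  expect_equal(ba$upper_loa, ba$bias + 1.96 * sd(y - p))
  expect_lte(ba$lower_loa, ba$bias)
  expect_lte(ba$bias, ba$upper_loa)
  # antisymmetry under swapping the two methods
  rev <- bland_altman(p, y)
  expect_equal(rev$bias, -ba$bias)
  expect_equal(rev$upper_loa, -ba$lower_loa)
  expect_equal(rev$lower_loa, -ba$upper_loa)
  # perfect agreement collapses everything to zero
  same <- bland_altman(y, y)
  expect_equal(c(same$bias, same$upper_loa, same$lower_loa), c(0, 0, 0))
  expect_error(bland_altman(1, 1), ">= 2")
  # the within-limits flag is reported, not assumed
  expect_type(ba$all_within, "logical")
  expect_equal(ba$all_within,
               all(ba$pairs$difference >= ba$lower_loa &
                     ba$pairs$difference <= ba$upper_loa))
  # non-default multiplier widens the limits accordingly
  ba3 <- bland_altman(y, p, multiplier = 3)
  expect_equal(ba3$upper_loa - ba3$lower_loa,
               (ba$upper_loa - ba$lower_loa) * 3 / 1.96)
})

test_that("goodness of fit separates its two R-squared definitions", {
  set.seed(5)
  y <- runif(15, 0, 100)
  fit <- goodness_of_fit(y, y)
  expect_equal(fit$r2_sse, 1)
  expect_equal(fit$r2_pearson, 1)
  shifted <- goodness_of_fit(y, y + 10)
  expect_equal(shifted$r2_pearson, 1)
  expect_lt(shifted$r2_sse, 1)
  expect_equal(shifted$rmse, 10)
  expect_equal(shifted$max_abs_error, 10)
  expect_error(goodness_of_fit(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("model comparison bundles per-model reports over the test subset", {
  ds <- reference_dataset()
  cmp <- compare_models(ds, reference_mlr(), reference_ann(),
                        labels = c("mlr", "ann"))
  expect_named(cmp, c("mlr", "ann"))
  expect_equal(cmp$mlr$predictions$n, 8)
  expect_lt(abs(cmp$mlr$predictions$rmse - 27.27), 0.05)
  expect_lt(abs(cmp$ann$predictions$rmse - 13.67), 0.05)
  expect_lt(abs(cmp$mlr$rank_correlation$tau - 0.714), 1e-3)
  expect_lt(abs(cmp$ann$rank_correlation$tau - 0.643), 1e-3)
  # comparing a model with itself yields identical sub-reports
  self <- compare_models(ds, reference_mlr(), reference_mlr())
  expect_equal(self[[1]], self[[2]])
})
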