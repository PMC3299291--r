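test_that("the reference regression equation is wired correctly", {
  m <- reference_mlr()
  expect_equal(m$intercept, -34.3303)
  expect_equal(m$coef[["asol"]], 2.1249)
  expect_equal(length(m$coef), 6L)
  expect_identical(names(m$coef), descriptor_names())
  expect_null(m$fit)

  # intercept passes through on the all-zero descriptor vector
  expect_equal(unname(predict(m, rep(0, 6))), m$intercept)
})

test_that("reference equation reproduces the reference test predictions", {
  ds <- reference_dataset()
  te <- ds[ds$subset == "test", ]
  p <- predict(reference_mlr(), te)
  expect_lt(abs(p[["Abacavir"]] - -10.6738), 1e-3)
  expect_lt(abs(p[["Nevirapine"]] - -54.1862), 1e-3)
  expect_true(any(p < 0))              # unclipped: negative doses appear
})

test_that("OLS refit reproduces the reference inference table", {
  refit <- fit_ols(reference_dataset(), "train")
  expect_equal(refit$fit$n, 23)
  expect_lt(abs(refit$fit$r2 - 0.5970), 0.010)
  expect_lt(abs(refit$fit$mcc - 0.7727), 0.007)
  expect_lt(abs(refit$fit$rsd - 33.89), 0.05)
  expect_lt(abs(unname(refit$fit$f_ratio) - 3.9507), 0.10)
  expect_lt(abs(refit$fit$coef_p[["asol"]] - 0.0140), 0.005)
  expect_lt(abs(refit$fit$coef_p[["p_bd"]] - 0.0349), 0.005)
  # reference coefficient/SE pairs, at reported precision
  expect_lt(abs(refit$coef[["asol"]] - 2.1239), 1e-3)
  expect_lt(abs(refit$coef_se[["asol"]] - 0.7697), 1e-3)
  expect_lt(abs(refit$coef[["p_bd"]] - 46.5133), 1e-3)
})

test_that("OLS agrees with the normal-equations oracle", {
  ds <- reference_dataset()
  tr <- ds[ds$subset == "train", ]
  fit <- fit_ols(ds, "train")
  beta <- ols_normal_equations(as.matrix(tr[descriptor_names()]), tr$mrtd)
  expect_equal(unname(c(fit$intercept, fit$coef)), unname(beta),
               tolerance = 1e-8)

  g <- generate_dataset(40, make_positive_mlr(), noise_sd = 8, seed = 21)
  fit2 <- fit_ols(g$data, "train")
  beta2 <- ols_normal_equations(as.matrix(g$data[descriptor_names()]),
                                g$data$mrtd)
  expect_equal(unname(c(fit2$intercept, fit2$coef)), unname(beta2),
               tolerance = 1e-8)
})

test_that("fit statistics satisfy their defining identities", {
  fit <- fit_ols(reference_dataset(), "train")$fit
  expect_equal(fit$mcc, sqrt(fit$r2), tolerance = 1e-9)
  # F from R2 vs F from the SSR/SSE decomposition
  f_from_r2 <- (fit$r2 / 6) / ((1 - fit$r2) / (fit$n - 7))
  expect_equal(unname(fit$f_ratio), f_from_r2, tolerance = 1e-8)
  # coefficient t and p are consistent at df = n - 7
  fitm <- fit_ols(reference_dataset(), "train")
  expect_equal(unname(fitm$fit$coef_t),
               unname(fitm$coef / fitm$coef_se), tolerance = 1e-10)
  expect_equal(unname(fitm$fit$coef_p),
               unname(2 * pt(-abs(fitm$fit$coef_t), df = 16)),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  ds <- reference_dataset()
  expect_error(fit_ols(ds[1:7, ], "train"), "insufficient data")
  collinear <- as.data.frame(ds[ds$subset == "train", ])
  collinear$log_bio_hl <- 2 * collinear$alogp
  expect_error(fit_ols(as_drug_dataset(collinear), "train"),
               "rank-deficient.*collinear")
})

test_that("noiseless synthetic data is recovered exactly", {
  truth <- reference_mlr()
  g <- generate_dataset(50, truth, noise_sd = 0, seed = 4)
  clean <- g$data[!attr(g$data, "floored"), ]  # floor is a generator artifact
  fit <- suppressWarnings(fit_ols(clean, "train"))  # lm warns: perfect fit
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-6)
  expect_equal(fit$coef, truth$coef, tolerance = 1e-6)
})

test_that("confidence intervals cover generating coefficients at ~95%", {
  truth <- make_positive_mlr()
  n <- 50
  reps <- 200
  hits <- 0L
  total <- 0L
  tcrit <- qt(0.975, df = n - 7)
  for (r in seq_len(reps)) {
    g <- generate_dataset(n, truth, noise_sd = 10, seed = 5000 + r)
    keep <- !attr(g$data, "floored")
    if (sum(keep) < n) next             # keep the design exactly linear
    fit <- fit_ols(g$data, "train")
    covered <- abs(fit$coef - truth$coef) <= tcrit * fit$coef_se
    hits <- hits + sum(covered)
    total <- total + length(covered)
  }
  expect_gt(total, 1000)
  expect_equal(hits / total, 0.95, tolerance = 0.05)
})

test_that("univariate screen matches the reference correlations", {
  sc <- univariate_screen(reference_dataset(), "train")
  rownames(sc) <- sc$descriptor
  expect_equal(sc["asol", "pearson_r"], 0.476, tolerance = 0.005)
  expect_equal(sc["oxid_hl", "pearson_r"], 0.448, tolerance = 0.005)
  expect_equal(sc$r2, sc$pearson_r^2)
  expect_true(all(abs(sc$pearson_r) <= 1))

  # a descriptor equal to the response correlates perfectly
  df <- as.data.frame(reference_dataset()[reference_dataset()$subset == "train", ])
  df$log_bio_hl <- df$mrtd
  expect_equal(univariate_screen(as_drug_dataset(df),
               "train")[3, "pearson_r"], 1.0)

  # zero-variance descriptor is flagged as undefined
  df2 <- as.data.frame(reference_dataset())
  df2$alogp <- 1.5
  expect_true(is.na(univariate_screen(as_drug_dataset(df2), "train")[4, "pearson_r"]))
})

test_that("linear models round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  fit <- fit_ols(reference_dataset(), "train")
  write_model(fit, tmp)
  back <- read_model(tmp)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coef, fit$coef)
  expect_equal(back$coef_se, fit$coef_se)
  expect_equal(back$fit$r2, fit$fit$r2)
  expect_equal(predict(back, reference_dataset()),
               predict(fit, reference_dataset()))
})
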