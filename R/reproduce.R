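## One-shot reproduction of the reference results on the bundled dataset.

#' Recompute the reference results and check them against expectations
#'
#' Runs the full reference analysis on the bundled dataset — the reference
#' regression equation and reference network evaluated on the 8-compound
#' test subset (predictions, RMSE, max squared error, Kendall tau,
#' Bland-Altman limits), the OLS refit on the 23-compound training subset,
#' and the reference network's training-subset fit — and compares every
#' quantity against the versioned expectations shipped in
#' `extdata/reference_expectations.csv`, each at its stated tolerance.
#'
#' @param ds Dataset to run on; the bundled [reference_dataset()] by
#'   default.
#' @return Data frame with one row per check: `check`, `computed`,
#'   `expected`, `tolerance`, `source`, `pass`.
#' @export
#' @examples
#' rep <- reproduce_reference()
#' all(rep$pass)
reproduce_reference <- function(ds = reference_dataset()) {
  ds <- as_drug_dataset(ds)
  tr <- dataset_rows(ds, "train")
  te <- dataset_rows(ds, "test")
  mlr <- reference_mlr()
  ann <- reference_ann()
  cmp <- compare_models(ds, mlr, ann, subset = "test",
                        labels = c("mlr", "ann"))
  refit <- fit_ols(ds, "train")
  train_fit <- goodness_of_fit(tr$mrtd, predict(ann, tr))
  pm <- cmp$mlr$predictions
  pa <- cmp$ann$predictions
  pick <- function(pt, compound) pt$table$predicted[pt$table$name == compound]

  computed <- c(
    mlr_abacavir_pred = pick(pm, "Abacavir"),
    mlr_nevirapine_pred = pick(pm, "Nevirapine"),
    mlr_test_mean = pm$mean_predicted,
    mlr_test_rmse = pm$rmse,
    mlr_max_sq_error = pm$max_sq_error,
    ann_abacavir_pred = pick(pa, "Abacavir"),
    ann_lopiravir_pred = pick(pa, "Lopiravir"),
    ann_test_rmse = pa$rmse,
    ann_max_sq_error = pa$max_sq_error,
    tau_mlr = cmp$mlr$rank_correlation$tau,
    tau_ann = cmp$ann$rank_correlation$tau,
    mlr_loa_upper = cmp$mlr$agreement$upper_loa,
    mlr_loa_lower = cmp$mlr$agreement$lower_loa,
    ann_loa_upper = cmp$ann$agreement$upper_loa,
    ann_loa_lower = cmp$ann$agreement$lower_loa,
    ols_r2 = refit$fit$r2,
    ols_mcc = refit$fit$mcc,
    ols_rsd = refit$fit$rsd,
    ols_f_ratio = refit$fit$f_ratio,
    ols_p_asol = refit$fit$coef_p[["asol"]],
    ols_p_pbd = refit$fit$coef_p[["p_bd"]],
    ann_train_rmse = train_fit$rmse,
    ann_train_max_abs_error = train_fit$max_abs_error)

  exp_path <- system.file("extdata", "reference_expectations.csv",
                          package = "mrtdqspr", mustWork = TRUE)
  expected <- utils::read.csv(exp_path, stringsAsFactors = FALSE)
  expected$computed <- unname(computed[expected$check])
  expected$pass <- !is.na(expected$computed) &
    abs(expected$computed - expected$expected) <= expected$tolerance
  expected[c("check", "computed", "expected", "tolerance", "source", "pass")]
}
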