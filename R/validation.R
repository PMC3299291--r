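## Prediction scoring, rank correlation and Bland-Altman method agreement.

#' Score predictions against clinical values
#'
#' Builds a per-compound prediction table with squared errors and the
#' aggregate statistics used for model comparison: column means, root mean
#' squared error (divisor n) and the maximum squared error.
#'
#' @param clinical Observed doses (mg/kg/day).
#' @param predicted Model predictions, same length.
#' @param names Optional compound names.
#' @return A `prediction_table`: list with `table` (data frame `name`,
#'   `clinical`, `predicted`, `sq_error`), `mean_clinical`,
#'   `mean_predicted`, `rmse`, `max_sq_error`, `n`.
#' @export
#' @examples
#' ds <- reference_dataset()
#' te <- ds[ds$subset == "test", ]
#' score_predictions(te$mrtd, predict(reference_mlr(), te), te$name)
score_predictions <- function(clinical, predicted, names = NULL) {
  if (length(clinical) != length(predicted))
    stopf("clinical and predicted lengths differ (%d vs %d)",
          length(clinical), length(predicted))
  if (length(clinical) < 1L) stopf("need at least one prediction to score")
  if (is.null(names)) names <- names(predicted)
  if (is.null(names)) names <- paste0("compound_", seq_along(clinical))
  sq <- (clinical - predicted)^2
  structure(list(
    table = data.frame(name = names, clinical = clinical,
                       predicted = unname(predicted), sq_error = unname(sq)),
    mean_clinical = mean(clinical), mean_predicted = mean(predicted),
    rmse = sqrt(mean(sq)), max_sq_error = max(sq), n = length(clinical)),
    class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, digits = 4, ...) {
  tab <- x$table
  tab$clinical <- round(tab$clinical, digits)
  tab$predicted <- round(tab$predicted, digits)
  tab$sq_error <- round(tab$sq_error, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("mean clinical %.4f, mean predicted %.4f, RMSE = %.2f, max SE = %.2f (n = %d)\n",
              x$mean_clinical, x$mean_predicted, x$rmse, x$max_sq_error, x$n))
  invisible(x)
}

## Number of pairs (i < j) whose order disagrees between x and y
## (inversions of the y-ranks after sorting by x). O(n^2); n here is tiny.
count_discordant <- function(x, y) {
  n <- length(x)
  d <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (sign(x[j] - x[i]) * sign(y[j] - y[i]) < 0) d <- d + 1L
  d
}

## Mahonian counts: number of permutations of n with exactly k inversions,
## k = 0 .. n(n-1)/2, by the standard convolution recurrence. Exact in
## doubles for the n <= 10 used here (10! = 3.6e6).
inversion_count_distribution <- function(n) {
  counts <- 1                       # permutations of 1 element: 0 inversions
  for (m in seq_len(n)[-1]) {       # insert element m: adds 0..m-1 inversions
    new <- numeric(length(counts) + m - 1)
    for (shift in 0:(m - 1))
      new[seq_along(counts) + shift] <- new[seq_along(counts) + shift] + counts
    counts <- new
  }
  counts
}

#' Kendall rank correlation with exact small-sample p-value
#'
#' Computes Kendall's tau-a from the discordant-pair (inversion) count,
#' `tau = 1 - 4 D / (n (n - 1))`. For tie-free data with `n <= 10` the
#' two-sided p-value is exact, from the full inversion-count distribution
#' over all `n!` permutations (`p = 2 * min(P(D <= d), P(D >= d))`, capped
#' at 1); for larger n the normal approximation
#' `z = 3 tau sqrt(n (n - 1)) / sqrt(2 (2 n + 5))` is used. Tied data fall
#' back to tau-b with a warning and the normal approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A `rank_correlation`: list with `tau`, `n`, `discordant`,
#'   `p_two_sided`, `method` (`"exact_enumeration"` or `"normal_approx"`).
#' @export
#' @examples
#' kendall_tau(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stopf("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("tau undefined for a constant input vector")
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (ties) {
    warning("ties present: reporting tau-b with normal-approximation p-value")
    tau <- stats::cor(x, y, method = "kendall")
    d <- NA_integer_
  } else {
    d <- count_discordant(x, y)
    tau <- 1 - 4 * d / (n * (n - 1))
  }
  if (!ties && n <= 10L) {
    counts <- inversion_count_distribution(n)
    total <- factorial(n)
    p <- min(1, 2 * min(sum(counts[seq_len(d + 1L)]),
                        sum(counts[(d + 1L):length(counts)])) / total)
    method <- "exact_enumeration"
  } else {
    z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(tau = tau, n = n, discordant = d, p_two_sided = p,
                 method = method), class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Kendall tau = %.4f (n = %d, discordant pairs = %s), p = %.4g [%s]\n",
              x$tau, x$n, format(x$discordant), x$p_two_sided, x$method))
  invisible(x)
}

#' Bland-Altman agreement between clinical and predicted doses
#'
#' Differences are taken as `clinical - predicted`; limits of agreement are
#' the mean difference (bias) plus/minus `multiplier` times the sample SD
#' of the differences (n - 1 divisor). Whether every difference lies within
#' the limits is reported as a boolean, not assumed.
#'
#' @inheritParams score_predictions
#' @param multiplier Width of the limits in SD units; the conventional 1.96
#'   by default.
#' @return An `agreement_report`: list with `bias`, `sd_diff`, `upper_loa`,
#'   `lower_loa`, `pairs` (data frame of per-pair `average`, `difference`),
#'   `all_within`, `n`, `multiplier`.
#' @export
bland_altman <- function(clinical, predicted, multiplier = 1.96) {
  if (length(clinical) != length(predicted)) stopf("input lengths differ")
  if (length(clinical) < 2L) stopf("need >= 2 pairs for limits of agreement")
  d <- clinical - predicted
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  up <- bias + multiplier * sd_diff
  lo <- bias - multiplier * sd_diff
  structure(list(bias = bias, sd_diff = sd_diff, upper_loa = up,
                 lower_loa = lo,
                 pairs = data.frame(average = (clinical + predicted) / 2,
                                    difference = d),
                 all_within = all(d >= lo & d <= up),
                 n = length(d), multiplier = multiplier),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SD of differences %.4f\n", x$bias, x$sd_diff))
  cat(sprintf("limits of agreement (bias +/- %.3g SD): (%.4f, %.4f); all within: %s\n",
              x$multiplier, x$upper_loa, x$lower_loa, x$all_within))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against averages with horizontal lines
#' at the bias and at the limits of agreement.
#'
#' @param x An [agreement_report][bland_altman].
#' @param main Plot title.
#' @param ... Passed to [plot()].
#' @export
plot.agreement_report <- function(x, main = "Bland-Altman agreement", ...) {
  plot(x$pairs$average, x$pairs$difference,
       xlab = "average of clinical and predicted MRTD (mg/kg/day)",
       ylab = "clinical - predicted (mg/kg/day)", main = main, pch = 19, ...)
  graphics::abline(h = c(x$bias, x$upper_loa, x$lower_loa),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Goodness of fit of predictions
#'
#' Returns both common definitions of R-squared — `1 - SSE/SST` and the
#' squared Pearson correlation between clinical and predicted — together
#' with the RMSE (divisor n) and maximum absolute error. The two R-squared
#' definitions coincide only for least-squares-calibrated predictions;
#' both are reported so the appropriate one can be cited explicitly.
#'
#' @inheritParams score_predictions
#' @return List with `r2_sse`, `r2_pearson`, `rmse`, `max_abs_error`, `n`.
#' @export
goodness_of_fit <- function(clinical, predicted) {
  if (length(clinical) != length(predicted)) stopf("input lengths differ")
  if (length(clinical) < 3L) stopf("need >= 3 pairs")
  if (stats::sd(clinical) == 0) stopf("clinical values have zero variance")
  err <- clinical - predicted
  sst <- sum((clinical - mean(clinical))^2)
  list(r2_sse = 1 - sum(err^2) / sst,
       r2_pearson = stats::cor(clinical, predicted)^2,
       rmse = sqrt(mean(err^2)), max_abs_error = max(abs(err)),
       n = length(clinical))
}

#' Compare two dose-prediction models on a dataset subset
#'
#' Evaluates both models on the chosen subset and bundles, per model, a
#' [prediction table][score_predictions], a
#' [rank correlation][kendall_tau] against the clinical values and a
#' [Bland-Altman agreement report][bland_altman].
#'
#' @inheritParams fit_ols
#' @param model_a,model_b Models with a `predict` method over descriptor
#'   data (`mlr_model` or `ann_model`).
#' @param subset Subset tag to evaluate on (default `"test"`).
#' @param labels Length-2 character vector naming the models in the report.
#' @return A `model_comparison`: list of two sub-reports, each with
#'   elements `predictions`, `rank_correlation`, `agreement`.
#' @export
#' @examples
#' compare_models(reference_dataset(), reference_mlr(), reference_ann())
compare_models <- function(ds, model_a, model_b, subset = "test",
                           labels = c("model_a", "model_b")) {
  ds <- as_drug_dataset(ds)
  rows <- dataset_rows(ds, subset)
  if (anyNA(rows$mrtd)) stopf("subset '%s' has records without MRTD", subset)
  report_one <- function(model) {
    p <- predict(model, rows)
    list(predictions = score_predictions(rows$mrtd, p, rows$name),
         rank_correlation = kendall_tau(rows$mrtd, p),
         agreement = bland_altman(rows$mrtd, p))
  }
  out <- stats::setNames(list(report_one(model_a), report_one(model_b)), labels)
  structure(out, class = "model_comparison", subset = subset)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison on the '%s' subset (n = %d)\n",
              attr(x, "subset"), x[[1]]$predictions$n))
  wide <- data.frame(name = x[[1]]$predictions$table$name,
                     clinical = x[[1]]$predictions$table$clinical)
  for (lab in names(x)) {
    wide[[lab]] <- round(x[[lab]]$predictions$table$predicted, 4)
    wide[[paste0(lab, "_sq_err")]] <- round(x[[lab]]$predictions$table$sq_error, 4)
  }
  print(wide, row.names = FALSE)
  for (lab in names(x)) {
    r <- x[[lab]]
    cat(sprintf(
      "%s: mean pred %.4f, RMSE %.2f, max SE %.2f, tau %.3f (p %.3g, %s), LoA (%.1f, %.1f)\n",
      lab, r$predictions$mean_predicted, r$predictions$rmse,
      r$predictions$max_sq_error, r$rank_correlation$tau,
      r$rank_correlation$p_two_sided, r$rank_correlation$method,
      r$agreement$upper_loa, r$agreement$lower_loa))
  }
  invisible(x)
}
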