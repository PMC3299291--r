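## Multiple linear regression: the reference dose equation, an OLS refitter
## with coefficient inference, and the univariate correlation screen.

new_mlr_model <- function(intercept, coef, coef_se = NULL, fit = NULL) {
  coef <- coef[DESCRIPTOR_NAMES]
  if (anyNA(coef) || !identical(names(coef), DESCRIPTOR_NAMES))
    stopf("an MLR model needs exactly the six canonical coefficients (%s)",
          paste(DESCRIPTOR_NAMES, collapse = ", "))
  structure(list(intercept = intercept, coef = coef,
                 coef_se = coef_se, fit = fit),
            class = c("mlr_model", "mrtd_model"))
}

#' The reference MRTD regression equation
#'
#' Returns the reference multiple linear regression model for antiretroviral
#' MRTD (mg/kg/day):
#'
#' \deqn{-34.3303 + 5.659\,\mathrm{OxidHL} + 46.5133\,\mathrm{P[BD]}
#'       + 15.90\,\mathrm{logBioHL} - 12.20\,\mathrm{AlogP}
#'       + 2.1249\,\mathrm{ASol} + 0.2159\,\mathrm{MW}}
#'
#' The coefficients are the published rounded values; no inference
#' statistics are attached (use [fit_ols()] on [reference_dataset()] to
#' recompute them at full precision).
#'
#' @return An `mlr_model`.
#' @export
#' @examples
#' predict(reference_mlr(), reference_dataset())
reference_mlr <- function() {
  new_mlr_model(
    intercept = -34.3303,
    coef = c(oxid_hl = 5.659, p_bd = 46.5133, log_bio_hl = 15.90,
             alogp = -12.20, asol = 2.1249, mw = 0.2159))
}

#' Predict MRTD with a linear model
#'
#' Evaluates intercept plus the dot product of the six coefficients with the
#' descriptor columns of `newdata`. Predictions are not clipped and may be
#' negative: the linear model is an unconstrained least-squares surface.
#'
#' @param object An `mlr_model` (from [reference_mlr()] or [fit_ols()]).
#' @param newdata A [drug_dataset][as_drug_dataset], a data frame with the
#'   six descriptor columns, or a bare numeric vector of length 6 in
#'   canonical order.
#' @param ... Unused.
#' @return Numeric vector of predicted doses (mg/kg/day), named by compound
#'   where names are available.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  x <- descriptor_matrix(newdata)
  drop(object$intercept + x %*% object$coef[colnames(x)])
}

#' Refit the dose equation by ordinary least squares
#'
#' Fits MRTD on the six descriptors with an intercept over the chosen subset
#' and attaches full coefficient inference: standard errors, t statistics
#' and two-sided p-values at `n - 7` residual degrees of freedom, plus
#' fit-level statistics (R-squared, multiple correlation coefficient
#' `mcc = sqrt(r2)`, residual standard deviation `rsd = sqrt(SSE/(n - 7))`,
#' and the ANOVA F ratio with its p-value).
#'
#' The solve uses a QR decomposition (via [stats::lm()]); the normal
#' equations are never formed.
#'
#' @param ds A [drug_dataset][as_drug_dataset] with MRTD present on every
#'   fitted row.
#' @param subset Subset tag to fit on (default `"train"`).
#' @return An `mlr_model` with `coef_se` and a `fit` list
#'   (`n`, `r2`, `mcc`, `rsd`, `f_ratio`, `f_p`, `coef_t`, `coef_p`).
#' @export
#' @examples
#' m <- fit_ols(reference_dataset(), "train")
#' m$fit$r2
fit_ols <- function(ds, subset = "train") {
  ds <- as_drug_dataset(ds)
  rows <- dataset_rows(ds, subset)
  if (anyNA(rows$mrtd)) stopf("subset '%s' has records without MRTD", subset)
  n <- nrow(rows)
  if (n < 8L)
    stopf("insufficient data: OLS with six descriptors needs >= 8 records, got %d", n)
  x <- descriptor_matrix(rows)
  qrx <- qr(cbind(1, x))
  if (qrx$rank < 7L) {
    cols <- c("(intercept)", colnames(x))
    dropped <- cols[-qrx$pivot[seq_len(qrx$rank)]]
    stopf("rank-deficient design: collinear column(s) %s",
          paste(sQuote(dropped), collapse = ", "))
  }
  df <- as.data.frame(x)
  df$mrtd <- rows$mrtd
  fit <- stats::lm(mrtd ~ ., data = df)
  s <- summary(fit)
  cf <- s$coefficients
  r2 <- s$r.squared
  fstat <- unname(s$fstatistic)
  new_mlr_model(
    intercept = unname(cf["(Intercept)", "Estimate"]),
    coef = stats::setNames(cf[DESCRIPTOR_NAMES, "Estimate"], DESCRIPTOR_NAMES),
    coef_se = stats::setNames(cf[DESCRIPTOR_NAMES, "Std. Error"], DESCRIPTOR_NAMES),
    fit = list(
      n = n, r2 = r2, mcc = sqrt(r2), rsd = s$sigma,
      f_ratio = fstat[1],
      f_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      coef_t = stats::setNames(cf[DESCRIPTOR_NAMES, "t value"], DESCRIPTOR_NAMES),
      coef_p = stats::setNames(cf[DESCRIPTOR_NAMES, "Pr(>|t|)"], DESCRIPTOR_NAMES)))
}

#' Univariate correlation screen
#'
#' Pearson correlation of each descriptor with MRTD over a subset, with its
#' square — the single-variable coefficient of determination. A descriptor
#' with zero variance over the subset is flagged with `NA` correlation.
#'
#' @inheritParams fit_ols
#' @return Data frame with columns `descriptor`, `pearson_r`, `r2`.
#' @export
univariate_screen <- function(ds, subset = "train") {
  ds <- as_drug_dataset(ds)
  rows <- dataset_rows(ds, subset)
  if (nrow(rows) < 3L) stopf("need >= 3 records for a correlation screen")
  if (anyNA(rows$mrtd)) stopf("subset '%s' has records without MRTD", subset)
  r <- vapply(DESCRIPTOR_NAMES, function(col) {
    v <- rows[[col]]
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, rows$mrtd)
  }, 0.0)
  data.frame(descriptor = DESCRIPTOR_NAMES, pearson_r = unname(r),
             r2 = unname(r)^2)
}

#' @export
coef.mlr_model <- function(object, ...) c("(intercept)" = object$intercept, object$coef)

#' @export
print.mlr_model <- function(x, digits = 4, ...) {
  cat("<mlr_model> MRTD (mg/kg/day) ~ six molecular descriptors\n")
  tab <- data.frame(coefficient = signif(c(x$intercept, x$coef), digits),
                    row.names = c("(intercept)", names(x$coef)))
  if (!is.null(x$coef_se)) {
    tab$se <- signif(c(NA, x$coef_se), digits)
    tab$p <- signif(c(NA, x$fit$coef_p), digits)
  }
  print(tab)
  if (!is.null(x$fit))
    cat(sprintf("n = %d, R2 = %.4f, MCC = %.4f, RSD = %.2f, F = %.4f (p = %.4g)\n",
                x$fit$n, x$fit$r2, x$fit$mcc, x$fit$rsd, x$fit$f_ratio, x$fit$f_p))
  invisible(x)
}
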