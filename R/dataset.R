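#' Construct and validate a drug dataset
#'
#' A `drug_dataset` is a data frame with one row per compound and columns
#' `name`, `subset` (one of `"train"`, `"test"`, `"unassigned"`), `mrtd`
#' (mg/kg/day, may be `NA` for prediction-only input) and the six descriptor
#' columns in canonical order (see [descriptor_names()]).
#'
#' Validation enforces the physical invariants of the descriptor space:
#' `oxid_hl`, `asol` and `mw` strictly positive, `p_bd` in \[0, 1\], all
#' descriptors finite, `mrtd` positive when present, and unique non-empty
#' compound names.
#'
#' @param x A data frame with the columns described above (`subset` optional,
#'   defaulting to `"unassigned"`).
#' @return A validated `drug_dataset`.
#' @export
#' @examples
#' as_drug_dataset(data.frame(
#'   name = "ExampleDrug", mrtd = 10,
#'   oxid_hl = 0.1, p_bd = 0.5, log_bio_hl = -2, alogp = 1, asol = 5, mw = 300))
as_drug_dataset <- function(x) {
  if (!is.data.frame(x)) stopf("expected a data frame, got %s", class(x)[1])
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("name", "mrtd", DESCRIPTOR_NAMES)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("schema error: missing column(s) %s",
          paste(sQuote(missing_cols), collapse = ", "))
  if (is.null(x$subset)) x$subset <- rep("unassigned", nrow(x))
  x <- x[c("name", "subset", "mrtd", DESCRIPTOR_NAMES)]
  x$name <- as.character(x$name)
  x$subset <- as.character(x$subset)

  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, sprintf("row %s (%s): %s",
        which(rows), x$name[which(rows)], msg))
  }
  bad_subset <- !x$subset %in% c("train", "test", "unassigned")
  note(bad_subset, "subset must be 'train', 'test' or 'unassigned'")
  note(is.na(x$name) | !nzchar(x$name), "name must be non-empty")
  for (col in c("mrtd", DESCRIPTOR_NAMES)) {
    v <- x[[col]]
    if (!is.numeric(v)) stopf("schema error: column '%s' is not numeric", col)
    if (col != "mrtd") note(!is.finite(v), sprintf("%s must be finite", col))
  }
  note(!is.na(x$mrtd) & !(x$mrtd > 0), "mrtd must be > 0 when present")
  for (col in c("oxid_hl", "asol", "mw"))
    note(is.finite(x[[col]]) & x[[col]] <= 0, sprintf("%s must be > 0", col))
  note(is.finite(x$p_bd) & (x$p_bd < 0 | x$p_bd > 1),
       "p_bd must lie in [0, 1]")
  dup <- duplicated(x$name)
  note(dup, "duplicated compound name")
  if (length(problems))
    stopf("invalid drug dataset:\n%s", paste("  -", problems, collapse = "\n"))

  rownames(x) <- NULL
  class(x) <- c("drug_dataset", "data.frame")
  x
}

#' Read a descriptor table from CSV
#'
#' Reads a comma-separated UTF-8 table with '.' decimal separator. A Unicode
#' minus sign in any numeric cell is normalised to an ASCII hyphen before
#' parsing. Non-numeric cells and schema violations are reported with the
#' offending row and column.
#'
#' @param path Path to a CSV file with columns `name`, `mrtd`, the six
#'   descriptors, and optionally `subset`.
#' @return A [drug_dataset][as_drug_dataset].
#' @seealso [write_dataset()] for the inverse, [reference_dataset()] for the
#'   bundled antiretroviral table.
#' @export
load_dataset <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  required <- c("name", "mrtd", DESCRIPTOR_NAMES)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stopf("schema error in '%s': missing column(s) %s", path,
          paste(sQuote(missing_cols), collapse = ", "))
  for (col in c("mrtd", DESCRIPTOR_NAMES)) {
    cell <- trimws(gsub("−", "-", raw[[col]]))
    cell[!nzchar(cell)] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is.na(cell) & is.na(num)
    if (any(bad))
      stopf("parse error in '%s': non-numeric value %s in column '%s', row %d",
            path, sQuote(cell[which(bad)[1]]), col, which(bad)[1])
    raw[[col]] <- num
  }
  as_drug_dataset(raw)
}

#' Write a drug dataset to CSV
#'
#' Numeric values are written with full precision (up to 15 significant
#' digits) so that `load_dataset(write_dataset(x))` round-trips exactly.
#'
#' @param ds A [drug_dataset][as_drug_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  ds <- as_drug_dataset(ds)
  out <- ds
  for (col in c("mrtd", DESCRIPTOR_NAMES))
    out[[col]] <- vapply(ds[[col]], function(v)
      if (is.na(v)) "" else formatC(v, digits = 15, format = "g"), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled 31-compound antiretroviral MRTD dataset
#'
#' Clinical MRTD values (FDA MRTD database / package inserts) and six
#' computed molecular property descriptors for 31 compounds used to build
#' the reference dose-prediction models: 23 training compounds and 8
#' external test compounds.
#'
#' Data notes: `p_bd` is stored as a 0-1 fraction. Tipranavir's MRTD is
#' 16.67 mg/kg/day (500 mg twice daily for a 60 kg adult); this value — not
#' the occasionally-seen misprint 6.670 — is the one consistent with the
#' training-subset summary statistics (mean 28.54, SD 45.53 mg/kg/day) and
#' with the reference models' reported training fit.
#'
#' @return A [drug_dataset][as_drug_dataset] with 31 rows.
#' @export
#' @examples
#' ds <- reference_dataset()
#' table(ds$subset)
reference_dataset <- function() {
  load_dataset(system.file("extdata", "arv_mrtd.csv", package = "mrtdqspr",
                           mustWork = TRUE))
}

#' Per-column summary statistics for a dataset subset
#'
#' Computes, for the MRTD column and each descriptor, the count, mean,
#' sample standard deviation (n - 1 divisor) and coefficient of variation
#' `cv_pct = 100 * sd / mean`. With a single record the SD is reported as
#' `NA` (undefined), not zero; `cv_pct` is `NA` whenever the mean is zero
#' or the SD undefined.
#'
#' @param ds A [drug_dataset][as_drug_dataset].
#' @param subset `"train"`, `"test"`, `"unassigned"` or `"all"`.
#' @return A data frame with one row per column (`mrtd` first, then the six
#'   descriptors) and columns `column`, `n`, `mean`, `sd`, `cv_pct`.
#' @export
#' @examples
#' summarize_dataset(reference_dataset(), "train")
summarize_dataset <- function(ds, subset = "all") {
  ds <- as_drug_dataset(ds)
  rows <- dataset_rows(ds, subset)
  cols <- c("mrtd", DESCRIPTOR_NAMES)
  stats <- lapply(cols, function(col) {
    v <- rows[[col]]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- mean(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(column = col, n = n, mean = m, sd = s,
               cv_pct = if (!is.na(s) && m != 0) 100 * s / m else NA_real_)
  })
  do.call(rbind, stats)
}

## Stable-ordered subset filter shared by the modelling functions.
dataset_rows <- function(ds, subset) {
  subset <- match.arg(subset, c("train", "test", "unassigned", "all"))
  rows <- if (subset == "all") ds else ds[ds$subset == subset, , drop = FALSE]
  if (nrow(rows) == 0L) stopf("subset '%s' is empty", subset)
  rows
}

## Descriptor matrix in canonical column order. Accepts a drug_dataset or any
## data frame carrying the six descriptor columns.
descriptor_matrix <- function(data) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != 6L)
      stopf("a bare descriptor vector must have length 6 (canonical order)")
    data <- as.data.frame(as.list(stats::setNames(data, DESCRIPTOR_NAMES)))
  }
  missing_cols <- setdiff(DESCRIPTOR_NAMES, names(data))
  if (length(missing_cols))
    stopf("missing descriptor column(s): %s",
          paste(sQuote(missing_cols), collapse = ", "))
  m <- as.matrix(as.data.frame(data)[DESCRIPTOR_NAMES])
  storage.mode(m) <- "double"
  rownames(m) <- if (!is.null(data$name)) as.character(data$name) else NULL
  m
}

#' @export
print.drug_dataset <- function(x, ...) {
  cat(sprintf("<drug_dataset> %d compounds (%d train, %d test, %d unassigned)\n",
              nrow(x), sum(x$subset == "train"), sum(x$subset == "test"),
              sum(x$subset == "unassigned")))
  print.data.frame(x, ...)
  invisible(x)
}
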