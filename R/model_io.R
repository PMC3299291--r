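## Flat JSON import/export of fitted models, so models are portable across
## the CLI and between sessions as plain text.

#' Write a model to a JSON file
#'
#' Serialises an `mlr_model` or `ann_model` as a flat JSON document
#' (intercept and named coefficients, or unit weights/biases/activations
#' plus the output scaling) with full double precision.
#'
#' @param model An `mlr_model` or `ann_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
#' @seealso [read_model()]
write_model <- function(model, path) {
  listify <- function(v) if (length(v) > 1L && !is.null(names(v))) as.list(v) else v
  doc <- if (inherits(model, "mlr_model")) {
    d <- list(type = "mlr", intercept = model$intercept,
              coef = as.list(model$coef))
    if (!is.null(model$coef_se)) d$coef_se <- as.list(model$coef_se)
    if (!is.null(model$fit)) d$fit <- lapply(model$fit, listify)
    d
  } else if (inherits(model, "ann_model")) {
    list(type = "ann",
         hidden = lapply(model$hidden, function(u)
           list(weights = as.list(u$weights), bias = u$bias,
                activation = u$activation, post_scale = u$post_scale)),
         constants = model$constants, divisor = model$divisor,
         out_range = model$out_range, out_offset = model$out_offset)
  } else stopf("cannot serialise object of class %s", class(model)[1])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from a JSON file
#'
#' @param path Path written by [write_model()].
#' @return An `mlr_model` or `ann_model`, according to the document's
#'   `type` field.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(doc$type, "mlr")) {
    new_mlr_model(intercept = doc$intercept,
                  coef = unlist(doc$coef)[DESCRIPTOR_NAMES],
                  coef_se = if (!is.null(doc$coef_se))
                    unlist(doc$coef_se)[DESCRIPTOR_NAMES],
                  fit = if (!is.null(doc$fit)) lapply(doc$fit, unlist))
  } else if (identical(doc$type, "ann")) {
    units <- lapply(doc$hidden, function(u)
      ann_unit(unlist(u$weights)[DESCRIPTOR_NAMES], bias = u$bias,
               activation = u$activation, post_scale = u$post_scale))
    new_ann_model(hidden = units, constants = unlist(doc$constants),
                  divisor = doc$divisor, out_range = doc$out_range,
                  out_offset = doc$out_offset)
  } else stopf("'%s' is not a recognised model file", path)
}
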