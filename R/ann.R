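## The 6-H-1 feedforward network representation and the reference 6-2-1 net.
##
## A network is a set of weighted hidden units plus optional constant units.
## Unit j emits post_scale_j * act(w_j . x + b_j) with act either tanh or the
## identity; constant units emit a fixed value. The hidden-layer sum S is
## averaged over the weighted units (divisor H) and mapped back to dose by
## the min-max denormalisation
##     MRTD = ((S / H) + 0.5) * out_range + out_offset
## where out_offset / out_offset + out_range are the minimum / maximum MRTD
## of the training subset. Outputs are not clipped to that range: the
## identity-activation unit is unbounded, and the reference model does
## produce negative and out-of-range doses.

ann_unit <- function(weights, bias, activation = c("tanh", "identity"),
                     post_scale = 1) {
  activation <- match.arg(activation)
  weights <- weights[DESCRIPTOR_NAMES]
  if (anyNA(weights) || !identical(names(weights), DESCRIPTOR_NAMES))
    stopf("a hidden unit needs exactly the six canonical input weights")
  if (!is.finite(bias) || !is.finite(post_scale))
    stopf("hidden-unit bias and post_scale must be finite")
  list(weights = weights, bias = bias, activation = activation,
       post_scale = post_scale)
}

new_ann_model <- function(hidden, constants = numeric(0), divisor = length(hidden),
                          out_range, out_offset) {
  if (length(hidden) < 1L) stopf("a network needs at least one hidden unit")
  if (!all(is.finite(constants))) stopf("constant units must be finite")
  if (divisor < 1) stopf("divisor must be >= 1")
  if (!is.finite(out_range) || out_range <= 0) stopf("out_range must be > 0")
  structure(list(hidden = hidden, constants = as.numeric(constants),
                 divisor = divisor, out_range = out_range,
                 out_offset = out_offset),
            class = c("ann_model", "mrtd_model"))
}

## Constants of the reference scoring script, kept unfolded so the bias fold
## is an explicit arithmetic step rather than a pre-computed literal.
reference_ann_constants <- function() {
  list(
    var1 = list(
      weights = c(oxid_hl = -0.543086558961242, p_bd = -5.67413921537257,
                  log_bio_hl = 0.40828801067156, alogp = -0.848110602763694,
                  asol = -2.55399028293542e-02, mw = 1.40343495376914e-02),
      offsets = c(3.63976611815824, 2.81153598121711, 0.747514104338025,
                  1.43330691867064, 0.517313285798853, -5.94322423917294,
                  3.86733992096867),
      post_scale = 0.108990429907616),
    var2 = list(
      weights = c(oxid_hl = 8.23491975851945e-02, p_bd = 3.12529587401663,
                  log_bio_hl = 0.431493610228662, alogp = -0.04107624611641,
                  asol = 4.12997852313067e-02, mw = 1.05078568602304e-03),
      offsets = c(-0.551904322215974, -1.54858410557524, 0.790000076287146,
                  6.94188559367329e-02, -0.836531279838639, -0.444983569959981,
                  9.28741349960935e-02),
      post_scale = 1.44376333322051),
    var3 = -0.535249116383622,
    divisor = 2.0, out_range = 199.9625, out_offset = 0.0375)
}

#' The reference 6-2-1 MRTD network
#'
#' Returns the reference trained neural network for antiretroviral MRTD as
#' an `ann_model`: two weighted hidden units — one affine (identity
#' activation, post-scale 0.10899...) and one tanh-squashed (post-scale
#' 1.44376...) — plus one constant unit (-0.53525...), hidden-layer divisor
#' 2, and min-max output denormalisation with offset 0.0375 and range
#' 199.9625 mg/kg/day (the training-subset MRTD minimum and span).
#'
#' The per-input additive offsets of the original scoring script are folded
#' into a single bias per unit; [eval_dialect_script()] on
#' [reference_ann_script()] evaluates the unfolded script and is the
#' equivalence oracle for that fold.
#'
#' @return An `ann_model`.
#' @export
#' @examples
#' predict(reference_ann(), reference_dataset())
reference_ann <- function() {
  k <- reference_ann_constants()
  new_ann_model(
    hidden = list(
      ann_unit(k$var1$weights, bias = sum(k$var1$offsets),
               activation = "identity", post_scale = k$var1$post_scale),
      ann_unit(k$var2$weights, bias = sum(k$var2$offsets),
               activation = "tanh", post_scale = k$var2$post_scale)),
    constants = k$var3, divisor = k$divisor,
    out_range = k$out_range, out_offset = k$out_offset)
}

## tanh via the explicit exponential quotient, the form the scoring-script
## dialect spells out. Agrees with base tanh to machine precision; kept as a
## single point of truth for both the evaluator and the trainer.
tanh_quotient <- function(x) {
  e1 <- exp(x); e2 <- exp(-x)
  (e1 - e2) / (e1 + e2)
}

ann_activation <- function(x, activation) {
  switch(activation, tanh = tanh_quotient(x), identity = x,
         stopf("unknown activation '%s'", activation))
}

#' Predict MRTD with a feedforward network
#'
#' Evaluates each hidden unit as `post_scale * act(weights . x + bias)`,
#' adds the constant units, averages over the weighted units and applies
#' the min-max output denormalisation. Predictions are unclipped.
#'
#' @param object An `ann_model` (from [reference_ann()] or [train_ann()]).
#' @inheritParams predict.mlr_model
#' @return Numeric vector of predicted doses (mg/kg/day).
#' @export
predict.ann_model <- function(object, newdata, ...) {
  x <- descriptor_matrix(newdata)
  s <- rep(sum(object$constants), nrow(x))
  for (u in object$hidden)
    s <- s + u$post_scale *
      ann_activation(drop(x %*% u$weights[colnames(x)]) + u$bias, u$activation)
  stats::setNames(((s / object$divisor) + 0.5) * object$out_range +
                    object$out_offset, rownames(x))
}

#' Path to the reference network's scoring script
#'
#' The bundled statement-by-statement scoring script for the reference
#' 6-2-1 network, in the `COMPUTE ... Execute.` dialect. Evaluating it with
#' [eval_dialect_script()] reproduces [reference_ann()] predictions exactly
#' (the per-unit bias fold is an arithmetic identity).
#'
#' @return Path to the script file.
#' @export
reference_ann_script <- function() {
  system.file("extdata", "reference_ann.sps", package = "mrtdqspr",
              mustWork = TRUE)
}

#' Evaluate a scoring script in the COMPUTE dialect
#'
#' Parses and evaluates, statement by statement, a network scoring script in
#' the `COMPUTE <var> = <expression>.` dialect (`Execute.` statements are
#' no-ops; `Exp()` is the exponential; a Unicode minus is accepted).
#' Descriptor inputs are bound to the dialect variable names `OxidHL`,
#' `Pr_BD_`, `LogBioHL`, `ALogP`, `Sol`, `MW`. The value of the last
#' assigned variable is returned. Expressions are evaluated in a sealed
#' environment exposing only arithmetic and `exp`.
#'
#' This is the verbatim evaluator used as the independent oracle for
#' [predict.ann_model()], and the consumer side of
#' [export_dialect_script()].
#'
#' @param script Path to a script file, or the script as a character scalar
#'   or vector of lines.
#' @inheritParams predict.mlr_model
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
#' @examples
#' eval_dialect_script(reference_ann_script(),
#'                     reference_dataset()[1:3, ])
eval_dialect_script <- function(script, newdata) {
  lines <- if (length(script) == 1L && !grepl("\n", script) && file.exists(script))
    readLines(script, warn = FALSE) else unlist(strsplit(script, "\n"))
  lines <- gsub("−", "-", lines)

  ## A statement runs until a line whose last non-blank character is '.'
  statements <- character(0); buf <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    buf <- c(buf, ln)
    if (grepl("\\.\\s*$", ln)) {
      statements <- c(statements, paste(buf, collapse = " "))
      buf <- character(0)
    }
  }
  if (length(buf)) stopf("unterminated statement: %s", buf[1])

  x <- descriptor_matrix(newdata)
  env <- new.env(parent = emptyenv())
  for (op in c("+", "-", "*", "/", "(")) assign(op, get(op, baseenv()), env)
  assign("Exp", exp, env)
  for (v in names(DIALECT_VARS)) assign(v, x[, DIALECT_VARS[[v]]], env)

  target <- NULL
  for (st in statements) {
    st <- sub("\\.\\s*$", "", trimws(st))
    if (tolower(st) == "execute") next
    m <- regmatches(st, regexec("^COMPUTE\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", st))[[1]]
    if (length(m) != 3L) stopf("cannot parse statement: %s", st)
    value <- eval(parse(text = m[3], keep.source = FALSE)[[1]], env)
    assign(m[2], value, env)
    target <- m[2]
  }
  if (is.null(target)) stopf("script contains no COMPUTE statement")
  stats::setNames(rep_len(get(target, env), nrow(x)), rownames(x))
}

#' Export a network as a scoring script
#'
#' Renders an `ann_model` in the `COMPUTE ... Execute.` scoring dialect:
#' one affine accumulation statement per hidden unit, the activation and
#' post-scale pass, the constant units, and the output denormalisation
#' statement. Constants are written with 17 significant digits so the text
#' round-trips doubles exactly; re-evaluating the export with
#' [eval_dialect_script()] reproduces [predict.ann_model()] to within
#' floating-point noise.
#'
#' @param net An `ann_model`.
#' @return The script as a single character scalar.
#' @export
#' @examples
#' cat(export_dialect_script(reference_ann()))
export_dialect_script <- function(net) {
  stopifnot(inherits(net, "ann_model"))
  num <- function(v) {
    s <- formatC(v, digits = 17, format = "g")
    ifelse(v < 0, paste0("(", s, ")"), s)
  }
  dialect_of <- stats::setNames(names(DIALECT_VARS), DIALECT_VARS)
  out <- character(0)
  nh <- length(net$hidden)
  vars <- paste0("Var", seq_len(nh + length(net$constants)))
  for (j in seq_len(nh)) {
    u <- net$hidden[[j]]
    terms <- sprintf("(%s * %s)", dialect_of[DESCRIPTOR_NAMES],
                     num(u$weights[DESCRIPTOR_NAMES]))
    out <- c(out, sprintf("COMPUTE %s = %s\n + %s.", vars[j],
                          paste(terms, collapse = "\n + "), num(u$bias)))
  }
  for (k in seq_along(net$constants))
    out <- c(out, sprintf("COMPUTE %s = %s.", vars[nh + k],
                          num(net$constants[k])))
  out <- c(out, "Execute.")
  for (j in seq_len(nh)) {
    u <- net$hidden[[j]]
    out <- c(out, switch(u$activation,
      identity = sprintf("COMPUTE %s = %s * %s.", vars[j], num(u$post_scale), vars[j]),
      tanh = sprintf(
        "COMPUTE %s = %s * (Exp(%s) - Exp(-%s)) / (Exp(%s) + Exp(-%s)).",
        vars[j], num(u$post_scale), vars[j], vars[j], vars[j], vars[j])))
  }
  out <- c(out, "Execute.")
  out <- c(out, sprintf(
    "COMPUTE Predicted_MRTD = ((((%s)/%s) + 0.5) * %s) + %s.",
    paste(vars, collapse = " + "), num(net$divisor), num(net$out_range),
    num(net$out_offset)))
  out <- c(out, "Execute.")
  paste(out, collapse = "\n")
}

#' @export
print.ann_model <- function(x, ...) {
  acts <- vapply(x$hidden, `[[`, "", "activation")
  cat(sprintf("<ann_model> 6-%d-1 network (+%d constant unit%s)\n",
              length(x$hidden), length(x$constants),
              if (length(x$constants) == 1) "" else "s"))
  cat(sprintf("  activations: %s; divisor %g\n", paste(acts, collapse = ", "),
              x$divisor))
  cat(sprintf("  output scale: MRTD = ((S/%g) + 0.5) * %.6g + %.6g mg/kg/day\n",
              x$divisor, x$out_range, x$out_offset))
  invisible(x)
}
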