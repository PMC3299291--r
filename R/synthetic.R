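## Seeded generator of descriptor datasets with a known ground-truth model.

#' Default descriptor sampling laws
#'
#' Per-descriptor distributions shaped like the bundled antiretroviral
#' training subset: heavy-tailed positive log-normals for the oxidation
#' half-life and aqueous solubility, a U-shaped beta law for the
#' biodegradation probability, symmetric normals for AlogP and the log
#' biotransformation half-life, and a moderately skewed log-normal for
#' molecular weight. Each law's parameters are chosen to match the training
#' subset's column mean and SD (oxid_hl 0.672/2.77 days, p_bd 0.402/0.394,
#' log_bio_hl -2.51/1.57, alogp 0.94/2.81, asol 6.15/10.9 g/L,
#' mw 364.7/178 Da).
#'
#' @return Named list of law specifications (`family` plus parameters),
#'   one per canonical descriptor.
#' @export
default_descriptor_laws <- function() {
  ## log-normal matching mean m and coefficient of variation cv:
  ## sdlog^2 = log(1 + cv^2), meanlog = log(m) - sdlog^2 / 2
  lnorm_for <- function(m, cv) {
    s2 <- log(1 + cv^2)
    list(family = "lognormal", meanlog = log(m) - s2 / 2, sdlog = sqrt(s2),
         target_mean = m)
  }
  ## beta matching mean m and sd s: a + b = m (1 - m) / s^2 - 1
  beta_for <- function(m, s) {
    k <- m * (1 - m) / s^2 - 1
    list(family = "beta", shape1 = m * k, shape2 = (1 - m) * k, target_mean = m)
  }
  list(
    oxid_hl = lnorm_for(0.672, 2.769 / 0.672),
    p_bd = beta_for(0.402, 0.394),
    log_bio_hl = list(family = "normal", mean = -2.5133, sd = 1.5738,
                      target_mean = -2.5133),
    alogp = list(family = "normal", mean = 0.939, sd = 2.809,
                 target_mean = 0.939),
    asol = lnorm_for(6.15, 10.90 / 6.15),
    mw = lnorm_for(364.72, 178.20 / 364.72))
}

draw_law <- function(law, n) {
  switch(law$family,
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    beta = stats::rbeta(n, law$shape1, law$shape2),
    normal = stats::rnorm(n, law$mean, law$sd),
    stopf("unknown distribution family '%s'", law$family))
}

#' Generate a synthetic descriptor dataset from a known model
#'
#' Draws `n` descriptor vectors independently from the configured laws
#' (descriptors are mutually independent by default; `correlation` mixes in
#' a shared Gaussian factor on the normal-scale of every law for stress
#' tests), computes the ground-truth dose with `truth`, adds Gaussian noise
#' and floors the result at `clip_floor` so every record satisfies the
#' positive-dose invariant. The flooring is a generator artifact, not a
#' property of the dose models; rows where it bound are recorded in the
#' `floored` attribute so exact-recovery checks can exclude them.
#'
#' Identical seeds give byte-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param n Number of records.
#' @param truth A model with a `predict` method (`mlr_model` or
#'   `ann_model`) supplying the noiseless dose surface.
#' @param noise_sd SD of the additive Gaussian dose noise (mg/kg/day).
#' @param seed RNG seed.
#' @param clip_floor Minimum MRTD (default 0.01 mg/kg/day).
#' @param laws Descriptor laws, as [default_descriptor_laws()].
#' @param correlation Optional common-factor loading in \[0, 1) applied on
#'   each law's underlying normal scale; 0 (default) keeps descriptors
#'   independent.
#' @param subset Subset tag assigned to every generated record.
#' @return List with `data` (a [drug_dataset][as_drug_dataset] carrying a
#'   logical `floored` attribute) and `truth` (the generating model).
#' @export
#' @examples
#' g <- generate_dataset(50, reference_mlr(), noise_sd = 0, seed = 42)
#' head(g$data)
generate_dataset <- function(n, truth, noise_sd = 0, seed = 1,
                             clip_floor = 0.01, laws = default_descriptor_laws(),
                             correlation = 0, subset = "train") {
  if (n < 1L) stopf("n must be >= 1")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (correlation < 0 || correlation >= 1) stopf("correlation must be in [0, 1)")
  if (!inherits(truth, "mrtd_model"))
    stopf("truth must be an mlr_model or ann_model")
  missing_laws <- setdiff(DESCRIPTOR_NAMES, names(laws))
  if (length(missing_laws))
    stopf("laws missing descriptor(s): %s", paste(missing_laws, collapse = ", "))

  with_seed(seed, {
    desc <- if (correlation == 0) {
      as.data.frame(lapply(laws[DESCRIPTOR_NAMES], draw_law, n = n))
    } else {
      ## shared factor injected through a Gaussian copula on each margin
      z <- sqrt(correlation) * stats::rnorm(n)
      u <- stats::pnorm(sapply(seq_along(DESCRIPTOR_NAMES), function(k)
        z + sqrt(1 - correlation) * stats::rnorm(n)))
      qs <- list(
        lognormal = function(p, l) stats::qlnorm(p, l$meanlog, l$sdlog),
        beta = function(p, l) stats::qbeta(p, l$shape1, l$shape2),
        normal = function(p, l) stats::qnorm(p, l$mean, l$sd))
      out <- lapply(seq_along(DESCRIPTOR_NAMES), function(k) {
        l <- laws[[DESCRIPTOR_NAMES[k]]]
        qs[[l$family]](u[, k], l)
      })
      stats::setNames(as.data.frame(out), DESCRIPTOR_NAMES)
    }
    names(desc) <- DESCRIPTOR_NAMES
    dose <- predict(truth, desc) + stats::rnorm(n, 0, noise_sd)
    floored <- dose < clip_floor
    dose[floored] <- clip_floor
    df <- cbind(data.frame(name = sprintf("syn_%04d", seq_len(n)),
                           subset = subset, mrtd = unname(dose)), desc)
    ds <- as_drug_dataset(df)
    attr(ds, "floored") <- unname(floored)
    list(data = ds, truth = truth)
  })
}
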