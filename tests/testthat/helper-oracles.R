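# Independent oracles and fixtures built in code. These deliberately use
# different algorithms from the implementation they check.

# OLS by explicit normal equations: beta = (X'X)^-1 X'y. Numerically naive
# on purpose -- the implementation must agree with it on well-conditioned
# problems, but never shares code with it.
ols_normal_equations <- function(x, y) {
  xd <- cbind(intercept = 1, x)
  drop(solve(crossprod(xd), crossprod(xd, y)))
}

# All permutations of 1..n, one per row (n <= 8 in the tests).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, k] <- n
    out[rows, -k] <- sub
    r <- r + nrow(sub)
  }
  out
}

count_inversions_naive <- function(p) {
  n <- length(p)
  sum(vapply(seq_len(n - 1), function(i) sum(p[(i + 1):n] < p[i]), 0L))
}

# Exact two-sided Kendall p by brute force over every permutation of n.
kendall_p_bruteforce <- function(x, y) {
  n <- length(x)
  d_obs <- count_inversions_naive(rank(y)[order(x)])
  d_all <- apply(all_permutations(n), 1, count_inversions_naive)
  min(1, 2 * min(mean(d_all <= d_obs), mean(d_all >= d_obs)))
}

# Central finite differences of the scalar function f in the named numeric
# pieces of par, for the backprop gradient check.
finite_diff_gradient <- function(f, par, pieces, eps = 1e-6) {
  out <- list()
  for (nm in pieces) {
    g <- par[[nm]]
    for (i in seq_along(g)) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      g[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# A bounded tanh-only 6-2-1 teacher network in raw descriptor space, with
# outputs confined to roughly [15, 95] mg/kg/day so the generator's dose
# floor never binds and the surface stays exactly realisable by the
# trainer's architecture.
make_teacher_ann <- function() {
  x <- as.matrix(reference_dataset()[reference_dataset()$subset == "train",
                                     descriptor_names()])
  mu <- colMeans(x)
  sig <- apply(x, 2, sd)
  unit <- function(w_std, b_std, v)
    mrtdqspr:::ann_unit(setNames(w_std / sig, descriptor_names()),
                        bias = b_std - sum(w_std * mu / sig),
                        activation = "tanh", post_scale = v)
  mrtdqspr:::new_ann_model(
    hidden = list(unit(c(0.8, -0.5, 0.6, -0.4, 0.7, 0.3), 0.2, 0.45),
                  unit(c(-0.3, 0.9, -0.2, 0.6, -0.5, 0.8), -0.1, -0.35)),
    constants = 0.05, divisor = 2, out_range = 100, out_offset = 5)
}

# A linear ground truth whose doses stay well above the generator floor
# under the default descriptor laws (large positive intercept, mild slopes).
make_positive_mlr <- function() {
  mrtdqspr:::new_mlr_model(
    intercept = 120,
    coef = c(oxid_hl = 2, p_bd = 15, log_bio_hl = 4, alogp = -3,
             asol = 1.5, mw = 0.05))
}

# Printed reference values for the 8-compound test subset (prediction
# tables of the reference models), used by several suites.
reference_test_expectations <- function() {
  data.frame(
    name = c("Abacavir", "Emtricitabine", "Raltegravir", "Nevirapine",
             "Efavirenz", "Fosamprenavir", "Atazanavir", "Lopiravir"),
    mlr = c(-10.6738, -23.9239, 0.0628, -54.1862, -10.2863, 44.0515,
            11.4360, 42.6361),
    ann = c(6.4861, 3.3678, 19.7700, -16.5700, -5.7782, 50.7500,
            29.8700, 64.5900))
}
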