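## Online error-backpropagation trainer for 6-H-1 networks.
##
## Internal parameterisation (all in standardised input space):
##   W  H x 6 matrix of input weights        b  H hidden biases
##   v  H output weights (post-scales)       cc output constant
## Scaled forward pass: u = (sum_j v_j tanh(W_j x + b_j) + cc) / H, trained
## against targets t = (y - min y) / (max y - min y) - 0.5 in [-0.5, 0.5].
## The fitted parameters are folded back to raw descriptor space on export,
## so a trained model is an ordinary `ann_model` and scores raw descriptors
## exactly like the reference scoring script.

ann_forward_scaled <- function(par, x) {
  h <- tanh_quotient(drop(par$W %*% x) + par$b)
  list(h = h, u = (sum(par$v * h) + par$cc) / par$H)
}

ann_loss <- function(par, x, t) {
  0.5 * (ann_forward_scaled(par, x)$u - t)^2
}

## Exact gradient of ann_loss in all parameters, for one pattern.
ann_gradient <- function(par, x, t) {
  fw <- ann_forward_scaled(par, x)
  e <- (fw$u - t) / par$H
  dh <- e * par$v * (1 - fw$h^2)        # through tanh
  list(W = tcrossprod(dh, x), b = dh, v = e * fw$h, cc = e)
}

ann_rmse_scaled <- function(par, X, t) {
  u <- vapply(seq_len(nrow(X)), function(i) ann_forward_scaled(par, X[i, ])$u, 0.0)
  sqrt(mean((u - t)^2))
}

#' Train a 6-H-1 network by online backpropagation
#'
#' Trains a single-hidden-layer tanh network on a dataset subset with
#' per-pattern (online) gradient descent in seeded shuffled order, no
#' momentum. Inputs are standardised internally to training-subset z-scores
#' and targets are min-max scaled to \[-0.5, 0.5\]; both scalings are folded
#' into the returned weights, so the resulting [ann_model][reference_ann]
#' consumes raw descriptors. Initial weights are uniform on \[-0.5, 0.5\]
#' from `seed`; training is bit-reproducible for a fixed seed.
#'
#' Training stops at `max_epochs`, or after `patience` consecutive epochs
#' without the training RMSE improving by more than `1e-6` of the target
#' range. The parameters from the best epoch (lowest training RMSE) are
#' returned, so the recorded best-so-far RMSE history is non-increasing.
#'
#' @inheritParams fit_ols
#' @param hidden Number of weighted hidden units (default 2, the reference
#'   architecture).
#' @param learning_rate Gradient step size (default 0.7, the reference
#'   training setting).
#' @param max_epochs Maximum number of passes over the training patterns.
#' @param patience Epochs without improvement tolerated before stopping.
#' @param seed RNG seed controlling initialisation and pattern order.
#' @return An `ann_model` with attributes `history` (best-so-far training
#'   RMSE per epoch, mg/kg/day) and `train_rmse` (final best RMSE).
#' @export
#' @examples
#' net <- train_ann(reference_dataset(), "train", max_epochs = 50, seed = 1)
#' attr(net, "train_rmse")
train_ann <- function(ds, subset = "train", hidden = 2, learning_rate = 0.7,
                      max_epochs = 1000, patience = 100, seed = 1) {
  ds <- as_drug_dataset(ds)
  if (hidden < 1L) stopf("hidden must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (max_epochs < 1L) stopf("max_epochs must be >= 1")
  rows <- dataset_rows(ds, subset)
  if (anyNA(rows$mrtd)) stopf("subset '%s' has records without MRTD", subset)
  y <- rows$mrtd
  out_offset <- min(y)
  out_range <- max(y) - min(y)
  if (out_range <= 0) stopf("degenerate target range: all MRTD values equal")
  t <- (y - out_offset) / out_range - 0.5

  xraw <- descriptor_matrix(rows)
  mu <- colMeans(xraw)
  sig <- apply(xraw, 2, stats::sd)
  sig[sig == 0] <- 1                    # constant column: leave centred only
  X <- sweep(sweep(xraw, 2, mu), 2, sig, "/")

  n <- nrow(X); H <- as.integer(hidden)
  with_seed(seed, {
    par <- list(W = matrix(stats::runif(H * 6, -0.5, 0.5), H, 6),
                b = stats::runif(H, -0.5, 0.5),
                v = stats::runif(H, -0.5, 0.5),
                cc = stats::runif(1, -0.5, 0.5), H = H)
    best <- list(par = par, rmse = ann_rmse_scaled(par, X, t))
    history <- numeric(0)
    stale <- 0L
    for (epoch in seq_len(max_epochs)) {
      for (i in sample.int(n)) {
        g <- ann_gradient(par, X[i, ], t[i])
        par$W <- par$W - learning_rate * g$W
        par$b <- par$b - learning_rate * g$b
        par$v <- par$v - learning_rate * g$v
        par$cc <- par$cc - learning_rate * g$cc
      }
      rmse <- ann_rmse_scaled(par, X, t)
      if (!is.finite(rmse))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      if (rmse < best$rmse - 1e-6) {
        best <- list(par = par, rmse = rmse); stale <- 0L
      } else stale <- stale + 1L
      history <- c(history, best$rmse)
      if (stale >= patience) break
    }
  })

  ## Fold the z-scoring into raw-space weights:
  ##   w_std . x_std + b = (w_std / sig) . x_raw + (b - w_std . (mu / sig))
  par <- best$par
  units <- lapply(seq_len(H), function(j) {
    w_std <- par$W[j, ]
    ann_unit(stats::setNames(w_std / sig, DESCRIPTOR_NAMES),
             bias = par$b[j] - sum(w_std * mu / sig),
             activation = "tanh", post_scale = par$v[j])
  })
  net <- new_ann_model(hidden = units, constants = par$cc, divisor = H,
                       out_range = out_range, out_offset = out_offset)
  attr(net, "history") <- history * out_range
  attr(net, "train_rmse") <- best$rmse * out_range
  net
}
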