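# The two modified weighted binary-crossentropy losses of the adversarial
# scheme.  Both compare a prediction array (per-row simplices) entrywise
# against a one-hot target array: per valid entry
# -[t log p + (1 - t) log(1 - p)], averaged over the valid categories of each
# row, combined across rows with weight vector [W, 1, ..., 1] and normalized
# by (W + K), then averaged over the batch.  The encoder loss targets the
# adversarial (confound-erased) array, the regressor loss the true array;
# the two coincide on the label row.  Predictions are clipped to
# [eps, 1 - eps] before the logs.

#' Loss weights
#'
#' @param W weight of the label row relative to each confound row; in
#'   practice set to 6.
#' @param epsilon log-clip constant for numerical stability.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(W = 6, epsilon = 1e-7) {
  if (!(W > 0)) {
    stop_mucran("W must be positive", class = "mucran_config_error")
  }
  if (!(epsilon > 0 && epsilon < 0.5)) {
    stop_mucran("epsilon must lie in (0, 0.5)", class = "mucran_config_error")
  }
  structure(list(W = W, epsilon = epsilon), class = "loss_weights")
}

# per-entry weight vector on the flattened (out_dim) layout:
# row weight / (row width * (W + K)); 0 at padded entries
loss_entry_weights <- function(layout, weights) {
  K <- layout$n_rows - 1L
  wrow <- c(weights$W, rep(1, K)) / (weights$W + K)
  wvec <- numeric(layout$out_dim)
  for (r in seq_len(layout$n_rows)) {
    idx <- layout$row_idx[[r]]
    wvec[idx] <- wrow[r] / length(idx)
  }
  wvec
}

# matrix-form loss + gradient used in training: p, t are (out_dim x B)
loss_from_matrices <- function(p, t, layout, weights, want_grad = FALSE) {
  eps <- weights$epsilon
  wvec <- loss_entry_weights(layout, weights)
  pc <- clip01(p, eps)
  bce <- -(t * log(pc) + (1 - t) * log(1 - pc))
  loss <- sum(wvec * rowSums(bce)) / ncol(p)
  out <- list(loss = loss)
  if (want_grad) {
    g <- wvec * (pc - t) / (pc * (1 - pc)) / ncol(p)
    g[p < eps | p > 1 - eps] <- 0  # clipped region: flat
    out$d_probs <- g
  }
  out
}

as_flat_pair <- function(pred, target) {
  if (inherits(pred, "prediction_array")) pred <- list(pred)
  if (inherits(target, "target_array")) target <- list(target)
  stopifnot(length(pred) == length(target), length(pred) >= 1)
  p <- vapply(pred, function(a) as.numeric(t(a$values)),
              numeric(length(pred[[1]]$values)))
  t <- vapply(target, function(a) as.numeric(t(a$values)),
              numeric(length(target[[1]]$values)))
  p <- matrix(p, ncol = length(pred))
  t <- matrix(t, ncol = length(target))
  m1 <- pred[[1]]$mask
  m2 <- target[[1]]$mask
  if (!identical(dim(m1), dim(m2)) || any(m1 != m2)) {
    stop_mucran("prediction and target geometry differ",
                class = "mucran_geometry_error")
  }
  if (anyNA(p) || anyNA(t)) {
    stop_mucran("NaN/NA in loss inputs", class = "mucran_value_error")
  }
  list(p = p, t = t)
}

#' Weighted per-row binary crossentropy
#'
#' @param pred a `prediction_array` (see [as_prediction_array()]) or list of
#'   them (a batch).
#' @param target a `target_array` ([encode_true_targets()] /
#'   [encode_adversarial_targets()]) or list of them, geometry-matched to
#'   `pred`.
#' @param weights a [loss_weights()] object.
#' @return Non-negative scalar loss.
#' @export
weighted_row_bce <- function(pred, target, weights = loss_weights()) {
  pt <- as_flat_pair(pred, target)
  schema <- if (inherits(pred, "prediction_array")) pred$schema
            else pred[[1]]$schema
  loss_from_matrices(pt$p, pt$t, schema_layout(schema), weights)$loss
}

#' Encoder (adversarial) loss for one record
#'
#' Evaluates [weighted_row_bce()] against the adversarial target array of
#' `record`: true label row, every confound row the constant `[1, 0, ..., 0]`.
#' The value is therefore invariant to the record's confound values.
#'
#' @param pred a `prediction_array` for the record's volume.
#' @param record metadata record (one-row data frame or named list).
#' @param schema a [build_schema()] result.
#' @param weights a [loss_weights()] object.
#' @return Non-negative scalar loss.
#' @export
encoder_loss <- function(pred, record, schema, weights = loss_weights()) {
  weighted_row_bce(pred, encode_adversarial_targets(record, schema), weights)
}

#' Regressor loss for one record
#'
#' Evaluates [weighted_row_bce()] against the true target array of `record`
#' (label and observed confound categories).
#'
#' @inheritParams encoder_loss
#' @return Non-negative scalar loss.
#' @export
regressor_loss <- function(pred, record, schema, weights = loss_weights()) {
  weighted_row_bce(pred, encode_true_targets(record, schema), weights)
}
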