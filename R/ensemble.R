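# Ensemble consensus and uncertainty thresholding.
#
# Each base learner outputs per-row softmax probabilities; the ensemble
# prediction is their unweighted elementwise mean, and the averaged label row
# entry with the higher value is the final prediction.  For a binary label
# the winning averaged probability (the consensus confidence) lies in
# [0.5, 1]: near 1 when all learners agree (in-distribution), near 0.5 when
# their outputs are essentially random (out-of-distribution).  Thresholding
# the confidence therefore isolates an in-distribution test subset.

#' Ensemble consensus prediction
#'
#' @param ensemble a `mucran_ensemble` (see [train_ensemble()]) or a list of
#'   `mucran_model`s sharing one schema.
#' @param newdata a `mucran_dataset` or `voxels x n` volume matrix.
#' @param batch_size volumes per forward pass.
#' @return An `ensemble_prediction`: list with `per_model` (list of
#'   `out_dim x n` probability matrices), `averaged` (their elementwise
#'   mean), `label_confidence` (max of the averaged label row per sample),
#'   `predicted_label` (argmax category) and `schema`.
#' @export
ensemble_predict <- function(ensemble, newdata, batch_size = 128L) {
  models <- if (inherits(ensemble, "mucran_ensemble")) ensemble$models
            else ensemble
  stopifnot(length(models) >= 1)
  schema <- models[[1]]$schema
  for (m in models) {
    if (!identical(unclass(m$schema), unclass(schema))) {
      stop_mucran("ensemble members use different schemas",
                  class = "mucran_schema_error")
    }
  }
  per_model <- lapply(models, predict, newdata = newdata,
                      batch_size = batch_size)
  averaged <- Reduce(`+`, per_model) / length(per_model)
  lab_idx <- seq_along(schema$label_categories)
  lab <- averaged[lab_idx, , drop = FALSE]
  win <- apply(lab, 2, which.max)
  structure(list(per_model = per_model, averaged = averaged,
                 label_confidence = apply(lab, 2, max),
                 predicted_label = schema$label_categories[win],
                 sample_ids = colnames(averaged), schema = schema),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat("ensemble prediction: ", length(x$per_model), " base learners, ",
      length(x$label_confidence), " samples; mean consensus confidence ",
      sprintf("%.3f", mean(x$label_confidence)), "\n", sep = "")
  invisible(x)
}

confidence_of <- function(preds) {
  if (inherits(preds, "ensemble_prediction")) preds$label_confidence
  else as.numeric(preds)
}

#' Split samples into in-distribution (kept) and rejected by consensus
#'
#' A sample is kept iff its consensus confidence is at least `tau`
#' (ties kept).  `tau = 0.5` keeps the entire test set; `tau = 0.9` isolates
#' the in-distribution portion on which the ensemble unanimously agrees.
#'
#' @param preds an `ensemble_prediction` or a numeric confidence vector.
#' @param tau threshold in \[0.5, 1\].
#' @return list with integer vectors `kept` and `rejected`.
#' @export
threshold_in_distribution <- function(preds, tau = 0.9) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0.5 || tau > 1) {
    stop_mucran("tau must lie in [0.5, 1]", class = "mucran_config_error")
  }
  conf <- confidence_of(preds)
  kept <- which(conf >= tau)
  list(kept = kept, rejected = setdiff(seq_along(conf), kept))
}

#' Coverage/accuracy trade-off across thresholds
#'
#' @param preds an `ensemble_prediction` (or confidence vector, in which
#'   case `predicted` must be given).
#' @param truths true label per sample.
#' @param taus threshold grid.
#' @param predicted predicted label per sample (taken from `preds` when it is
#'   an `ensemble_prediction`).
#' @return data frame with one row per threshold: `tau`, `kept_fraction`
#'   (non-increasing in tau), `n_kept` and `accuracy` (`NA` when nothing is
#'   kept).
#' @export
coverage_accuracy_curve <- function(preds, truths,
                                    taus = seq(0.5, 0.95, by = 0.05),
                                    predicted = NULL) {
  conf <- confidence_of(preds)
  if (is.null(predicted)) {
    stopifnot(inherits(preds, "ensemble_prediction"))
    predicted <- preds$predicted_label
  }
  if (length(truths) != length(conf)) {
    stop_mucran("length mismatch between predictions and truths",
                class = "mucran_geometry_error")
  }
  do.call(rbind, lapply(taus, function(tau) {
    kept <- threshold_in_distribution(conf, tau)$kept
    data.frame(tau = tau,
               kept_fraction = length(kept) / length(conf),
               n_kept = length(kept),
               accuracy = if (length(kept)) {
                 mean(predicted[kept] == truths[kept])
               } else NA_real_)
  }))
}

#' Write the per-sample prediction table
#'
#' One row per sample: id, each base learner's label-row probabilities, the
#' averaged probabilities, the consensus confidence and the kept flag at
#' `tau`.
#'
#' @param preds an `ensemble_prediction`.
#' @param path CSV path.
#' @param tau threshold used for the `kept` column.
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(preds, path, tau = 0.9) {
  schema <- preds$schema
  lab_idx <- seq_along(schema$label_categories)
  df <- data.frame(sample_id = preds$sample_ids %||%
                     seq_along(preds$label_confidence))
  for (m in seq_along(preds$per_model)) {
    for (j in lab_idx) {
      df[[sprintf("m%02d_p_%s", m, schema$label_categories[j])]] <-
        preds$per_model[[m]][j, ]
    }
  }
  for (j in lab_idx) {
    df[[sprintf("avg_p_%s", schema$label_categories[j])]] <-
      preds$averaged[j, ]
  }
  df$confidence <- preds$label_confidence
  df$predicted <- preds$predicted_label
  df$kept <- preds$label_confidence >= tau
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
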