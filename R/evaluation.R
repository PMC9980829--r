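# Evaluation protocol: confound-predictability AUROC, age-matched test
# sampling, and threshold-stratified accuracy reporting.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive outscores a random negative, ties counting one half.  Invariant
#' to strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truths binary ground truth (logical, 0/1, or two-level factor whose
#'   second level is positive... supply logical to be explicit).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truths) {
  if (is.factor(truths)) truths <- as.integer(truths) == 2L
  truths <- as.logical(truths)
  if (anyNA(scores) || anyNA(truths)) {
    stop_mucran("NA in auroc inputs", class = "mucran_value_error")
  }
  n_pos <- sum(truths)
  n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    stop_mucran("auroc undefined: both classes must be present",
                class = "mucran_value_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truths]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confound predictability of an ensemble (macro one-vs-rest AUROC)
#'
#' Scores each confound by how well the ensemble-averaged confound rows of
#' the prediction array predict the true (binned) categories: per category, a
#' one-vs-rest AUROC using the averaged probability of that category; the
#' confound's value is the unweighted macro average over categories present
#' in the test set.  0.5 means the features carry no usable confound
#' information — the adversarial goal is every confound within the 10%
#' margin of 0.5 — while a directly supervised (confounded) model scores
#' high on confounds it can see.
#'
#' @param ensemble a `mucran_ensemble` (or `ensemble_prediction` from
#'   [ensemble_predict()]).
#' @param dataset a `mucran_dataset` whose metadata holds the true confound
#'   values (ignored when `ensemble` is already a prediction).
#' @param metadata metadata table; defaults to `dataset$metadata`.
#' @return data frame with one row per confound: `confound`, `auroc`,
#'   `n_categories` evaluated.  Confounds whose test coverage has fewer than
#'   two categories are skipped with a warning.
#' @export
confound_predictability <- function(ensemble, dataset = NULL,
                                    metadata = NULL) {
  preds <- if (inherits(ensemble, "ensemble_prediction")) ensemble
           else ensemble_predict(ensemble, dataset)
  metadata <- metadata %||% dataset$metadata
  schema <- preds$schema
  W <- schema$row_width
  out <- list()
  for (r in seq_along(schema$confounds)) {
    cc <- schema$confounds[[r]]
    truth <- confound_categories(metadata, schema, cc$name)
    present <- levels(truth)[tabulate(truth, nbins = nlevels(truth)) > 0]
    if (length(present) < 2) {
      warning("confound '", cc$name,
              "' skipped: fewer than two categories in the test set")
      next
    }
    per_cat <- vapply(present, function(cat) {
      j <- match(cat, cc$categories)
      auroc(preds$averaged[r * W + j, ], truth == cat)
    }, 0)
    out[[cc$name]] <- data.frame(confound = cc$name,
                                 auroc = mean(per_cat),
                                 n_categories = length(present))
  }
  if (!length(out)) {
    return(data.frame(confound = character(), auroc = numeric(),
                      n_categories = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age-matched equal-size case/control sample
#'
#' Keeps records older than the age threshold, then pairs each member of the
#' smaller label group with its nearest-age counterpart in the other group
#' (greedy, without replacement, no caliper), yielding equal group sizes
#' with closely matched age distributions — so age imbalance cannot inflate
#' apparent classification accuracy.
#'
#' @param metadata metadata table with an age column.
#' @param age_min minimum age (inclusive) for inclusion, default 55.
#' @param seed seed for the (otherwise arbitrary) processing order of the
#'   smaller group; the result is deterministic given it.
#' @param label_col,age_col column names.
#' @param positive_class label value treated as the case group; defaults to
#'   the first value observed.
#' @return A `matched_sample`: list with `rows` (row indices into
#'   `metadata`), `pairs` (data frame of matched row pairs and their age
#'   gap), and `group_sizes`.
#' @export
age_matched_sample <- function(metadata, age_min = 55, seed = 1L,
                               label_col = "label", age_col = "age",
                               positive_class = NULL) {
  keep <- which(metadata[[age_col]] >= age_min)
  lab <- as.character(metadata[[label_col]][keep])
  positive_class <- positive_class %||% unique(lab)[1]
  pos <- keep[lab == positive_class]
  neg <- keep[lab != positive_class]
  if (!length(pos) || !length(neg)) {
    stop_mucran("a label group is empty after the age filter",
                class = "mucran_value_error")
  }
  swap <- length(pos) > length(neg)
  small <- if (swap) neg else pos
  large <- if (swap) pos else neg
  ages <- metadata[[age_col]]
  ord <- with_seed(seed, sample.int(length(small)))
  small <- small[ord]
  used <- logical(length(large))
  pairs <- lapply(small, function(i) {
    gaps <- abs(ages[large] - ages[i])
    gaps[used] <- Inf
    j <- which.min(gaps)
    used[j] <<- TRUE
    data.frame(small_row = i, large_row = large[j], age_gap = gaps[j])
  })
  pairs <- do.call(rbind, pairs)
  names(pairs)[1:2] <- if (swap) c("neg_row", "pos_row")
                       else c("pos_row", "neg_row")
  rows <- sort(c(pairs[[1]], pairs[[2]]))
  structure(list(rows = rows, pairs = pairs,
                 group_sizes = c(length(small), length(small)),
                 age_min = age_min, positive_class = positive_class),
            class = "matched_sample")
}

#' Threshold-stratified accuracy report
#'
#' Accuracy and kept-set size per (uncertainty threshold, subset) cell,
#' where the subsets are the whole test set and its age-matched equal-size
#' sample.  Mirrors the reporting layout "accuracy (n kept)" of clinical
#' evaluations: at `tau = 0.5` the whole subset is kept, at `tau = 0.9` only
#' the in-distribution portion.
#'
#' @param preds an `ensemble_prediction` aligned with `metadata` rows.
#' @param truths true label per sample.
#' @param metadata metadata table (for the age-matched subset).
#' @param taus thresholds to report (default 0.5 and 0.9).
#' @param age_min,seed passed to [age_matched_sample()].
#' @return data frame with columns `subset`, `tau`, `n_subset`, `n_kept`,
#'   `accuracy` (`NA` when a cell is empty).
#' @export
stratified_accuracy_report <- function(preds, truths, metadata,
                                       taus = c(0.5, 0.9), age_min = 55,
                                       seed = 1L) {
  conf <- confidence_of(preds)
  predicted <- preds$predicted_label
  if (length(truths) != length(conf) || nrow(metadata) != length(conf)) {
    stop_mucran("predictions, truths and metadata must be aligned",
                class = "mucran_geometry_error")
  }
  subsets <- list(all = seq_along(conf))
  ms <- tryCatch(age_matched_sample(metadata, age_min = age_min, seed = seed,
                                    label_col = "label"),
                 mucran_error = function(e) NULL)
  if (!is.null(ms)) subsets$age_matched <- ms$rows
  do.call(rbind, lapply(names(subsets), function(sn) {
    idx <- subsets[[sn]]
    do.call(rbind, lapply(taus, function(tau) {
      kept <- idx[conf[idx] >= tau]
      data.frame(subset = sn, tau = tau, n_subset = length(idx),
                 n_kept = length(kept),
                 accuracy = if (length(kept)) {
                   mean(predicted[kept] == truths[kept])
                 } else NA_real_)
    }))
  }))
}

#' Render a stratified accuracy report as plain text
#'
#' @param report data frame from [stratified_accuracy_report()] (optionally
#'   with an extra `model` column when several variants are bound together).
#' @return character vector of lines, in the "accuracy% (n)" table style.
#' @export
format_accuracy_table <- function(report) {
  cell <- ifelse(is.na(report$accuracy), "-- (0)",
                 sprintf("%.1f%% (%d)", 100 * report$accuracy,
                         report$n_kept))
  lead <- if ("model" %in% names(report)) {
    sprintf("%-12s", report$model)
  } else ""
  paste0(lead, sprintf("%-12s tau=%.2f  %s", report$subset, report$tau,
                       cell))
}
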