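#' Run the full deconfounding benchmark on synthetic data
#'
#' End-to-end parameter-recovery experiment: simulate a confounded training
#' archive (site and age skewed towards the positive class), train small
#' ensembles of the three variants side-by-side on identical batch streams,
#' and evaluate (i) label AUROC and accuracy on a confound-balanced test set,
#' (ii) confound-predictability AUROC per variant, and (iii) ensemble
#' consensus confidence on in-distribution versus out-of-distribution
#' samples with threshold-stratified accuracies.
#'
#' The defaults are the study conditions of the package's acceptance
#' experiments: 2,000 training volumes at 32^3 with label-confound
#' association 0.8, a 6,000-datapoint budget, and 3-model ensembles, with a
#' compact network (channels 8/16/32/32, 256 features) sized so the whole
#' run fits in minutes on one CPU.
#'
#' @param n_train,n_test,n_ood sample sizes (training pool; confound-balanced
#'   test set; in-distribution and out-of-distribution uncertainty sets).
#' @param volume_shape volume grid.
#' @param assoc label-confound association of the training pool (the test
#'   pool always uses 0, i.e. confound-balanced).
#' @param budget scheduler datapoint budget per model.
#' @param n_models base learners per variant ensemble.
#' @param variants model variants to train.
#' @param channels,feature_dim,hidden network widths.
#' @param lr_encoder,lr_regressor learning rates.
#' @param ood_shift acquisition-shift magnitude of the OOD regime.
#' @param seed master seed; every stage derives its stream from it.
#' @param verbose print progress.
#' @return list with `label` (per-variant AUROC/accuracy on the balanced
#'   test set), `confounds` (per-variant confound AUROC table),
#'   `uncertainty` (confidence summaries, stratified accuracies and the
#'   coverage curve for the adversarially regressed ensemble), `reports`
#'   (per-variant stratified accuracy reports), the trained `ensembles` and
#'   the `schema`.
#' @export
run_deconfounding_experiment <- function(
    n_train = 2000L, n_test = 400L, n_ood = 500L,
    volume_shape = c(32L, 32L, 32L), assoc = 0.8,
    budget = 6000L, n_models = 3L,
    variants = c("mucran", "baseline", "confounded"),
    channels = c(8L, 16L, 32L, 32L), feature_dim = 256L,
    hidden = c(64L, 32L), lr_encoder = 1e-3, lr_regressor = 2e-3,
    ood_shift = 3, seed = 1L, verbose = FALSE) {

  msg <- function(...) if (verbose) message(sprintf(...))

  sim_train <- simulation_config(
    n_samples = n_train, volume_shape = volume_shape,
    label_confound_assoc = list(site = assoc, age = assoc),
    seed = derive_seed(seed, 11))
  msg("simulating %d training volumes (%s)", n_train,
      paste(volume_shape, collapse = "x"))
  ds_train <- simulate_dataset(sim_train)

  schema <- build_schema(
    ds_train$metadata, "label",
    list("site", list(name = "age", kind = "binned_continuous", n_bins = 4)),
    positive_class = "case")

  sim_test <- sim_train
  sim_test$n_samples <- as.integer(n_test)
  sim_test$label_confound_assoc <- list(site = 0, age = 0)
  sim_test$seed <- derive_seed(seed, 12)
  ds_test <- simulate_dataset(sim_test, split = "test")

  sim_id <- sim_train
  sim_id$n_samples <- as.integer(n_ood)
  sim_id$seed <- derive_seed(seed, 13)
  ds_id <- simulate_dataset(sim_id, split = "test")

  sim_ood <- sim_id
  sim_ood$ood_shift <- ood_shift
  sim_ood$seed <- derive_seed(seed, 14)
  ds_ood <- make_ood_samples(sim_ood, n_ood)

  # identical batch streams (and identical derived member seeds) across
  # variants, so variants differ only in their training objective
  plans <- lapply(seq_len(n_models), function(i) {
    plan_batches(ds_train$metadata, schema,
                 scheduler_config(datapoint_budget = budget,
                                  seed = derive_seed(seed, 20 + i)))
  })
  ensembles <- lapply(variants, function(v) {
    msg("training %d-model '%s' ensemble (budget %d)", n_models, v, budget)
    cfg <- train_config(variant = v, channels = channels,
                        feature_dim = feature_dim, hidden = hidden,
                        lr_encoder = lr_encoder,
                        lr_regressor = lr_regressor,
                        scheduler = scheduler_config(datapoint_budget =
                                                       budget),
                        seed = seed)
    train_ensemble(ds_train, schema, cfg, n_models = n_models, plans = plans)
  })
  names(ensembles) <- variants

  truth_test <- ds_test$metadata$label
  preds_test <- lapply(ensembles, ensemble_predict, newdata = ds_test)
  label <- do.call(rbind, lapply(variants, function(v) {
    p <- preds_test[[v]]
    data.frame(variant = v,
               auroc = auroc(p$averaged[1, ], truth_test == "case"),
               accuracy = mean(p$predicted_label == truth_test))
  }))

  confounds <- do.call(rbind, lapply(variants, function(v) {
    cbind(variant = v,
          confound_predictability(preds_test[[v]],
                                  metadata = ds_test$metadata))
  }))

  reports <- do.call(rbind, lapply(variants, function(v) {
    cbind(model = v,
          stratified_accuracy_report(preds_test[[v]], truth_test,
                                     ds_test$metadata,
                                     seed = derive_seed(seed, 30)))
  }))

  mp <- ensembles[[variants[1]]]
  preds_id <- ensemble_predict(mp, ds_id)
  preds_ood <- ensemble_predict(mp, ds_ood)
  curve <- coverage_accuracy_curve(preds_id, ds_id$metadata$label)
  acc_at <- function(tau) {
    kept <- threshold_in_distribution(preds_id, tau)$kept
    if (length(kept)) {
      mean(preds_id$predicted_label[kept] == ds_id$metadata$label[kept])
    } else NA_real_
  }
  uncertainty <- list(
    mean_confidence_id = mean(preds_id$label_confidence),
    mean_confidence_ood = mean(preds_ood$label_confidence),
    t_p = stats::t.test(preds_ood$label_confidence,
                        preds_id$label_confidence,
                        alternative = "less")$p.value,
    accuracy_tau_05 = acc_at(0.5),
    accuracy_tau_09 = acc_at(0.9),
    kept_tau_09 = length(threshold_in_distribution(preds_id, 0.9)$kept),
    curve = curve)

  list(label = label, confounds = confounds, reports = reports,
       uncertainty = uncertainty, ensembles = ensembles, schema = schema,
       test_metadata = ds_test$metadata, preds_test = preds_test,
       seed = seed)
}
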