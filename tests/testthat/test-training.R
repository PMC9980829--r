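make_batch <- function(ds, sch, idx = seq_len(8)) {
  list(x = ds$volumes[, idx, drop = FALSE],
       targets_true = mucran:::encode_targets_matrix(ds$metadata, sch)[, idx],
       targets_adv = mucran:::encode_targets_matrix(ds$metadata, sch,
                                                    adversarial = TRUE)[, idx])
}

test_that("freezing is airtight in the two-step adversarial update", {
  ds <- tiny_dataset(n = 16, seed = 61)
  sch <- tiny_schema(ds$metadata)
  cfg <- tiny_train_config("mucran", seed = 61)
  enc <- build_encoder(ds$shape, channels = cfg$channels,
                       feature_dim = cfg$feature_dim, seed = 1)
  reg <- build_regressor(sch, feature_dim = cfg$feature_dim,
                         hidden = cfg$hidden, seed = 2)
  batch <- make_batch(ds, sch)
  # with the regressor's own update disabled, a full step must leave its
  # parameters bit-identical: step 1 cannot leak into the frozen component
  cfg0 <- cfg
  cfg0$lr_regressor <- 0
  st <- train_step(enc, reg, batch, cfg0)
  expect_identical(st$regressor$params, reg$params)
  expect_false(identical(st$encoder$params$conv[[1]]$W,
                         enc$params$conv[[1]]$W))
  # symmetric: with the encoder update disabled, encoder weights are fixed
  cfg1 <- cfg
  cfg1$lr_encoder <- 0
  st2 <- train_step(enc, reg, batch, cfg1)
  expect_identical(st2$encoder$params$conv[[1]]$W, enc$params$conv[[1]]$W)
  expect_identical(st2$encoder$params$dense[[2]]$W,
                   enc$params$dense[[2]]$W)
  expect_false(identical(st2$regressor$params, reg$params))
})

test_that("the loss on a fixed batch decreases for every variant", {
  ds <- tiny_dataset(n = 8, seed = 62)
  sch <- tiny_schema(ds$metadata)
  batch <- make_batch(ds, sch)
  for (v in c("mucran", "baseline", "confounded")) {
    cfg <- tiny_train_config(v, seed = 62)
    cfg$lr_encoder <- 1e-3
    cfg$lr_regressor <- 5e-3
    enc <- build_encoder(ds$shape, channels = cfg$channels,
                         feature_dim = cfg$feature_dim, seed = 3)
    reg <- build_regressor(sch, feature_dim = cfg$feature_dim,
                           hidden = cfg$hidden, seed = 4)
    state <- NULL
    losses <- numeric(50)
    for (i in 1:50) {
      st <- train_step(enc, reg, batch, cfg, state)
      enc <- st$encoder; reg <- st$regressor; state <- st$state
      losses[i] <- if (v == "mucran") st$reg_loss else st$enc_loss
    }
    expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
  }
})

test_that("confounded and baseline differ only in their targets", {
  ds <- tiny_dataset(n = 8, seed = 63)
  sch <- tiny_schema(ds$metadata)
  batch <- make_batch(ds, sch)
  # with no confounds in the schema the adversarial and true targets
  # coincide, so the two single-loss variants take identical steps
  sch0 <- build_schema(ds$metadata, "label", list(),
                       positive_class = "case")
  b0 <- list(x = batch$x,
             targets_true = mucran:::encode_targets_matrix(ds$metadata,
                                                           sch0)[, 1:8],
             targets_adv = mucran:::encode_targets_matrix(
               ds$metadata, sch0, adversarial = TRUE)[, 1:8])
  expect_identical(b0$targets_true, b0$targets_adv)
  enc <- build_encoder(ds$shape, channels = c(2, 4, 4, 4), feature_dim = 16,
                       seed = 5)
  reg0 <- build_regressor(sch0, feature_dim = 16, hidden = c(12, 8),
                          seed = 6)
  s_conf <- train_step(enc, reg0, b0, tiny_train_config("confounded"))
  s_base <- train_step(enc, reg0, b0, tiny_train_config("baseline"))
  expect_identical(s_conf$encoder$params, s_base$encoder$params)
  expect_identical(s_conf$regressor$params, s_base$regressor$params)
  expect_identical(s_conf$enc_loss, s_base$enc_loss)
  # and the two loss functions agree record-wise when K = 0
  mask <- mucran:::schema_mask(sch0)
  p <- structure(list(values = matrix(c(0.7, 0.3), 1, 2), mask = mask,
                      schema = sch0), class = "prediction_array")
  expect_identical(encoder_loss(p, ds$metadata[1, ], sch0),
                   regressor_loss(p, ds$metadata[1, ], sch0))
})

test_that("training runs are exactly reproducible given the seed", {
  ds <- tiny_dataset(n = 24, seed = 64)
  sch <- tiny_schema(ds$metadata)
  cfg <- tiny_train_config("mucran", budget = 32, seed = 64)
  m1 <- train_model(ds, sch, cfg)
  m2 <- train_model(ds, sch, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$encoder$params, m2$encoder$params)
  expect_identical(predict(m1, ds), predict(m2, ds))
  cfg2 <- cfg
  cfg2$seed <- 65L
  expect_false(identical(train_model(ds, sch, cfg2)$trace, m1$trace))
})

test_that("ensembles are independent and honor shared plans", {
  ds <- tiny_dataset(n = 24, seed = 66)
  sch <- tiny_schema(ds$metadata)
  cfg <- tiny_train_config("mucran", budget = 16, seed = 66)
  ens <- train_ensemble(ds, sch, cfg, n_models = 2)
  expect_length(ens$models, 2)
  expect_false(identical(ens$models[[1]]$encoder$params,
                         ens$models[[2]]$encoder$params))
  expect_warning(train_ensemble(ds, sch, cfg, n_models = 1),
                 "single-model")
  # side-by-side variants consume the same plan object
  plans <- lapply(1:2, function(i) {
    plan_batches(ds$metadata, sch,
                 scheduler_config(chunk_size = 8, datapoint_budget = 16,
                                  seed = i))
  })
  e1 <- train_ensemble(ds, sch, cfg, n_models = 2, plans = plans)
  cfg$variant <- "confounded"
  e2 <- train_ensemble(ds, sch, cfg, n_models = 2, plans = plans)
  expect_identical(e1$models[[2]]$trace$chunk, e2$models[[2]]$trace$chunk)
  expect_error(train_model(subset_dataset(ds, ds$metadata$label == "case"),
                           sch, cfg),
               class = "mucran_scheduler_error")
})
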