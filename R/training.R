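# Two-step adversarial training and the three model variants.
#
# Per batch, the adversarially regressed variant ("mucran") performs:
#   Step 1 - with the regressor frozen, the encoder is fit against the
#            adversarial targets (true label row, constant confound rows),
#            so its features stop carrying confound information;
#   Step 2 - with the encoder fixed, the regressor is fit against the true
#            targets, so it keeps trying to recover the confounds.
# The "confounded" variant fits both components against the true targets
# (label + confounds predicted directly); the "baseline" variant fits both
# against the adversarial targets, making it a plain label classifier.
# The encoder uses Adam, the regressor plain SGD, following GAN practice;
# gradients are clipped by global norm as an adversarial-training stabilizer.

#' Training configuration
#'
#' @param variant one of `"mucran"`, `"baseline"`, `"confounded"`.
#' @param weights a [loss_weights()] object (label-row weight W, log clip).
#' @param lr_encoder Adam learning rate for the encoder.
#' @param lr_regressor SGD learning rate for the regressor.
#' @param adam_beta1 Adam first-moment decay for the encoder; 0.5 following
#'   GAN training conventions (adversarial objectives are non-stationary, so
#'   a short momentum horizon stabilizes the two-player dynamics).
#' @param sgd_momentum classical momentum for the regressor's SGD.
#' @param lr_decay final learning-rate fraction reached by linear decay over
#'   the training run (1 = constant rates).  Annealing both players damps
#'   the oscillation inherent in adversarial objectives so the run ends near
#'   a stable point instead of mid-cycle.
#' @param clip_norm global gradient-norm clip.
#' @param scheduler a [scheduler_config()].
#' @param channels,feature_dim,hidden network widths passed to
#'   [build_encoder()] / [build_regressor()].
#' @param seed master seed; initialization, batch plans and shuffles derive
#'   from it, so a run is fully reproducible.
#' @return A `train_config` list.
#' @export
train_config <- function(variant = c("mucran", "baseline", "confounded"),
                         weights = loss_weights(),
                         lr_encoder = 1e-3, lr_regressor = 2e-3,
                         adam_beta1 = 0.5, sgd_momentum = 0.9,
                         lr_decay = 0.1, clip_norm = 5,
                         scheduler = scheduler_config(),
                         channels = c(16L, 32L, 64L, 128L),
                         feature_dim = 1024L, hidden = c(256L, 128L),
                         seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(lr_encoder > 0, lr_regressor > 0, clip_norm > 0)
  structure(list(variant = variant, weights = weights,
                 lr_encoder = lr_encoder, lr_regressor = lr_regressor,
                 adam_beta1 = adam_beta1, sgd_momentum = sgd_momentum,
                 lr_decay = lr_decay,
                 clip_norm = clip_norm, scheduler = scheduler,
                 channels = as.integer(channels),
                 feature_dim = as.integer(feature_dim),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "train_config")
}

# --- flat parameter/gradient views ----------------------------------------

enc_param_list <- function(enc) {
  out <- list()
  for (l in 1:4) {
    for (nm in c("W", "b", "gamma", "beta")) {
      out[[sprintf("conv%d.%s", l, nm)]] <- enc$params$conv[[l]][[nm]]
    }
  }
  for (nm in c("W", "b", "gamma", "beta")) {
    out[[paste0("d1.", nm)]] <- enc$params$dense[[1]][[nm]]
  }
  out[["d2.W"]] <- enc$params$dense[[2]]$W
  out[["d2.b"]] <- enc$params$dense[[2]]$b
  out
}

enc_set_params <- function(enc, p) {
  for (l in 1:4) {
    for (nm in c("W", "b", "gamma", "beta")) {
      enc$params$conv[[l]][[nm]] <- p[[sprintf("conv%d.%s", l, nm)]]
    }
  }
  for (nm in c("W", "b", "gamma", "beta")) {
    enc$params$dense[[1]][[nm]] <- p[[paste0("d1.", nm)]]
  }
  enc$params$dense[[2]]$W <- p[["d2.W"]]
  enc$params$dense[[2]]$b <- p[["d2.b"]]
  enc
}

enc_grad_list <- function(g) {
  out <- list()
  for (l in 1:4) {
    out[[sprintf("conv%d.W", l)]] <- g$conv_dW[[l]]
    out[[sprintf("conv%d.b", l)]] <- g$conv_db[[l]]
    out[[sprintf("conv%d.gamma", l)]] <- g$conv_dgamma[[l]]
    out[[sprintf("conv%d.beta", l)]] <- g$conv_dbeta[[l]]
  }
  out[["d1.W"]] <- g$d1_dW
  out[["d1.b"]] <- g$d1_db
  out[["d1.gamma"]] <- g$d1_dgamma
  out[["d1.beta"]] <- g$d1_dbeta
  out[["d2.W"]] <- g$d2_dW
  out[["d2.b"]] <- g$d2_db
  out
}

reg_param_list <- function(reg) {
  out <- list()
  for (l in 1:3) {
    out[[sprintf("r%d.W", l)]] <- reg$params[[l]]$W
    out[[sprintf("r%d.b", l)]] <- reg$params[[l]]$b
  }
  out
}

reg_set_params <- function(reg, p) {
  for (l in 1:3) {
    reg$params[[l]]$W <- p[[sprintf("r%d.W", l)]]
    reg$params[[l]]$b <- p[[sprintf("r%d.b", l)]]
  }
  reg
}

reg_grad_list <- function(grads) {
  out <- list()
  for (l in 1:3) {
    out[[sprintf("r%d.W", l)]] <- grads[[l]]$W
    out[[sprintf("r%d.b", l)]] <- grads[[l]]$b
  }
  out
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (!is.finite(total)) {
    stop_mucran("non-finite gradients encountered (global norm = ", total,
                ")", class = "mucran_numeric_error")
  }
  if (total > max_norm) grads <- lapply(grads, function(g) g * max_norm / total)
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

sgd_init <- function(params) {
  list(v = lapply(params, function(p) p * 0))
}

sgd_update <- function(params, grads, state, lr, momentum = 0.9) {
  for (nm in names(params)) {
    state$v[[nm]] <- momentum * state$v[[nm]] + grads[[nm]]
    params[[nm]] <- params[[nm]] - lr * state$v[[nm]]
  }
  list(params = params, state = state)
}

# --- single adversarial step ----------------------------------------------

#' One training step on a batch
#'
#' @param encoder,regressor current networks.
#' @param batch list with `x` (volumes, `voxels x B` matrix),
#'   `targets_true` and `targets_adv` (both `out_dim x B` one-hot matrices,
#'   see [encode_true_targets()] / [encode_adversarial_targets()]).
#' @param config a [train_config()]; `config$variant` selects the update
#'   rule.
#' @param state optimizer state from the previous step (`NULL` on the first
#'   call).
#' @return list with updated `encoder`, `regressor`, `state`, and the scalar
#'   `enc_loss` / `reg_loss` of this step.
#' @export
train_step <- function(encoder, regressor, batch, config, state = NULL) {
  stopifnot(ncol(batch$x) >= 1)
  if (is.null(state)) {
    state <- list(adam = adam_init(enc_param_list(encoder)),
                  sgd = sgd_init(reg_param_list(regressor)))
  }
  layout <- regressor$layout
  w <- config$weights
  beta1 <- config$adam_beta1 %||% 0.5
  mom <- config$sgd_momentum %||% 0.9

  if (config$variant == "mucran") {
    # Step 1: encoder vs adversarial targets, regressor frozen
    ef <- encoder_forward(encoder, batch$x, train = TRUE, want_cache = TRUE)
    encoder <- ef$encoder
    rf <- regressor_forward(regressor, ef$features, want_cache = TRUE)
    l1 <- loss_from_matrices(rf$probs, batch$targets_adv, layout, w,
                             want_grad = TRUE)
    if (!is.finite(l1$loss)) {
      stop_mucran("non-finite encoder loss", class = "mucran_numeric_error")
    }
    rb <- regressor_backward(regressor, rf$cache, l1$d_probs)
    raw <- encoder_backward(ef$cache, rb$d_features)
    cpp_enc_cache_release(ef$cache)
    eg <- clip_global_norm(enc_grad_list(raw), config$clip_norm)
    up <- adam_update(enc_param_list(encoder), eg, state$adam,
                      config$lr_encoder, beta1 = beta1)
    encoder <- enc_set_params(encoder, up$params)
    state$adam <- up$state

    # Step 2: regressor vs true targets, encoder fixed
    ef2 <- encoder_forward(encoder, batch$x, train = TRUE, want_cache = FALSE)
    encoder <- ef2$encoder
    rf2 <- regressor_forward(regressor, ef2$features, want_cache = TRUE)
    l2 <- loss_from_matrices(rf2$probs, batch$targets_true, layout, w,
                             want_grad = TRUE)
    if (!is.finite(l2$loss)) {
      stop_mucran("non-finite regressor loss", class = "mucran_numeric_error")
    }
    rb2 <- regressor_backward(regressor, rf2$cache, l2$d_probs)
    rg <- clip_global_norm(reg_grad_list(rb2$grads), config$clip_norm)
    up2 <- sgd_update(reg_param_list(regressor), rg, state$sgd,
                      config$lr_regressor, momentum = mom)
    regressor <- reg_set_params(regressor, up2$params)
    state$sgd <- up2$state
    enc_loss <- l1$loss
    reg_loss <- l2$loss
  } else {
    targets <- if (config$variant == "confounded") batch$targets_true
               else batch$targets_adv
    ef <- encoder_forward(encoder, batch$x, train = TRUE, want_cache = TRUE)
    encoder <- ef$encoder
    rf <- regressor_forward(regressor, ef$features, want_cache = TRUE)
    ll <- loss_from_matrices(rf$probs, targets, layout, w, want_grad = TRUE)
    if (!is.finite(ll$loss)) {
      stop_mucran("non-finite loss", class = "mucran_numeric_error")
    }
    rb <- regressor_backward(regressor, rf$cache, ll$d_probs)
    raw <- encoder_backward(ef$cache, rb$d_features)
    cpp_enc_cache_release(ef$cache)
    eg <- clip_global_norm(enc_grad_list(raw), config$clip_norm)
    up <- adam_update(enc_param_list(encoder), eg, state$adam,
                      config$lr_encoder, beta1 = beta1)
    encoder <- enc_set_params(encoder, up$params)
    state$adam <- up$state
    rg <- clip_global_norm(reg_grad_list(rb$grads), config$clip_norm)
    up2 <- sgd_update(reg_param_list(regressor), rg, state$sgd,
                      config$lr_regressor, momentum = mom)
    regressor <- reg_set_params(regressor, up2$params)
    state$sgd <- up2$state
    enc_loss <- reg_loss <- ll$loss
  }
  list(encoder = encoder, regressor = regressor, state = state,
       enc_loss = enc_loss, reg_loss = reg_loss)
}

# --- full training run ----------------------------------------------------

#' Train one model on a dataset
#'
#' Consumes the balanced batch stream to the configured datapoint budget.
#' Fully reproducible given `config$seed`; two runs with the same seed
#' produce identical loss traces and parameters.
#'
#' @param dataset a `mucran_dataset` (or list with `volumes`, `shape`,
#'   `metadata`).
#' @param schema a [build_schema()] result describing label and confounds.
#' @param config a [train_config()].
#' @param plan optional precomputed batch-plan list (see [paired_stream()])
#'   so several variants can consume identical streams; defaults to a plan
#'   derived from `config$seed`.
#' @param verbose print a line per chunk.
#' @return A `mucran_model`: list with `encoder`, `regressor`, `schema`,
#'   `config`, `variant` and the per-step loss `trace` data frame.
#' @export
train_model <- function(dataset, schema, config, plan = NULL,
                        verbose = FALSE) {
  lab <- as.character(dataset$metadata[[schema$label_name]])
  if (length(unique(lab)) < 2) {
    stop_mucran("training data must contain both label classes",
                class = "mucran_scheduler_error")
  }
  encoder <- build_encoder(input_shape = dataset$shape,
                           channels = config$channels,
                           feature_dim = config$feature_dim,
                           seed = derive_seed(config$seed, 1))
  regressor <- build_regressor(schema, feature_dim = config$feature_dim,
                               hidden = config$hidden,
                               seed = derive_seed(config$seed, 2))
  sch_cfg <- config$scheduler
  sch_cfg$seed <- derive_seed(config$seed, 3)
  if (is.null(plan)) plan <- plan_batches(dataset$metadata, schema, sch_cfg)

  t_true <- encode_targets_matrix(dataset$metadata, schema)
  t_adv <- encode_targets_matrix(dataset$metadata, schema, adversarial = TRUE)

  state <- NULL
  total_steps <- length(plan) * sch_cfg$iterations_per_chunk
  decay <- config$lr_decay %||% 1
  trace <- vector("list", total_steps)
  ti <- 0L
  with_seed(derive_seed(config$seed, 4), {
    for (pl in plan) {
      rows <- pl$sample_rows
      xs <- dataset$volumes[, rows, drop = FALSE]
      tt <- t_true[, rows, drop = FALSE]
      ta <- t_adv[, rows, drop = FALSE]
      for (it in seq_len(sch_cfg$iterations_per_chunk)) {
        # the presentation order within a full-batch gradient step does not
        # affect the update; drawing it keeps the RNG stream aligned with a
        # mini-batched implementation without paying for the copy
        ord <- sample.int(length(rows))
        scale <- 1 - (1 - decay) * ti / max(total_steps - 1L, 1L)
        cfg_step <- config
        cfg_step$lr_encoder <- config$lr_encoder * scale
        cfg_step$lr_regressor <- config$lr_regressor * scale
        st <- train_step(encoder, regressor,
                         list(x = xs, targets_true = tt, targets_adv = ta),
                         cfg_step, state)
        encoder <- st$encoder
        regressor <- st$regressor
        state <- st$state
        ti <- ti + 1L
        trace[[ti]] <- data.frame(chunk = pl$chunk_index, iteration = it,
                                  enc_loss = st$enc_loss,
                                  reg_loss = st$reg_loss)
      }
      if (verbose) {
        message(sprintf("[%s] chunk %d/%d enc %.4f reg %.4f", config$variant,
                        pl$chunk_index, length(plan), st$enc_loss,
                        st$reg_loss))
      }
    }
  })
  structure(list(encoder = encoder, regressor = regressor, schema = schema,
                 config = config, variant = config$variant,
                 trace = do.call(rbind, trace)),
            class = "mucran_model")
}

#' Predict label/confound probability arrays for new volumes
#'
#' @param object a `mucran_model`.
#' @param newdata a `mucran_dataset` or a `voxels x n` volume matrix.
#' @param batch_size volumes per forward pass.
#' @param ... unused.
#' @return An `out_dim x n` matrix of probabilities (row blocks follow the
#'   schema layout; use [as_prediction_array()] on a column).
#' @export
predict.mucran_model <- function(object, newdata, batch_size = 128L, ...) {
  x <- if (inherits(newdata, "mucran_dataset")) newdata$volumes else newdata
  n <- ncol(x)
  out <- matrix(0, object$regressor$layout$out_dim, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    feats <- encoder_forward(object$encoder, x[, idx, drop = FALSE],
                             train = FALSE)$features
    out[, idx] <- regressor_forward(object$regressor, feats)$probs
  }
  colnames(out) <- colnames(x)
  out
}

#' Train an ensemble of independent base learners
#'
#' Base learners share the architecture and data pool but differ in their
#' derived seeds (initialization and batch stream); no parameters are
#' shared.
#'
#' @param dataset,schema,config as in [train_model()].
#' @param n_models ensemble size (default 10).
#' @param plans optional list of per-member batch-plan lists (for
#'   side-by-side variant training).
#' @param verbose print progress.
#' @return A `mucran_ensemble`: list of `mucran_model`s plus the shared
#'   schema and variant tag.
#' @export
train_ensemble <- function(dataset, schema, config, n_models = 10L,
                           plans = NULL, verbose = FALSE) {
  if (n_models < 2) {
    warning("single-model ensemble: consensus confidence degenerates to ",
            "the model's own softmax confidence")
  }
  models <- lapply(seq_len(n_models), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100 + i)
    train_model(dataset, schema, cfg,
                plan = if (!is.null(plans)) plans[[i]] else NULL,
                verbose = verbose)
  })
  structure(list(models = models, schema = schema,
                 variant = config$variant),
            class = "mucran_ensemble")
}

#' Save / load a trained model or ensemble
#'
#' The checkpoint embeds the schema and training configuration, so a loaded
#' model is self-describing.
#'
#' @param object a `mucran_model` or `mucran_ensemble`.
#' @param path file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("mucran_model", "mucran_ensemble")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("mucran_model", "mucran_ensemble"))) {
    stop_mucran("file does not contain a mucran checkpoint",
                class = "mucran_io_error")
  }
  obj
}
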