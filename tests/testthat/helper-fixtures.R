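# Shared fixtures: tiny datasets, schemas and network configurations sized
# for fast unit tests (16^3 volumes, narrow networks).

tiny_dataset <- function(n = 40, seed = 1, assoc_site = 0, assoc_age = 0,
                         shape = 16, ...) {
  simulate_dataset(simulation_config(
    n_samples = n, volume_shape = rep(shape, 3),
    label_confound_assoc = list(site = assoc_site, age = assoc_age),
    seed = seed, ...))
}

tiny_schema <- function(metadata, n_bins = 2) {
  build_schema(metadata, "label",
               list("site", list(name = "age", kind = "binned_continuous",
                                 n_bins = n_bins)),
               positive_class = "case")
}

tiny_train_config <- function(variant = "mucran", budget = 32,
                              chunk_size = 8, iterations = 2, seed = 1,
                              ...) {
  train_config(variant = variant, channels = c(2L, 4L, 4L, 4L),
               feature_dim = 16L, hidden = c(12L, 8L),
               scheduler = scheduler_config(chunk_size = chunk_size,
                                            iterations_per_chunk = iterations,
                                            datapoint_budget = budget),
               seed = seed, ...)
}

# a stub model whose regressor ignores its input and emits fixed label-row
# probabilities (exact, since the output layer weights are zeroed);
# confound rows become uniform
stub_model <- function(label_probs, schema, shape = 16) {
  enc <- build_encoder(rep(shape, 3), channels = c(2, 4, 4, 4),
                       feature_dim = 16, seed = 1)
  reg <- build_regressor(schema, feature_dim = 16, hidden = c(12, 8),
                         seed = 1)
  reg$params[[3]]$W[] <- 0
  reg$params[[3]]$b[] <- 0
  reg$params[[3]]$b[seq_along(label_probs)] <- log(label_probs)
  structure(list(encoder = enc, regressor = reg, schema = schema,
                 variant = "stub", trace = NULL),
            class = "mucran_model")
}
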