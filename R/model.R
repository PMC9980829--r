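# Encoder and regressor construction.
#
# The encoder maps a volume to a fixed-width intermediary feature vector via
# four 3x3x3 stride-2 convolutions (no pooling: strided convolutions keep
# gradients dense, as do leaky ReLUs) and two fully-connected layers.  Batch
# normalization sits between layers but never after the encoder output nor at
# the regressor input, which adversarial training does not tolerate.  The
# regressor maps features to the padded one-hot prediction array through
# three fully-connected layers and a per-row masked softmax, so every valid
# row is a probability simplex and padded entries are exactly zero.

#' Build the convolutional encoder
#'
#' @param input_shape integer triple; every dimension must be divisible by 16
#'   so the four stride-2 stages halve it exactly (e.g. 96^3 -> 6^3 spatial
#'   grid before flattening, 32^3 -> 2^3).
#' @param channels channel widths of the four convolution blocks.
#' @param feature_dim width of the intermediary feature vector (default
#'   1024).
#' @param leaky_slope leaky ReLU negative slope (default 0.3).
#' @param bn_momentum,bn_eps batch-normalization running-average momentum and
#'   variance floor.
#' @param seed integer; parameter initialization is deterministic given the
#'   seed.
#' @return An object of class `mucran_encoder`.
#' @export
build_encoder <- function(input_shape = c(96L, 96L, 96L),
                          channels = c(16L, 32L, 64L, 128L),
                          feature_dim = 1024L, leaky_slope = 0.3,
                          bn_momentum = 0.9, bn_eps = 1e-4, seed = 1L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape %% 16L != 0L)) {
    stop_mucran("input_shape dimensions must be divisible by 16 ",
                "(four stride-2 convolution stages)",
                class = "mucran_config_error")
  }
  if (length(channels) != 4) {
    stop_mucran("exactly four convolution blocks are required",
                class = "mucran_config_error")
  }
  channels <- as.integer(channels)
  flat_dim <- channels[4] * prod(input_shape %/% 16L)
  params <- with_seed(seed, {
    cin <- 1L
    conv <- vector("list", 4)
    for (l in 1:4) {
      fan_in <- 27L * cin
      conv[[l]] <- list(
        W = matrix(rnorm(channels[l] * fan_in, sd = sqrt(2 / fan_in)),
                   channels[l], fan_in),
        b = numeric(channels[l]),
        gamma = rep(1, channels[l]), beta = numeric(channels[l]),
        run_mean = numeric(channels[l]), run_var = rep(1, channels[l]))
      cin <- channels[l]
    }
    dense <- list(
      list(W = matrix(rnorm(feature_dim * flat_dim, sd = sqrt(2 / flat_dim)),
                      feature_dim, flat_dim),
           b = numeric(feature_dim),
           gamma = rep(1, feature_dim), beta = numeric(feature_dim),
           run_mean = numeric(feature_dim), run_var = rep(1, feature_dim)),
      list(W = matrix(rnorm(feature_dim * feature_dim,
                            sd = sqrt(2 / feature_dim)),
                      feature_dim, feature_dim),
           b = numeric(feature_dim)))
    list(conv = conv, dense = dense)
  })
  structure(list(
    spec = list(input_shape = input_shape, channels = channels,
                feature_dim = as.integer(feature_dim),
                leaky_slope = leaky_slope, bn_momentum = bn_momentum,
                bn_eps = bn_eps, flat_dim = flat_dim,
                activation = "leaky_relu", pooling = "none",
                downsampling = "strided_convolution"),
    params = params, seed = as.integer(seed)),
    class = "mucran_encoder")
}

#' Encoder forward pass
#'
#' @param encoder a [build_encoder()] object.
#' @param x volumes as a `prod(input_shape) x n` matrix (one volume per
#'   column, voxels column-major) or a single 3D array.
#' @param train use batch statistics and update running averages (`TRUE`
#'   during training) or the stored running averages (`FALSE`, inference;
#'   deterministic).
#' @param want_cache keep the intermediate buffers needed for a backward
#'   pass.
#' @return list with `features` (a `feature_dim x n` matrix), `encoder`
#'   (with updated running statistics when `train = TRUE`) and, when
#'   requested, `cache`.
#' @export
encoder_forward <- function(encoder, x, train = FALSE, want_cache = FALSE) {
  if (is.array(x) && length(dim(x)) == 3) x <- matrix(as.numeric(x), ncol = 1)
  sp <- encoder$spec
  stopifnot(nrow(x) == prod(sp$input_shape))
  out <- cpp_enc_forward(x, encoder$params, sp$input_shape, sp$channels,
                         sp$feature_dim, train, sp$bn_momentum, sp$bn_eps,
                         sp$leaky_slope, want_cache)
  if (train) {
    for (l in 1:4) {
      encoder$params$conv[[l]]$run_mean <- out$run_mean[[l]]
      encoder$params$conv[[l]]$run_var <- out$run_var[[l]]
    }
    encoder$params$dense[[1]]$run_mean <- out$run_mean[[5]]
    encoder$params$dense[[1]]$run_var <- out$run_var[[5]]
  }
  list(features = out$features, encoder = encoder,
       cache = out$cache %||% NULL)
}

encoder_backward <- function(cache, d_features) {
  cpp_enc_backward(cache, d_features)
}

# ---------------------------------------------------------------------------

# output-array layout shared by the regressor head and the losses
schema_layout <- function(schema) {
  widths <- schema_row_widths(schema)
  W <- schema$row_width
  rows <- lapply(seq_along(widths), function(r) {
    (r - 1L) * W + seq_len(widths[r])
  })
  mask <- numeric(length(widths) * W)
  for (r in seq_along(rows)) mask[rows[[r]]] <- 1
  list(out_dim = length(widths) * W, n_rows = length(widths),
       widths = widths, row_idx = rows, mask_vec = mask,
       row_names = schema_row_names(schema))
}

#' Build the regressor head
#'
#' @param schema a [build_schema()] result; fixes the output-array geometry.
#' @param feature_dim width of the incoming feature vector (must match the
#'   encoder).
#' @param hidden widths of the two hidden fully-connected layers (the third
#'   layer is the output).
#' @param leaky_slope leaky ReLU negative slope.
#' @param seed integer initialization seed.
#' @return An object of class `mucran_regressor`.
#' @export
build_regressor <- function(schema, feature_dim = 1024L,
                            hidden = c(256L, 128L), leaky_slope = 0.3,
                            seed = 1L) {
  stopifnot(inherits(schema, "confound_schema"), length(hidden) == 2)
  layout <- schema_layout(schema)
  dims <- c(as.integer(feature_dim), as.integer(hidden), layout$out_dim)
  params <- with_seed(seed, {
    lapply(1:3, function(l) {
      list(W = matrix(rnorm(dims[l + 1] * dims[l], sd = sqrt(2 / dims[l])),
                      dims[l + 1], dims[l]),
           b = numeric(dims[l + 1]))
    })
  })
  structure(list(spec = list(feature_dim = as.integer(feature_dim),
                             hidden = as.integer(hidden),
                             leaky_slope = leaky_slope,
                             activation = "leaky_relu",
                             batch_norm = "none"),
                 schema = schema, layout = layout, params = params,
                 seed = as.integer(seed)),
            class = "mucran_regressor")
}

lrelu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

masked_softmax <- function(z, layout) {
  p <- matrix(0, nrow(z), ncol(z))
  for (idx in layout$row_idx) {
    s <- z[idx, , drop = FALSE]
    s <- exp(sweep(s, 2, apply(s, 2, max), `-`))
    p[idx, ] <- sweep(s, 2, colSums(s), `/`)
  }
  p
}

#' Regressor forward pass
#'
#' @param regressor a [build_regressor()] object.
#' @param features `feature_dim x n` matrix.
#' @param want_cache keep buffers for a backward pass.
#' @return list with `probs` (an `out_dim x n` matrix of per-row simplices;
#'   padded entries exactly 0) and optionally `cache`.
#' @export
regressor_forward <- function(regressor, features, want_cache = FALSE) {
  pr <- regressor$params
  sl <- regressor$spec$leaky_slope
  a1 <- lrelu(pr[[1]]$W %*% features + pr[[1]]$b, sl)
  a2 <- lrelu(pr[[2]]$W %*% a1 + pr[[2]]$b, sl)
  z3 <- pr[[3]]$W %*% a2 + pr[[3]]$b
  p <- masked_softmax(z3, regressor$layout)
  out <- list(probs = p)
  if (want_cache) out$cache <- list(a0 = features, a1 = a1, a2 = a2, p = p)
  out
}

# Backward pass given the gradient of the loss w.r.t. the output
# probabilities; returns parameter gradients and the feature gradient.
regressor_backward <- function(regressor, cache, d_probs) {
  pr <- regressor$params
  sl <- regressor$spec$leaky_slope
  p <- cache$p
  dz3 <- matrix(0, nrow(p), ncol(p))
  for (idx in regressor$layout$row_idx) {
    gp <- d_probs[idx, , drop = FALSE]
    pp <- p[idx, , drop = FALSE]
    dz3[idx, ] <- pp * sweep(gp, 2, colSums(gp * pp), `-`)
  }
  g3 <- list(W = tcrossprod(dz3, cache$a2), b = rowSums(dz3))
  da2 <- crossprod(pr[[3]]$W, dz3)
  dz2 <- da2 * ifelse(cache$a2 > 0, 1, sl)
  g2 <- list(W = tcrossprod(dz2, cache$a1), b = rowSums(dz2))
  da1 <- crossprod(pr[[2]]$W, dz2)
  dz1 <- da1 * ifelse(cache$a1 > 0, 1, sl)
  g1 <- list(W = tcrossprod(dz1, cache$a0), b = rowSums(dz1))
  d_features <- crossprod(pr[[1]]$W, dz1)
  list(grads = list(g1, g2, g3), d_features = d_features)
}

#' Convert one prediction-matrix column to a prediction array
#'
#' @param p numeric vector of length `(K+1) * row_width` (one column of the
#'   matrix returned by [predict.mucran_model()]).
#' @param schema the schema that defines the geometry.
#' @return list with `values` (`(K+1) x row_width` matrix, each valid row a
#'   probability simplex) and `mask`.
#' @export
as_prediction_array <- function(p, schema) {
  mask <- schema_mask(schema)
  values <- matrix(p, nrow(mask), ncol(mask), byrow = TRUE,
                   dimnames = dimnames(mask))
  structure(list(values = values, mask = mask, schema = schema),
            class = "prediction_array")
}

#' @export
print.mucran_encoder <- function(x, ...) {
  cat("mucran encoder: input ", paste(x$spec$input_shape, collapse = "x"),
      ", channels ", paste(x$spec$channels, collapse = "/"),
      ", features ", x$spec$feature_dim, "\n", sep = "")
  invisible(x)
}

#' @export
print.mucran_regressor <- function(x, ...) {
  cat("mucran regressor: ", x$spec$feature_dim, " features -> ",
      paste(x$spec$hidden, collapse = "/"), " -> ",
      x$layout$n_rows, " x ", x$schema$row_width, " output array\n",
      sep = "")
  invisible(x)
}
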