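#' Configuration for the confounded phantom simulator
#'
#' The simulator emulates the structure of a heterogeneous clinical MRI
#' archive at desk scale: a binary disease label carried by a focal
#' morphological signal, plus confounding factors that are statistically
#' associated with the label to a controllable degree and carried by
#' spatially/statistically distinct signals, so that label and confounds are
#' separable in principle:
#'
#' * label ("case" vs "control"): the radius of a centered dark
#'   ventricle-like ellipsoid is enlarged in cases;
#' * `site` (categorical, 2 scanners): a global affine intensity transform
#'   (gain and offset differ per site);
#' * `age` (continuous, years): acquisition smoothness — a Gaussian blur
#'   whose width grows with age.
#'
#' The association parameters skew the confound's conditional distribution
#' given the label: at 0 the confound is independent of the label, at 1 it is
#' deterministic (e.g. every case comes from the older regime).  An
#' out-of-distribution regime shifts the global intensity scale/offset and
#' the noise level, emulating data from an unseen acquisition protocol, while
#' keeping the label mechanism intact.
#'
#' All randomness flows from `seed` through a per-sample counter-based
#' stream, so any subset of samples is reproducible independently of
#' generation order.
#'
#' @param n_samples number of volumes.
#' @param volume_shape integer triple; each dim must be divisible by 16
#'   (four stride-2 convolution stages).  Default `c(32, 32, 32)`.
#' @param label_effect size of the case/control ventricle-radius difference
#'   (unitless multiple of the default effect; 0 removes the label signal).
#' @param confound_effects named list with elements `site` and `age` scaling
#'   the two confound signals (0 removes the signal).
#' @param label_confound_assoc named list with elements `site` and `age` in
#'   \[0, 1\]: probability skew linking the confound to the label.
#' @param noise_sd additive Gaussian voxel noise (intensity units, brain
#'   tissue has intensity 1).
#' @param ood_shift magnitude of the out-of-distribution acquisition shift
#'   used by [make_ood_samples()].
#' @param prevalence probability that a sample is a case.
#' @param seed integer master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 100,
                              volume_shape = c(32L, 32L, 32L),
                              label_effect = 1,
                              confound_effects = list(site = 1, age = 1.5),
                              label_confound_assoc = list(site = 0, age = 0),
                              noise_sd = 0.1,
                              ood_shift = 0,
                              prevalence = 0.5,
                              seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape <= 0)) {
    stop_mucran("volume_shape must be a positive integer triple",
                class = "mucran_config_error")
  }
  assoc <- unlist(label_confound_assoc)
  if (any(assoc < 0 | assoc > 1)) {
    stop_mucran("label_confound_assoc values must lie in [0, 1]",
                class = "mucran_config_error")
  }
  stopifnot(n_samples >= 1, noise_sd > 0, ood_shift >= 0,
            prevalence > 0, prevalence < 1, label_effect >= 0,
            all(unlist(confound_effects) >= 0))
  structure(list(n_samples = as.integer(n_samples),
                 volume_shape = volume_shape,
                 label_effect = label_effect,
                 confound_effects = confound_effects,
                 label_confound_assoc = label_confound_assoc,
                 noise_sd = noise_sd, ood_shift = ood_shift,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw the metadata for sample i from its private RNG stream.  The volume
# noise uses the same stream, *after* these draws, so simulate_metadata()
# and simulate_dataset() agree exactly on the metadata.
draw_record <- function(config, i, ood = FALSE) {
  prefix <- if (ood) "O" else "S"
  offset <- if (ood) 1000000L else 0L
  with_seed(derive_seed(config$seed, i + offset), {
    case <- runif(1) < config$prevalence
    a_site <- config$label_confound_assoc$site %||% 0
    a_age <- config$label_confound_assoc$age %||% 0
    # aligned category: cases tend to site B / the older regime
    p_b <- if (case) 0.5 + a_site / 2 else 0.5 - a_site / 2
    site <- if (runif(1) < p_b) "siteB" else "siteA"
    p_old <- if (case) 0.5 + a_age / 2 else 0.5 - a_age / 2
    age <- if (runif(1) < p_old) runif(1, 75, 95) else runif(1, 55, 75)
    list(sample_id = sprintf("%s%05d", prefix, i),
         label = if (case) "case" else "control",
         site = site, age = age,
         jitter = rnorm(1),
         noise_state = get(".Random.seed", envir = globalenv()))
  })
}

#' Generate sample metadata only
#'
#' Returns the metadata table [simulate_dataset()] would produce, without
#' synthesizing the volumes (useful for scheduler and association tests at
#' large n).
#'
#' @param config a [simulation_config()].
#' @param split split tag recorded for all rows (default `"train"`).
#' @return data frame with columns `sample_id`, `label`, `site`, `age`,
#'   `split`, `acquisition_epoch`.
#' @export
simulate_metadata <- function(config, split = "train") {
  recs <- lapply(seq_len(config$n_samples), function(i) {
    r <- draw_record(config, i)
    data.frame(sample_id = r$sample_id, label = r$label, site = r$site,
               age = r$age, stringsAsFactors = FALSE)
  })
  md <- do.call(rbind, recs)
  md$split <- split
  md$acquisition_epoch <- "standard"
  md
}

# squared-distance grid from the volume center, in voxel units
dist2_grid <- function(shape) {
  ctr <- (shape + 1) / 2
  gx <- (seq_len(shape[1]) - ctr[1])^2
  gy <- (seq_len(shape[2]) - ctr[2])^2
  gz <- (seq_len(shape[3]) - ctr[3])^2
  outer(outer(gx, gy, `+`), gz, `+`)
}

render_volume <- function(config, rec, d2, ood = FALSE) {
  shape <- config$volume_shape
  scale <- min(shape)
  eff_site <- config$confound_effects$site %||% 0
  eff_age <- config$confound_effects$age %||% 0

  brain_r <- 0.40 * scale
  vent_r <- (0.10 + 0.035 * config$label_effect *
               (rec$label == "case")) * scale + 0.015 * scale * rec$jitter
  vent_r <- max(vent_r, 1)

  vol <- ifelse(d2 <= brain_r^2, 1.0, 0.05)
  vol[d2 <= vent_r^2] <- 0.25

  noise_sd <- config$noise_sd
  gain <- 1 + 0.1 * eff_site * (if (rec$site == "siteB") 1 else -1)
  offs <- 0.05 * eff_site * (if (rec$site == "siteB") 1 else -1)
  if (ood) {
    # shifted acquisition protocol: different receiver gain and baseline,
    # and markedly different noise level.  The noise term dominates so that
    # the shift degrades information rather than pushing every volume in one
    # systematic intensity direction.
    s <- config$ood_shift
    gain <- gain * (1 + 0.15 * s)
    offs <- offs + 0.1 * s
    noise_sd <- noise_sd * (1 + 2 * s)
  }

  # resume the sample's RNG stream where the metadata draws stopped
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", rec$noise_state, envir = globalenv())
  noise <- rnorm(length(vol), sd = noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  vol <- vol + noise
  sigma <- eff_age * (rec$age - 55) / 40
  if (sigma > 0) {
    vol <- cpp_gauss_blur3d(as.numeric(vol), shape, sigma)
  }
  gain * as.numeric(vol) + offs
}

#' Simulate a confounded volumetric dataset
#'
#' @param config a [simulation_config()].
#' @param split split tag for the metadata (default `"train"`).
#' @return A `mucran_dataset`: list with `volumes` (a `prod(shape) x n`
#'   matrix, one volume per column, voxels in column-major order), `shape`,
#'   `metadata` and `config`.  Use [get_sample()] to extract one sample as a
#'   3D array plus its record.
#' @export
simulate_dataset <- function(config, split = "train") {
  shape <- config$volume_shape
  d2 <- dist2_grid(shape)
  vols <- matrix(0, prod(shape), config$n_samples)
  recs <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    rec <- draw_record(config, i)
    vols[, i] <- render_volume(config, rec, d2)
    recs[[i]] <- rec
  }
  md <- do.call(rbind, lapply(recs, function(r) {
    data.frame(sample_id = r$sample_id, label = r$label, site = r$site,
               age = r$age, stringsAsFactors = FALSE)
  }))
  md$split <- split
  md$acquisition_epoch <- "standard"
  colnames(vols) <- md$sample_id
  structure(list(volumes = vols, shape = shape, metadata = md,
                 config = config),
            class = "mucran_dataset")
}

#' Draw out-of-distribution samples
#'
#' Samples share the in-distribution label mechanism but are acquired under a
#' shifted protocol: global intensity gain/offset and voxel noise scale with
#' `config$ood_shift`.  With `ood_shift = 0` the generator coincides with the
#' in-distribution one.
#'
#' @param config a [simulation_config()]; `ood_shift` sets the magnitude.
#' @param n number of samples (must be positive).
#' @return A `mucran_dataset` whose metadata has
#'   `acquisition_epoch = "shifted"`.
#' @export
make_ood_samples <- function(config, n) {
  if (n <= 0) {
    stop_mucran("n must be positive", class = "mucran_config_error")
  }
  shape <- config$volume_shape
  d2 <- dist2_grid(shape)
  vols <- matrix(0, prod(shape), n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- draw_record(config, i, ood = TRUE)
    vols[, i] <- render_volume(config, rec, d2, ood = TRUE)
    recs[[i]] <- rec
  }
  md <- do.call(rbind, lapply(recs, function(r) {
    data.frame(sample_id = r$sample_id, label = r$label, site = r$site,
               age = r$age, stringsAsFactors = FALSE)
  }))
  md$split <- "test"
  md$acquisition_epoch <- "shifted"
  colnames(vols) <- md$sample_id
  structure(list(volumes = vols, shape = shape, metadata = md,
                 config = config),
            class = "mucran_dataset")
}

#' @export
print.mucran_dataset <- function(x, ...) {
  cat("mucran dataset: ", ncol(x$volumes), " volumes of ",
      paste(x$shape, collapse = "x"), "; labels: ",
      paste(sprintf("%s=%d", names(table(x$metadata$label)),
                    table(x$metadata$label)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Extract one sample from a dataset
#'
#' @param dataset a `mucran_dataset`.
#' @param i sample index.
#' @return list with `volume` (3D array) and `record` (one-row data frame).
#' @export
get_sample <- function(dataset, i) {
  list(volume = array(dataset$volumes[, i], dim = dataset$shape),
       record = dataset$metadata[i, , drop = FALSE])
}

#' Subset a dataset by sample index
#'
#' @param dataset a `mucran_dataset`.
#' @param idx integer or logical index into the samples.
#' @return A `mucran_dataset` holding the selected samples.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(volumes = dataset$volumes[, idx, drop = FALSE],
                 shape = dataset$shape,
                 metadata = dataset$metadata[idx, , drop = FALSE],
                 config = dataset$config),
            class = "mucran_dataset")
}
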