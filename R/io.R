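# Volume and metadata I/O.
#
# Volumes live in NIfTI files; all processing uses 0-based voxel-index space
# (no anatomical-orientation handling).  Inputs of any size are resampled to
# the configured cubic grid by trilinear interpolation, the only
# preprocessing the pipeline assumes.

# 1D linear-interpolation weight matrix (n_tgt x n_src), voxel centers
# aligned; exact identity when n_src == n_tgt.
interp_matrix <- function(n_src, n_tgt) {
  s <- (seq_len(n_tgt) - 0.5) * n_src / n_tgt + 0.5
  s <- pmin(pmax(s, 1), n_src)
  lo <- pmin(floor(s), n_src - 1L)
  if (n_src == 1L) lo <- rep(1L, n_tgt)
  w <- s - lo
  m <- matrix(0, n_tgt, n_src)
  m[cbind(seq_len(n_tgt), lo)] <- 1 - w
  m[cbind(seq_len(n_tgt), pmin(lo + 1L, n_src))] <-
    m[cbind(seq_len(n_tgt), pmin(lo + 1L, n_src))] + w
  m
}

#' Resample a 3D volume to a target grid by trilinear interpolation
#'
#' @param volume 3D numeric array.
#' @param shape target integer triple.
#' @return 3D array of dimension `shape`.  A constant volume stays constant;
#'   matching shapes return the input unchanged.
#' @export
resize_volume <- function(volume, shape) {
  shape <- as.integer(shape)
  d <- dim(volume)
  stopifnot(length(d) == 3, length(shape) == 3, all(shape > 0))
  if (identical(d, shape)) return(volume)
  # axis 1
  m1 <- interp_matrix(d[1], shape[1])
  v <- m1 %*% matrix(volume, d[1], d[2] * d[3])
  dim(v) <- c(shape[1], d[2], d[3])
  # axis 2
  m2 <- interp_matrix(d[2], shape[2])
  v <- aperm(v, c(2, 1, 3))
  v <- m2 %*% matrix(v, d[2], shape[1] * d[3])
  dim(v) <- c(shape[2], shape[1], d[3])
  v <- aperm(v, c(2, 1, 3))
  # axis 3
  m3 <- interp_matrix(d[3], shape[3])
  v <- aperm(v, c(3, 1, 2))
  v <- m3 %*% matrix(v, d[3], shape[1] * shape[2])
  dim(v) <- c(shape[3], shape[1], shape[2])
  aperm(v, c(2, 3, 1))
}

#' Load one NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param target_shape optional integer triple; when given, the volume is
#'   resampled to it via [resize_volume()].
#' @return list with `volume` (3D array), `pixdim`, `path` and
#'   `original_shape`.  Unreadable/corrupt files raise a `mucran_io_error`.
#' @export
load_volume <- function(path, target_shape = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop_mucran("unreadable or empty volume file: ", path,
                class = "mucran_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop_mucran("corrupt volume file: ", path, " (", conditionMessage(e),
                ")", class = "mucran_io_error")
  })
  vol <- array(as.numeric(img), dim = dim(img)[1:3])
  orig <- dim(vol)
  if (!is.null(target_shape)) vol <- resize_volume(vol, target_shape)
  list(volume = vol, pixdim = RNifti::pixdim(img), path = path,
       original_shape = orig)
}

#' Load a set of volumes, logging rejects
#'
#' Files that cannot be read (zero-byte, truncated, non-NIfTI) are recorded
#' and skipped; the run continues with the loadable volumes.
#'
#' @param paths NIfTI file paths.
#' @param target_shape cubic grid all volumes are resampled to.
#' @return list with `volumes` (`prod(target_shape) x n_ok` matrix),
#'   `paths` of the loaded files, and a `rejected` data frame
#'   (`path`, `reason`).
#' @export
load_volumes <- function(paths, target_shape) {
  ok <- list()
  ok_paths <- character()
  rej <- list()
  for (p in paths) {
    res <- tryCatch(load_volume(p, target_shape), mucran_io_error =
                      function(e) e)
    if (inherits(res, "mucran_io_error")) {
      rej[[length(rej) + 1L]] <- data.frame(path = p,
                                            reason = conditionMessage(res))
    } else {
      ok[[length(ok) + 1L]] <- as.numeric(res$volume)
      ok_paths <- c(ok_paths, p)
    }
  }
  list(volumes = if (length(ok)) do.call(cbind, ok)
                 else matrix(0, prod(target_shape), 0),
       paths = ok_paths,
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(path = character(), reason = character()))
}

#' Write one volume as NIfTI
#'
#' @param volume 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Per-volume intensity standardization
#'
#' Centers and scales a volume to zero mean / unit variance.  Note that this
#' removes global affine intensity information (e.g. scanner gain/offset
#' differences), so it is an option, not a mandatory pipeline step.
#'
#' @param volume numeric array or vector.
#' @return standardized volume of the same shape.
#' @export
normalize_volume <- function(volume) {
  s <- stats::sd(volume)
  if (!is.finite(s) || s == 0) return(volume * 0)
  (volume - mean(volume)) / s
}

#' Write / read a dataset as NIfTI volumes plus a metadata CSV
#'
#' @param dataset a `mucran_dataset`.
#' @param dir output directory (created if missing); volumes are stored as
#'   `<sample_id>.nii.gz` next to `metadata.csv`.
#' @return `dir` (write) or a `mucran_dataset` (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(ncol(dataset$volumes))) {
    save_volume(array(dataset$volumes[, i], dim = dataset$shape),
                file.path(dir, paste0(dataset$metadata$sample_id[i],
                                      ".nii.gz")))
  }
  write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param target_shape grid to resample volumes to on read; defaults to the
#'   stored shape.
#' @export
read_dataset <- function(dir, target_shape = NULL) {
  md <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  paths <- file.path(dir, paste0(md$sample_id, ".nii.gz"))
  first <- load_volume(paths[1])
  target_shape <- as.integer(target_shape %||% dim(first$volume))
  lv <- load_volumes(paths, target_shape)
  keep <- match(lv$paths, paths)
  vols <- lv$volumes
  colnames(vols) <- md$sample_id[keep]
  structure(list(volumes = vols, shape = target_shape,
                 metadata = md[keep, , drop = FALSE], config = NULL),
            class = "mucran_dataset")
}
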