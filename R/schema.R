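#' Build a label/confound schema from a metadata table
#'
#' A schema fixes the geometry of the network's output array: one row for the
#' classification label and one row per confounding factor, each row a one-hot
#' vector over that variable's categories.  Rows of unequal category counts
#' are stored padded to the widest row, with a validity mask.  Continuous
#' confounds (age, scanner settings, ...) are quantile-binned on the training
#' split so every bin holds roughly equal mass.
#'
#' Category order is deterministic given the table: the label's positive
#' class sits at index 1, remaining label categories and categorical confound
#' categories follow first-seen order, bins are ascending.  Missing values
#' get a dedicated `"(missing)"` category so that incomplete clinical records
#' still contribute to training.
#'
#' @param metadata data frame with one row per scan.
#' @param label_col name of the label column.
#' @param confounds list describing the confounds to regress.  Each element is
#'   either a column name (treated as categorical) or a list with entries
#'   `name`, `kind` (`"categorical"` or `"binned_continuous"`) and, for binned
#'   confounds, `n_bins` (default 4).
#' @param positive_class label category to place at index 1.  Defaults to the
#'   first value observed in `label_col`.
#' @param use_train_split if `TRUE` (default) and a `split` column is present,
#'   bin edges and category sets are computed from rows with
#'   `split == "train"` only.
#' @return An object of class `confound_schema`.
#' @examples
#' md <- data.frame(label = c("case", "control"), sex = c("M", "F"),
#'                  age = c(71, 64))
#' sch <- build_schema(md, "label",
#'                     list("sex", list(name = "age",
#'                                      kind = "binned_continuous",
#'                                      n_bins = 2)))
#' sch$row_width
#' @export
build_schema <- function(metadata, label_col, confounds,
                         positive_class = NULL, use_train_split = TRUE) {
  stopifnot(is.data.frame(metadata))
  ref <- metadata
  if (use_train_split && "split" %in% names(metadata) &&
      any(metadata$split == "train")) {
    ref <- metadata[metadata$split == "train", , drop = FALSE]
  }
  if (!label_col %in% names(ref)) {
    stop_mucran("unknown label column '", label_col, "'",
                class = "mucran_config_error")
  }
  lab_vals <- as.character(ref[[label_col]])
  lab_cats <- unique(lab_vals[!is.na(lab_vals)])
  if (length(lab_cats) < 2) {
    stop_mucran("label column '", label_col, "' has fewer than 2 categories",
                class = "mucran_config_error")
  }
  positive_class <- positive_class %||% lab_cats[[1]]
  if (!positive_class %in% lab_cats) {
    stop_mucran("positive class '", positive_class, "' not observed",
                class = "mucran_config_error")
  }
  lab_cats <- c(positive_class, setdiff(lab_cats, positive_class))

  conf <- lapply(confounds, function(cs) {
    if (is.character(cs)) cs <- list(name = cs, kind = "categorical")
    kind <- cs$kind %||% "categorical"
    nm <- cs$name
    if (!nm %in% names(ref)) {
      stop_mucran("unknown confound column '", nm, "'",
                  class = "mucran_config_error")
    }
    x <- ref[[nm]]
    if (kind == "categorical") {
      vals <- as.character(x)
      cats <- unique(vals[!is.na(vals)])
      if (length(cats) < 2) {
        stop_mucran("confound '", nm, "' is single-valued; ",
                    "single-valued confounding factors cannot be regressed",
                    class = "mucran_config_error")
      }
      if (anyNA(x)) cats <- c(cats, "(missing)")
      list(name = nm, kind = "categorical", categories = cats,
           bin_edges = NULL)
    } else if (kind == "binned_continuous") {
      if (!is.numeric(x)) {
        stop_mucran("confound '", nm, "' must be numeric for binning",
                    class = "mucran_config_error")
      }
      if (length(unique(x[!is.na(x)])) < 2) {
        stop_mucran("confound '", nm, "' is single-valued; ",
                    "single-valued confounding factors cannot be regressed",
                    class = "mucran_config_error")
      }
      n_bins <- cs$n_bins %||% 4L
      edges <- unname(quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                               na.rm = TRUE))
      edges <- unique(edges)
      if (!length(edges)) {
        stop_mucran("confound '", nm, "' cannot be split into bins",
                    class = "mucran_config_error")
      }
      cats <- bin_labels(edges)
      if (anyNA(x)) cats <- c(cats, "(missing)")
      list(name = nm, kind = "binned_continuous", categories = cats,
           bin_edges = edges)
    } else {
      stop_mucran("unknown confound kind '", kind, "'",
                  class = "mucran_config_error")
    }
  })
  names(conf) <- vapply(conf, `[[`, "", "name")
  if (anyDuplicated(c(label_col, names(conf)))) {
    stop_mucran("label/confound names must be unique",
                class = "mucran_config_error")
  }

  widths <- c(length(lab_cats),
              vapply(conf, function(cc) length(cc$categories), 0L))
  structure(list(label_name = label_col, label_categories = lab_cats,
                 confounds = conf, row_width = max(widths)),
            class = "confound_schema")
}

bin_labels <- function(edges) {
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  sprintf("(%s,%s]", format(lo, trim = TRUE, digits = 6),
          format(hi, trim = TRUE, digits = 6))
}

#' @export
print.confound_schema <- function(x, ...) {
  cat("confound schema: label '", x$label_name, "' (",
      paste(x$label_categories, collapse = "/"), "), ",
      length(x$confounds), " confound(s), row width ", x$row_width, "\n",
      sep = "")
  for (cc in x$confounds) {
    cat("  - ", cc$name, " [", cc$kind, "]: ",
        paste(cc$categories, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

n_confounds <- function(schema) length(schema$confounds)

schema_row_names <- function(schema) {
  c(schema$label_name, names(schema$confounds))
}

schema_row_widths <- function(schema) {
  c(length(schema$label_categories),
    vapply(schema$confounds, function(cc) length(cc$categories), 0L))
}

# index of the category a value falls into, 1-based; NA -> "(missing)"
category_index <- function(value, categories, bin_edges = NULL) {
  if (is.null(bin_edges)) {
    v <- as.character(value)
    if (is.na(v)) v <- "(missing)"
    i <- match(v, categories)
    if (is.na(i)) {
      stop_mucran("value '", v, "' outside schema categories",
                  class = "mucran_encoding_error")
    }
    i
  } else {
    if (is.na(value)) {
      i <- match("(missing)", categories)
      if (is.na(i)) {
        stop_mucran("missing value but schema has no missing category",
                    class = "mucran_encoding_error")
      }
      return(i)
    }
    findInterval(as.numeric(value), bin_edges) + 1L
  }
}

schema_mask <- function(schema) {
  widths <- schema_row_widths(schema)
  mask <- matrix(0L, length(widths), schema$row_width,
                 dimnames = list(schema_row_names(schema), NULL))
  for (r in seq_along(widths)) mask[r, seq_len(widths[r])] <- 1L
  mask
}

new_target_array <- function(values, mask, schema) {
  structure(list(values = values, mask = mask, schema = schema),
            class = "target_array")
}

#' Encode a metadata record as the true one-hot output array
#'
#' Row 1 holds the label one-hot, rows `1 + k` the one-hot of confound `k`'s
#' observed category (binned for continuous confounds).  Entries outside the
#' validity mask are zero.
#'
#' @param record a one-row data frame or named list holding the label and
#'   confound values.
#' @param schema a [build_schema()] result.
#' @return A `target_array`: list with `(K+1) x row_width` matrices `values`
#'   and `mask`.
#' @export
encode_true_targets <- function(record, schema) {
  mask <- schema_mask(schema)
  values <- matrix(0L, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  values[1, category_index(record[[schema$label_name]],
                           schema$label_categories)] <- 1L
  for (r in seq_along(schema$confounds)) {
    cc <- schema$confounds[[r]]
    values[r + 1, category_index(record[[cc$name]], cc$categories,
                                 cc$bin_edges)] <- 1L
  }
  new_target_array(values, mask, schema)
}

#' Encode a metadata record as the adversarial (confound-erased) output array
#'
#' The label row is the true one-hot; every confound row is replaced by the
#' constant one-hot `[1, 0, ..., 0]` within its mask.  Fitting the encoder
#' against these targets removes confound information from its features while
#' preserving the label.
#'
#' @inheritParams encode_true_targets
#' @return A `target_array`.
#' @export
encode_adversarial_targets <- function(record, schema) {
  mask <- schema_mask(schema)
  values <- matrix(0L, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  values[1, category_index(record[[schema$label_name]],
                           schema$label_categories)] <- 1L
  if (nrow(values) > 1) values[2:nrow(values), 1] <- 1L
  new_target_array(values, mask, schema)
}

# Vectorized encoding used in training: returns an (out_dim x n) 0/1 matrix
# where out_dim = (K+1) * row_width and row block r occupies rows
# ((r-1)*row_width + 1):(r*row_width).
encode_targets_matrix <- function(metadata, schema, adversarial = FALSE) {
  W <- schema$row_width
  rows <- 1L + n_confounds(schema)
  n <- nrow(metadata)
  out <- matrix(0, rows * W, n)
  lab_idx <- match(as.character(metadata[[schema$label_name]]),
                   schema$label_categories)
  if (anyNA(lab_idx)) {
    stop_mucran("label values outside schema", class = "mucran_encoding_error")
  }
  out[cbind(lab_idx, seq_len(n))] <- 1
  for (r in seq_along(schema$confounds)) {
    cc <- schema$confounds[[r]]
    if (adversarial) {
      idx <- rep(1L, n)
    } else if (is.null(cc$bin_edges)) {
      v <- as.character(metadata[[cc$name]])
      v[is.na(v)] <- "(missing)"
      idx <- match(v, cc$categories)
      if (anyNA(idx)) {
        stop_mucran("values of '", cc$name, "' outside schema",
                    class = "mucran_encoding_error")
      }
    } else {
      x <- metadata[[cc$name]]
      idx <- findInterval(x, cc$bin_edges) + 1L
      if (anyNA(x)) idx[is.na(x)] <- match("(missing)", cc$categories)
    }
    out[cbind(r * W + idx, seq_len(n))] <- 1
  }
  out
}

# categories observed for each confound, after binning (factor of schema cats)
confound_categories <- function(metadata, schema, confound) {
  cc <- schema$confounds[[confound]]
  if (is.null(cc)) {
    stop_mucran("unknown confound '", confound, "'",
                class = "mucran_config_error")
  }
  if (is.null(cc$bin_edges)) {
    v <- as.character(metadata[[cc$name]])
    v[is.na(v)] <- "(missing)"
  } else {
    x <- metadata[[cc$name]]
    idx <- findInterval(x, cc$bin_edges) + 1L
    if (anyNA(x)) idx[is.na(x)] <- match("(missing)", cc$categories)
    v <- cc$categories[idx]
  }
  factor(v, levels = cc$categories)
}

#' Serialize / restore a schema as YAML
#'
#' @param schema a `confound_schema`.
#' @param path file to write to / read from.
#' @return `schema_to_yaml` returns `path` invisibly; `schema_from_yaml`
#'   returns a `confound_schema`.
#' @export
schema_to_yaml <- function(schema, path) {
  obj <- unclass(schema)
  obj$confounds <- lapply(obj$confounds, function(cc) {
    cc[!vapply(cc, is.null, TRUE)]
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname schema_to_yaml
#' @export
schema_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$confounds <- lapply(obj$confounds, function(cc) {
    cc$bin_edges <- if (!is.null(cc$bin_edges)) as.numeric(cc$bin_edges)
    cc
  })
  structure(obj, class = "confound_schema")
}
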