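# Balanced batch scheduler.
#
# Training is not performed in epochs.  Each chunk of `chunk_size` volumes is
# built half with equal counts per label class and half with equal counts per
# category of one confound; the balanced confound rotates round-robin across
# chunks in schema order.  Chunks are loaded one at a time and trained on for
# `iterations_per_chunk` gradient steps; the stream ends once
# `datapoint_budget` volumes have been loaded (iteration repeats do not
# consume budget).  Sampling is with replacement across the run, so balance
# is achievable under arbitrary class imbalance.

#' Scheduler configuration
#'
#' @param chunk_size volumes loaded into memory at a time; one chunk is
#'   trained as one batch (default 48).
#' @param iterations_per_chunk gradient steps per loaded chunk (default 5).
#' @param datapoint_budget total volumes loaded over the run (default
#'   33,000; configure down for desk-scale experiments).
#' @param seed integer seed controlling batch composition.
#' @return A `scheduler_config` list.
#' @export
scheduler_config <- function(chunk_size = 48L, iterations_per_chunk = 5L,
                             datapoint_budget = 33000L, seed = 1L) {
  stopifnot(chunk_size >= 2, iterations_per_chunk >= 1, datapoint_budget >= 1)
  structure(list(chunk_size = as.integer(chunk_size),
                 iterations_per_chunk = as.integer(iterations_per_chunk),
                 datapoint_budget = as.integer(datapoint_budget),
                 seed = as.integer(seed)),
            class = "scheduler_config")
}

# split `total` into `k` near-equal integer quotas (pseudo-randomly assigning
# the remainder so no position is systematically favored)
split_quota <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  q <- rep(base, k)
  if (extra > 0) q[sample.int(k, extra)] <- base + 1L
  q
}

#' Plan the balanced batch stream
#'
#' @param metadata metadata table covering the training pool.
#' @param schema a [build_schema()] result; defines label classes and the
#'   confound rotation order.
#' @param config a [scheduler_config()].
#' @return list of `batch_plan` objects.  Each has `sample_ids` (ordered,
#'   length `chunk_size`), `label_half_ids`, `confound_half_ids`,
#'   `balanced_confound` and `chunk_index`.
#' @export
plan_batches <- function(metadata, schema, config = scheduler_config()) {
  lab <- as.character(metadata[[schema$label_name]])
  classes <- schema$label_categories
  pools <- lapply(classes, function(cl) which(lab == cl))
  names(pools) <- classes
  empty <- classes[vapply(pools, length, 0L) == 0]
  if (length(empty)) {
    stop_mucran("no samples available for label class '", empty[1], "'",
                class = "mucran_scheduler_error")
  }
  conf_names <- names(schema$confounds)
  conf_cats <- lapply(conf_names, function(nm) {
    confound_categories(metadata, schema, nm)
  })
  names(conf_cats) <- conf_names

  half <- config$chunk_size %/% 2L
  n_chunks <- ceiling(config$datapoint_budget / config$chunk_size)
  with_seed(config$seed, {
    lapply(seq_len(n_chunks), function(ci) {
      # label half: equal counts per label class (+-1)
      lq <- split_quota(half, length(classes))
      label_ids <- unlist(lapply(seq_along(classes), function(j) {
        pool <- pools[[j]]
        pool[sample.int(length(pool), lq[j], replace = TRUE)]
      }))
      # confound half: equal counts per category with available samples
      other <- config$chunk_size - half
      if (length(conf_names)) {
        cf <- conf_names[(ci - 1L) %% length(conf_names) + 1L]
        cats <- levels(conf_cats[[cf]])
        cat_pools <- lapply(cats, function(cc) which(conf_cats[[cf]] == cc))
        avail <- vapply(cat_pools, length, 0L) > 0
        cq <- integer(length(cats))
        cq[avail] <- split_quota(other, sum(avail))
        conf_ids <- unlist(lapply(which(avail), function(j) {
          pool <- cat_pools[[j]]
          pool[sample.int(length(pool), cq[j], replace = TRUE)]
        }))
      } else {
        cf <- NA_character_
        lq2 <- split_quota(other, length(classes))
        conf_ids <- unlist(lapply(seq_along(classes), function(j) {
          pool <- pools[[j]]
          pool[sample.int(length(pool), lq2[j], replace = TRUE)]
        }))
      }
      ids <- c(label_ids, conf_ids)
      structure(list(sample_ids = metadata$sample_id[ids],
                     sample_rows = ids,
                     label_half_ids = metadata$sample_id[label_ids],
                     confound_half_ids = metadata$sample_id[conf_ids],
                     balanced_confound = cf, chunk_index = ci),
                class = "batch_plan")
    })
  })
}

#' Synchronized batch streams for side-by-side model variants
#'
#' All variants consume identical batch plans in identical order, so
#' adversarially regressed, baseline and confounded models see the data in
#' the same order and any performance difference is attributable to the
#' training objective.
#'
#' @param metadata,schema,config as in [plan_batches()].
#' @param variants character vector of variant names.
#' @return named list mapping each variant to the shared plan list.
#' @export
paired_stream <- function(metadata, schema, config = scheduler_config(),
                          variants = c("mucran", "baseline", "confounded")) {
  plan <- plan_batches(metadata, schema, config)
  setNames(rep(list(plan), length(variants)), variants)
}

#' Serialize batch plans to a text log
#'
#' One line per chunk: chunk index, balanced confound, and the ordered sample
#' ids, tab-separated — enough to rerun training with the exact same stream.
#'
#' @param plans list of `batch_plan`s from [plan_batches()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_batch_log <- function(plans, path) {
  lines <- vapply(plans, function(p) {
    paste(p$chunk_index, p$balanced_confound,
          paste(p$sample_ids, collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
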