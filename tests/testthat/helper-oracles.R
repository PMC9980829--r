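# Independent reference implementations used as oracles.

# brute-force elementwise weighted row BCE on one (pred, target) array pair
ref_weighted_bce <- function(pred_vals, target_vals, mask, W, eps = 1e-7) {
  K <- nrow(mask) - 1L
  row_loss <- numeric(nrow(mask))
  for (r in seq_len(nrow(mask))) {
    idx <- which(mask[r, ] == 1)
    p <- pmin(pmax(pred_vals[r, idx], eps), 1 - eps)
    t <- target_vals[r, idx]
    row_loss[r] <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  }
  sum(c(W, rep(1, K)) * row_loss) / (W + K)
}

# O(n^2) pair-counting AUROC, ties counted one half
ref_auroc <- function(scores, truths) {
  pos <- scores[truths]
  neg <- scores[!truths]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# random schema + geometry-consistent random prediction/target arrays
random_loss_case <- function(seed) {
  set.seed(seed)
  K <- sample(1:3, 1)
  widths <- c(2L, sample(2:4, K, replace = TRUE))
  n <- 30 + max(widths) * 10
  md <- data.frame(label = sample(c("a", "b"), n, replace = TRUE))
  confs <- list()
  for (k in seq_len(K)) {
    nm <- paste0("c", k)
    md[[nm]] <- sample(letters[seq_len(widths[k + 1])], n, replace = TRUE)
    confs[[k]] <- nm
  }
  # ensure all categories observed
  for (k in seq_len(K)) {
    md[[paste0("c", k)]][seq_len(widths[k + 1])] <-
      letters[seq_len(widths[k + 1])]
  }
  schema <- build_schema(md, "label", confs, positive_class = "a")
  mask <- mucran:::schema_mask(schema)
  rnd <- function() {
    v <- matrix(runif(length(mask)), nrow(mask), ncol(mask)) * mask
    v
  }
  pred <- structure(list(values = rnd(), mask = mask, schema = schema),
                    class = "prediction_array")
  tv <- matrix(0, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    tv[r, sample(which(mask[r, ] == 1), 1)] <- 1
  }
  target <- structure(list(values = tv, mask = mask, schema = schema),
                      class = "target_array")
  list(schema = schema, mask = mask, pred = pred, target = target,
       W = runif(1, 0.5, 8))
}
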