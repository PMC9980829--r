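# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed stream (all arithmetic exact in doubles, result
# < 2^31 so it is a valid R integer seed).
derive_seed <- function(seed, i) {
  as.integer((((seed %% 2147483647) * 48271) %% 2147483647 +
                (i * 104729) %% 2147483647) %% 2147483647)
}

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mucran <- function(..., class) {
  stop(structure(class = c(class, "mucran_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
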