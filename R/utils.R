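## Internal helpers: RNG state handling, derived seeds, structured logging.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed, a stream name and an index to an
#' integer seed below 2^31, so every stage (trajectory, imaging noise,
#' per-cilium replicate) is independently replayable from one master seed.
#'
#' @param master_seed integer master seed.
#' @param stream character stream label, e.g. `"trajectory"` or a preset
#'   label.
#' @param index nonnegative integer replicate index.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "pH7.0", 3)
#' @export
derive_seed <- function(master_seed, stream, index = 0) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1,
            is.character(stream), length(stream) == 1,
            is.numeric(index), index >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(master_seed) %% m)
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h %% (m - 1) + 1)
}

## Evaluate `expr` under `seed` (if non-NULL), restoring the RNG state.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

## One structured log line per pipeline stage, to stderr.
log_stage <- function(stage, ..., seed = NULL) {
  detail <- paste(sprintf(...), collapse = " ")
  msg <- sprintf("[ciliabeat] stage=%s%s %s", stage,
                 if (is.null(seed)) "" else sprintf(" seed=%d", seed),
                 detail)
  message(msg)
  invisible(msg)
}

## Sample standard deviation with the n = 1 -> 0 convention used for
## single-cilium cohorts.
sd0 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x)
}
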