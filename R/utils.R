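# Internal helpers: argument checking and reproducible RNG substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Derive a deterministic substream seed from a master seed
#'
#' All generators draw from per-component substreams derived from one master
#' seed, so that regenerating a single input (say, only the promoters) gives
#' byte-identical output to a full run.
#'
#' @param master integer master seed.
#' @param name character label of the substream (e.g. `"expression"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, name) {
  stop_if_not(is.numeric(master) && length(master) == 1L && is.finite(master),
              "`master` must be a single finite number")
  h <- 0
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(master)) * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
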