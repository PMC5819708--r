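#' Derive a reproducible stage seed from a master seed
#'
#' Stages of the pipeline (differential expression permutations, delta
#' selection, module significance, synthetic generation, ...) each draw their
#' own seed from the master seed and a short stage tag, so any stage can be
#' rerun in isolation with the same stream.
#'
#' @param master integer master seed.
#' @param tag character stage tag.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(master) + h) %% 2147480009)
}

#' Evaluate an expression with a local RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# one-line stage log, suppressed when options(netheat.quiet = TRUE)
nh_log <- function(...) {
  if (!isTRUE(getOption("netheat.quiet", FALSE))) {
    message(sprintf("[netheat] %s", sprintf(...)))
  }
  invisible(NULL)
}
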