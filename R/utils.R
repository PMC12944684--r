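# Shared internal helpers: seeded evaluation and seed fan-out.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded library code never disturbs
#' the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a module-level seed from a global seed
#'
#' One global seed fans out to per-module seeds through a fixed counter
#' scheme, so a module keeps its own reproducible stream regardless of the
#' order in which pipeline stages run.
#'
#' @param seed Global integer seed.
#' @param offset Integer counter identifying the consumer.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + 1000003 * as.numeric(offset)) %%
               (.Machine$integer.max - 1))
}

# stop() with a stable condition class so callers can catch module errors
abort2 <- function(msg, class) {
  stop(structure(class = c(class, "cyp3a4hybrid_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
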