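# Structured error conditions. Every user-facing failure carries a class so
# callers (and the command-line wrapper) can map it to a distinct exit code.

.cdeg_error_classes <- c(
  validation_error  = 2L,
  design_error      = 3L,
  config_error      = 4L,
  capability_error  = 5L,
  bias_guard_error  = 6L,
  sizing_error      = 7L,
  io_error          = 8L,
  usage_error       = 64L
)

cdeg_stop <- function(message, class) {
  stopifnot(class %in% names(.cdeg_error_classes))
  stop(structure(
    class = c(class, "consensusDEG_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Exit code associated with a condition class
#'
#' Maps the package's structured error classes to the distinct process exit
#' codes used by the command-line wrapper.
#'
#' @param cond A condition object.
#' @return An integer exit code (1 for unclassified errors).
#' @export
exit_code_for <- function(cond) {
  hit <- intersect(class(cond), names(.cdeg_error_classes))
  if (length(hit) == 0L) return(1L)
  unname(.cdeg_error_classes[hit[1L]])
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# All randomness in the package flows through explicit seeds; nothing relies
# on (or perturbs) the global RNG.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cdeg_stop("`seed` must be a single non-missing integer", "config_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
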