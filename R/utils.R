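# Internal helpers: seeded evaluation, condition constructors, validation.

#' Evaluate code under a local RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded operations never perturb the global
#' random stream. A `NULL` seed leaves the stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Derive a stream-specific child seed from a parent seed; kept < 2^31.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

slim_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "slimscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

parameter_error <- function(msg) slim_error("slimscreen_parameter_error", msg)
format_error    <- function(msg) slim_error("slimscreen_format_error", msg)
generation_error <- function(msg) slim_error("slimscreen_generation_error", msg)

assert_that <- function(cond, msg, kind = parameter_error) {
  if (!isTRUE(cond)) kind(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Tight half-open bounding box (r0, c0, r1, c1) of a logical mask, 0-based.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(0L, 0L, 0L, 0L))
  c(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L, max(idx[, 1L]), max(idx[, 2L]))
}
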