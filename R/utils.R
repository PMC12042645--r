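# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage sub-seed derived from a root seed and a stage label.
# Keeps all randomness flowing from one root seed while giving each pipeline
# stage an independent stream. Result is always a valid 32-bit integer seed.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (31L^(seq_along(utf8ToInt(label)) %% 7L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Accepted call types
#'
#' The analysis is restricted to the two soft contact-call categories of the
#' zebra finch: stack calls (harmonic, little frequency modulation, up to
#' ~100 ms) and the shorter tet calls.
#' @return Character vector `c("stack", "tet")`.
#' @export
call_types <- function() c("stack", "tet")

assert_call_types <- function(x) {
  bad <- setdiff(unique(as.character(x)), call_types())
  if (length(bad) > 0) {
    stopf("unknown call type(s) %s; accepted types are: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(call_types(), collapse = ", "))
  }
  invisible(TRUE)
}
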