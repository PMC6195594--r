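# Classed conditions so callers and tests can distinguish failure modes.
stop_with <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "preictal_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_param     <- function(fmt, ...) stop_with("preictal_parameter_error", fmt, ...)
stop_size      <- function(fmt, ...) stop_with("preictal_size_error", fmt, ...)
stop_length    <- function(fmt, ...) stop_with("preictal_length_error", fmt, ...)
stop_data      <- function(fmt, ...) stop_with("preictal_data_error", fmt, ...)
stop_format    <- function(fmt, ...) stop_with("preictal_format_error", fmt, ...)
stop_integrity <- function(fmt, ...) stop_with("preictal_integrity_error", fmt, ...)
stop_degenerate <- function(fmt, ...) stop_with("preictal_degenerate_error", fmt, ...)
stop_divergence <- function(fmt, ...) stop_with("preictal_divergence_error", fmt, ...)

#' Derive a reproducible sub-stream seed from a base seed and labels
#'
#' Hashes a base seed together with an arbitrary sequence of labels
#' (stage names, seizure ids, channel indices, ...) into a 31-bit integer
#' usable with [set.seed()]. Stages of the pipeline draw their randomness
#' from named sub-streams of a single global seed so each stage can be
#' re-run in isolation and reproduced exactly.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) naming the sub-stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "synth", 3, "preictal")
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
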