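# Classed conditions: every user-facing failure is either a format error
# (malformed file / wrong columns) or a validation error (well-formed but
# inconsistent data).  Tests catch these classes, not message strings.

rk_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "relapsekit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rk_format_error <- function(fmt, ...) rk_stop("relapsekit_format_error", fmt, ...)
rk_validation_error <- function(fmt, ...) rk_stop("relapsekit_validation_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' A single run-level seed fans out to independent per-table seeds by a fixed
#' integer derivation, so that regenerating one table does not disturb the
#' stream of another.  Results stay below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param offset integer offset identifying the consumer.
#' @return an integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  as.integer((abs(seed) * 1009 + 97 * offset + 13) %% 2147483647L)
}

# stats::sd with explicit n-1 denominator is what we use everywhere;
# alias kept so the choice is greppable.
sample_sd <- function(x) stats::sd(x)

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    rk_validation_error("cosine similarity undefined for an all-zero vector")
  }
  sum(a * b) / (na * nb)
}
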