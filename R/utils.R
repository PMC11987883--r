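#' @importFrom rlang abort warn %||% .data
#' @importFrom Rcpp evalCpp
#' @useDynLib farrowcast, .registration = TRUE
#' @importFrom stats rnorm runif sd quantile cor predict
#' @importFrom utils head tail modifyList
NULL

# internal: abort with a consistent class so callers can test on it
fc_abort <- function(msg, class = "farrowcast_error", ...) {
  abort(msg, class = c(class, "farrowcast_error"), ...)
}

check_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fc_abort(sprintf("`%s` must be a single finite number.", name),
             class = "farrowcast_config_error")
  }
  lo_ok <- if (allow_zero) x >= min else x > min
  if (!lo_ok) {
    fc_abort(sprintf("`%s` must be %s %s.", name,
                     if (allow_zero) ">=" else ">", format(min)),
             class = "farrowcast_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    fc_abort(sprintf("`%s` must be an integer >= %d.", name, min),
             class = "farrowcast_config_error")
  }
  invisible(as.integer(x))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' Derive a per-subject random seed from a master seed
#'
#' Mixes the subject index through a Knuth-style multiplicative hash and
#' XORs it with the master seed, so subject streams are decoupled while the
#' whole cohort remains reproducible from one integer. The result is always
#' a non-negative 32-bit integer.
#'
#' @param master_seed Single integer master seed.
#' @param index Non-negative subject index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1L, 0:3)
derive_seed <- function(master_seed, index) {
  check_count(master_seed, "master_seed", min = 0L)
  vapply(index, function(i) {
    h <- (i * 2654435761) %% 2147483647
    bitwXor(as.integer(master_seed %% 2147483647), as.integer(h))
  }, integer(1))
}
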