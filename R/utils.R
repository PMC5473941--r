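# Internal helpers: argument checking and seed fan-out.

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name))
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    cmp <- if (allow_zero) "nonnegative" else "strictly positive"
    abort(sprintf("`%s` must be %s.", name, cmp))
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

check_prob_vector <- function(p, name) {
  check_probability(p, name)
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", name, sum(p)))
  }
  invisible(p)
}

#' Derive a reproducible child seed from a global seed and a stage name
#'
#' A single pipeline seed fans out to per-stage seeds through a stable
#' character hash, so each stage is independently reproducible regardless of
#' the order stages run in. The hash is plain integer arithmetic on the UTF-8
#' bytes of the stage name (no platform-dependent hashing), kept below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "kinetics")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1999999973
  as.integer((as.numeric(seed) %% 1999999973 * 31 + h) %% 2147483647L)
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
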