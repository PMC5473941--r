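# Broom-style tidiers for fitted objects.

#' Tidy a two-phase dwell fit
#'
#' @param x A `dwell_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.dwell_fit <- function(x, ...) {
  tibble::tibble(
    term = c("w_fast", "tau_fast_s", "tau_slow_s"),
    estimate = c(x$w_fast, x$tau_fast_s, x$tau_slow_s)
  )
}

#' @rdname tidy.dwell_fit
#' @return `glance()`: one row with `r_squared`, `rss`, `n_points`,
#'   `truncation_s`.
#' @exportS3Method generics::glance
glance.dwell_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, rss = x$rss, n_points = x$n_points,
    truncation_s = x$truncation_s %||% 0
  )
}

#' Tidy a kinetics summary
#'
#' @param x A `kinetics_summary` object.
#' @param ... Unused.
#' @return Long tibble `term`, `estimate` over the headline kinetic
#'   quantities.
#' @exportS3Method generics::tidy
tidy.kinetics_summary <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    term = c("kon_mean", "kon_sem", "koff_s", "kd_uM", "w_fast",
             "tau_fast_s", "tau_slow_s"),
    estimate = c(s$kon_mean, s$kon_sem, s$koff_s, s$kd_uM, s$w_fast,
                 s$tau_fast_s, s$tau_slow_s)
  )
}

#' @rdname tidy.kinetics_summary
#' @exportS3Method generics::glance
glance.kinetics_summary <- function(x, ...) {
  dplyr::select(
    x$summary, "r_squared", "detection_fraction", "n_events", "n_mt"
  )
}

#' Tidy a resampling summary
#'
#' @param x A `resampling_summary` object.
#' @param ... Unused.
#' @return The per-class summary tibble.
#' @exportS3Method generics::tidy
tidy.resampling_summary <- function(x, ...) x$summary

#' @rdname tidy.resampling_summary
#' @exportS3Method generics::glance
glance.resampling_summary <- function(x, ...) {
  tibble::tibble(n_rounds = x$n_rounds,
                 micrographs_used = nrow(x$rounds))
}
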