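# Size-exclusion chromatogram quantification: baseline normalization, AUC
# fractions, and group comparison.

as_trace <- function(trace) {
  if (inherits(trace, "chromatogram")) trace <- trace$trace
  stopifnot(all(c("volume_mL", "a280") %in% names(trace)))
  tibble::as_tibble(trace)
}

#' Normalize a chromatogram to its baseline reading
#'
#' Subtracts the A280 reading at a reference elution volume (default 5 mL,
#' before the void volume) from the whole trace, so the baseline sits at
#' zero. The reference reading is linearly interpolated when it falls
#' between grid points; the output is exactly zero at the reference volume.
#'
#' @param trace A `chromatogram` or tibble with `volume_mL`, `a280`.
#' @param reference_volume_mL Baseline reference volume, mL (default 5).
#' @return The shifted trace tibble.
#' @export
normalize_baseline <- function(trace, reference_volume_mL = 5.0) {
  trace <- as_trace(trace)
  if (reference_volume_mL < min(trace$volume_mL) ||
      reference_volume_mL > max(trace$volume_mL)) {
    abort("`reference_volume_mL` lies outside the trace's volume range.")
  }
  ref <- approx(trace$volume_mL, trace$a280, xout = reference_volume_mL)$y
  dplyr::mutate(trace, a280 = .data$a280 - ref)
}

window_auc <- function(v, a, v0, v1) {
  inside <- v > v0 & v < v1
  vv <- c(v0, v[inside], v1)
  aa <- c(
    approx(v, a, xout = v0)$y, a[inside], approx(v, a, xout = v1)$y
  )
  trapezoid(vv, aa)
}

#' Fraction of chromatogram area inside an elution window
#'
#' Trapezoidal area under the (baseline-normalized) trace between
#' `v_start_mL` and `v_end_mL`, divided by the trapezoidal area under the
#' whole trace. Window endpoints falling between grid points are linearly
#' interpolated; integration otherwise uses the native grid without
#' resampling. Negative post-normalization values are clipped to zero
#' before integration (they would otherwise subtract "negative protein");
#' clipping is reported via the `clipped_points` attribute and can be
#' disabled.
#'
#' @param trace Normalized trace (tibble `volume_mL`, `a280`).
#' @param v_start_mL,v_end_mL Integration window, mL.
#' @param clip_negative Clip negative absorbances to zero (default `TRUE`).
#' @return The area fraction (numeric scalar, attribute `clipped_points`).
#' @export
auc_fraction <- function(trace, v_start_mL, v_end_mL, clip_negative = TRUE) {
  trace <- as_trace(trace)
  if (v_start_mL >= v_end_mL) abort("`v_start_mL` must be < `v_end_mL`.")
  if (v_start_mL < min(trace$volume_mL) || v_end_mL > max(trace$volume_mL)) {
    abort("the window must lie within the trace support.")
  }
  a <- trace$a280
  clipped <- 0L
  if (clip_negative && any(a < 0)) {
    clipped <- sum(a < 0)
    a[a < 0] <- 0
  }
  total <- trapezoid(trace$volume_mL, a)
  if (total <= 0) abort("total AUC must be positive.")
  frac <- window_auc(trace$volume_mL, a, v_start_mL, v_end_mL) / total
  attr(frac, "clipped_points") <- clipped
  frac
}

#' Compare complex-formation fractions between two groups
#'
#' Unpaired two-tailed Student's t test (equal variance by default; set
#' `welch = TRUE` for the Welch form) on per-replicate AUC fractions of two
#' conditions. Degenerate identical zero-variance groups return p = 1 with
#' a warning instead of failing.
#'
#' @param group_a,group_b Numeric vectors of per-replicate fractions
#'   (each length >= 2).
#' @param welch Use the Welch unequal-variance test (default `FALSE`).
#' @return Tibble `t_statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
compare_fractions <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    warn("identical zero-variance groups; returning p = 1.")
    return(tibble::tibble(
      t_statistic = 0, p_value = 1, df = length(group_a) + length(group_b) - 2,
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = length(group_a), n_b = length(group_b)
    ))
  }
  tt <- t.test(group_a, group_b, var.equal = !welch, paired = FALSE)
  tibble::tibble(
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
}
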