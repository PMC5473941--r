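# Synthetic size-exclusion chromatograms.

#' Simulate a size-exclusion chromatogram
#'
#' Builds an A280 trace as `baseline + sum of Gaussian peaks + noise` on a
#' strictly increasing elution-volume grid. Each peak is
#' `area * dnorm(v, center, sigma)`, so `area` is the analytic area under
#' that peak; the peak table is returned as ground truth so area-fraction
#' estimates can be checked against closed-form Gaussian mass.
#'
#' @param peaks A data frame with columns `center_mL`, `sigma_mL`, `area`
#'   (one row per species).
#' @param baseline_level Constant baseline absorbance.
#' @param noise_sd SD of additive Gaussian noise (default 0).
#' @param volume_mL Strictly increasing elution-volume grid, mL.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A list of class `chromatogram` with `trace` (tibble `volume_mL`,
#'   `a280`), `peaks` (the ground-truth peak table) and `baseline_level`.
#' @export
#' @examples
#' chrom <- simulate_sec_trace(
#'   peaks = data.frame(center_mL = c(9, 12), sigma_mL = c(0.3, 0.4), area = c(1, 3)),
#'   baseline_level = 0.02, volume_mL = seq(5, 20, by = 0.01)
#' )
simulate_sec_trace <- function(peaks, baseline_level = 0, noise_sd = 0,
                               volume_mL = seq(5, 24, by = 0.02), seed = 1L) {
  stopifnot(is.data.frame(peaks), all(c("center_mL", "sigma_mL", "area") %in% names(peaks)))
  check_positive(peaks$sigma_mL, "peaks$sigma_mL")
  check_positive(noise_sd, "noise_sd", allow_zero = TRUE)
  if (any(diff(volume_mL) <= 0)) {
    abort("`volume_mL` must be strictly increasing (no repeated grid points).")
  }

  a280 <- rep(baseline_level, length(volume_mL))
  for (i in seq_len(nrow(peaks))) {
    a280 <- a280 + peaks$area[i] * dnorm(volume_mL, peaks$center_mL[i], peaks$sigma_mL[i])
  }
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      a280 <- a280 + rnorm(length(a280), 0, noise_sd)
    })
  }
  structure(
    list(
      trace = tibble::tibble(volume_mL = volume_mL, a280 = a280),
      peaks = tibble::as_tibble(peaks),
      baseline_level = baseline_level
    ),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %d points, %d peak(s), baseline %.3g\n",
    nrow(x$trace), nrow(x$peaks), x$baseline_level
  ))
  invisible(x)
}

#' Analytic Gaussian mass of a chromatogram window
#'
#' Closed-form fraction of total peak area lying inside `[v_start, v_end]`,
#' from the ground-truth peak table of [simulate_sec_trace()]. Used as the
#' oracle against trapezoidal [auc_fraction()] estimates.
#'
#' @param peaks Peak table (`center_mL`, `sigma_mL`, `area`).
#' @param v_start_mL,v_end_mL Window bounds, mL.
#' @return Fraction in \[0, 1\].
#' @export
gaussian_window_mass <- function(peaks, v_start_mL, v_end_mL) {
  inside <- sum(peaks$area *
    (pnorm(v_end_mL, peaks$center_mL, peaks$sigma_mL) -
      pnorm(v_start_mL, peaks$center_mL, peaks$sigma_mL)))
  inside / sum(peaks$area)
}
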