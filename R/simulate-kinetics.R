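# Synthetic single-molecule TIRF data: binding events and tracks.

#' Simulate a single-molecule microtubule binding assay
#'
#' Generates binding events on a set of microtubules with the statistical
#' structure the kinetics pipeline assumes: arrivals on each microtubule are
#' Poisson with mean `kon_per_site * sites_per_um * length_um * conc_nM *
#' duration_s`, dwell times are drawn from a two-phase exponential mixture
#' (phase chosen Bernoulli(`fast_fraction`), then exponential with that
#' phase's time constant), and all times are quantized to the camera frame
#' cycle: the event start snaps to the first frame boundary at or after the
#' true arrival, and the dwell is rounded to the nearest whole number of
#' frames. Events shorter than one frame after quantization are discarded and
#' counted in the `dropped_subframe` attribute. Events still bound when the
#' movie ends are truncated at the movie end and flagged `censored`.
#'
#' @param kon_per_site Per-binding-site association rate, nM^-1 s^-1.
#' @param fast_fraction Weight of the fast dwell phase, in \[0, 1\].
#' @param tau_fast_s,tau_slow_s Fast and slow dwell time constants, seconds
#'   (`tau_fast_s <= tau_slow_s`).
#' @param mt_lengths_um Numeric vector of microtubule lengths, um (one
#'   microtubule per element).
#' @param duration_s Movie duration, seconds; must be a whole number of frame
#'   cycles.
#' @param conc_nM Dynein concentration, nM.
#' @param sites_per_um Binding sites per micrometre of microtubule lattice
#'   (see [lattice_sites()]).
#' @param acquisition An [acquisition_params()] object.
#' @param seed Integer seed; fixed seed gives byte-identical tables.
#' @return A list of class `binding_assay` with elements
#'   `events` (tibble: `mt_id`, `event_id`, `t_start_s`, `t_end_s`,
#'   `duration_s`, `censored`), `microtubules` (tibble: `mt_id`, `length_um`,
#'   `duration_s`, `conc_nM`), and `truth` (the generating parameters,
#'   for parameter-recovery tests). Attribute `dropped_subframe` counts
#'   discarded sub-frame events.
#' @export
#' @examples
#' assay <- simulate_binding_assay(
#'   kon_per_site = 1e-4, fast_fraction = 0.8,
#'   tau_fast_s = 0.3, tau_slow_s = 3,
#'   mt_lengths_um = rep(10, 5), duration_s = 100, conc_nM = 0.5, seed = 1
#' )
#' nrow(assay$events)
simulate_binding_assay <- function(kon_per_site, fast_fraction,
                                   tau_fast_s, tau_slow_s,
                                   mt_lengths_um, duration_s, conc_nM,
                                   sites_per_um = lattice_sites()$real,
                                   acquisition = acquisition_params(),
                                   seed = 1L) {
  check_positive(kon_per_site, "kon_per_site", allow_zero = TRUE)
  check_probability(fast_fraction, "fast_fraction")
  check_positive(tau_fast_s, "tau_fast_s")
  check_positive(tau_slow_s, "tau_slow_s")
  if (tau_fast_s > tau_slow_s) abort("`tau_fast_s` must be <= `tau_slow_s`.")
  if (length(mt_lengths_um) < 1 || any(mt_lengths_um <= 0)) {
    abort("`mt_lengths_um` must be strictly positive.")
  }
  check_positive(duration_s, "duration_s")
  check_positive(conc_nM, "conc_nM")
  check_positive(sites_per_um, "sites_per_um")
  cycle <- acquisition$frame_cycle_s
  if (abs(duration_s / cycle - round(duration_s / cycle)) > 1e-9) {
    abort("`duration_s` must be a whole number of frame cycles.")
  }

  withr::with_seed(as.integer(seed), {
    dropped <- 0L
    per_mt <- purrr::imap(mt_lengths_um, function(len, i) {
      n <- rpois(1L, kon_per_site * sites_per_um * len * conc_nM * duration_s)
      if (n == 0L) {
        return(tibble::tibble(
          mt_id = sprintf("mt%03d", i), t_start_s = double(), t_end_s = double(),
          censored = logical()
        ))
      }
      arrival <- sort(runif(n, 0, duration_s))
      fast <- runif(n) < fast_fraction
      dwell <- rexp(n, rate = 1 / ifelse(fast, tau_fast_s, tau_slow_s))
      t_start <- ceiling(arrival / cycle - 1e-12) * cycle
      frames <- round(dwell / cycle)
      sub <- frames < 1L | t_start >= duration_s
      dropped <<- dropped + sum(sub)
      t_start <- t_start[!sub]
      t_end <- t_start + frames[!sub] * cycle
      censored <- t_end > duration_s + 1e-12
      t_end[censored] <- duration_s
      tibble::tibble(
        mt_id = sprintf("mt%03d", i),
        t_start_s = t_start, t_end_s = t_end, censored = censored
      )
    })
    events <- dplyr::bind_rows(per_mt)
  })

  events <- events |>
    dplyr::mutate(
      event_id = dplyr::row_number(),
      duration_s = .data$t_end_s - .data$t_start_s,
      .after = "mt_id"
    ) |>
    dplyr::filter(.data$duration_s > 0)

  mts <- tibble::tibble(
    mt_id = sprintf("mt%03d", seq_along(mt_lengths_um)),
    length_um = as.double(mt_lengths_um),
    duration_s = duration_s,
    conc_nM = conc_nM
  )

  structure(
    list(
      events = events,
      microtubules = mts,
      truth = list(
        kon_per_site = kon_per_site, fast_fraction = fast_fraction,
        tau_fast_s = tau_fast_s, tau_slow_s = tau_slow_s,
        sites_per_um = sites_per_um,
        koff_s = 1 / tau_fast_s,
        kd_uM = if (kon_per_site > 0) (1 / tau_fast_s) / kon_per_site / 1000 else NA_real_
      )
    ),
    dropped_subframe = dropped,
    class = "binding_assay"
  )
}

#' @export
print.binding_assay <- function(x, ...) {
  cat(sprintf(
    "<binding_assay> %d events on %d microtubules (%d sub-frame events dropped)\n",
    nrow(x$events), nrow(x$microtubules), attr(x, "dropped_subframe")
  ))
  invisible(x)
}

#' Simulate single-molecule tracks
#'
#' Emits position-versus-time tracks under one of three motion models:
#' `"static"` (no true displacement), `"diffusive"` (1D Brownian motion with
#' diffusion coefficient `d_um2_s`), or `"processive"` (constant velocity
#' `v_um_s` over an exponentially distributed run length with mean
#' `mean_run_um`). Gaussian localization noise `noise_sd_um` is added before
#' positions are quantized to the pixel grid.
#'
#' @param model One of `"static"`, `"diffusive"`, `"processive"`.
#' @param n_tracks Number of tracks (>= 1).
#' @param acquisition An [acquisition_params()] object; samples are spaced by
#'   its frame cycle unless `sample_interval_s` overrides it.
#' @param pixel_size_um Pixel size used for quantization; `0` disables
#'   quantization.
#' @param duration_s Track duration for static/diffusive tracks, seconds.
#' @param v_um_s Velocity for the processive model, um/s.
#' @param mean_run_um Mean run length for the processive model, um.
#' @param d_um2_s Diffusion coefficient for the diffusive model, um^2/s.
#' @param noise_sd_um Localization noise SD, um (default 0 so analytic
#'   oracles apply).
#' @param sample_interval_s Optional sampling interval overriding the frame
#'   cycle (e.g. 3 s for gliding assays).
#' @param seed Integer seed.
#' @return A tibble with columns `track_id`, `frame`, `time_s`,
#'   `position_um`, plus attribute `truth` holding the model parameters.
#' @export
simulate_tracks <- function(model = c("static", "diffusive", "processive"),
                            n_tracks, acquisition = acquisition_params(),
                            pixel_size_um = acquisition$pixel_size_um,
                            duration_s = 5, v_um_s = 0.5, mean_run_um = 1,
                            d_um2_s = 0.01, noise_sd_um = 0,
                            sample_interval_s = NULL, seed = 1L) {
  model <- match.arg(model)
  if (n_tracks < 1) abort("`n_tracks` must be >= 1.")
  if (model == "processive") check_positive(v_um_s, "v_um_s")
  if (model == "diffusive") check_positive(d_um2_s, "d_um2_s")
  check_positive(noise_sd_um, "noise_sd_um", allow_zero = TRUE)
  dt <- sample_interval_s %||% acquisition$frame_cycle_s

  withr::with_seed(as.integer(seed), {
    tracks <- purrr::map(seq_len(n_tracks), function(i) {
      if (model == "processive") {
        run <- rexp(1L, 1 / mean_run_um)
        n <- max(2L, ceiling(run / (v_um_s * dt)) + 1L)
        pos <- pmin((seq_len(n) - 1L) * dt * v_um_s, run)
      } else {
        n <- max(2L, round(duration_s / dt) + 1L)
        pos <- if (model == "static") {
          rep(0, n)
        } else {
          c(0, cumsum(rnorm(n - 1L, 0, sqrt(2 * d_um2_s * dt))))
        }
      }
      if (noise_sd_um > 0) pos <- pos + rnorm(length(pos), 0, noise_sd_um)
      if (pixel_size_um > 0) pos <- round(pos / pixel_size_um) * pixel_size_um
      tibble::tibble(
        track_id = sprintf("trk%04d", i),
        frame = seq_along(pos) - 1L,
        time_s = (seq_along(pos) - 1L) * dt,
        position_um = pos
      )
    })
    out <- dplyr::bind_rows(tracks)
  })
  attr(out, "truth") <- list(
    model = model, v_um_s = v_um_s, mean_run_um = mean_run_um,
    d_um2_s = d_um2_s, noise_sd_um = noise_sd_um, dt = dt,
    pixel_size_um = pixel_size_um
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
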