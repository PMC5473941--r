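# Motility analysis: processivity classification, normalized processive
# event rates, and gliding velocimetry.

#' Processivity classification thresholds
#'
#' A single-molecule run counts as processive when it lasts longer than
#' `min_duration_s` (default 0.625 s, i.e. 5 frames at 8 fps) AND moves
#' unidirectionally by more than `min_displacement_nm` (default 500 nm).
#' "Unidirectional" is operationalized as net-displacement direction with
#' bounded counter-movement: no excursion against the net direction may
#' exceed `reversal_tolerance_um` (default 2 pixels = 0.32 um).
#'
#' @param min_duration_s Duration threshold, seconds (strict `>`).
#' @param min_displacement_nm Net displacement threshold, nm (strict `>`).
#' @param reversal_tolerance_um Maximum allowed counter-excursion, um.
#' @param strict Use strict inequalities at both thresholds (default `TRUE`,
#'   matching "longer than" / "greater than").
#' @return A list of class `processivity_params`.
#' @export
processivity_params <- function(min_duration_s = 0.625,
                                min_displacement_nm = 500,
                                reversal_tolerance_um = 0.32,
                                strict = TRUE) {
  check_positive(min_duration_s, "min_duration_s")
  check_positive(min_displacement_nm, "min_displacement_nm")
  check_positive(reversal_tolerance_um, "reversal_tolerance_um", allow_zero = TRUE)
  structure(
    list(
      min_duration_s = min_duration_s,
      min_displacement_nm = min_displacement_nm,
      reversal_tolerance_um = reversal_tolerance_um,
      strict = strict
    ),
    class = "processivity_params"
  )
}

track_metrics <- function(time_s, position_um) {
  net <- position_um[length(position_um)] - position_um[1]
  dir <- if (net >= 0) 1 else -1
  p <- position_um * dir
  max_rev <- max(cummax(p) - p) # largest excursion against the net direction
  tibble::tibble(
    duration_s = time_s[length(time_s)] - time_s[1],
    net_displacement_um = net,
    net_displacement_nm = net * 1000,
    max_reversal_um = max_rev
  )
}

#' Classify tracks as processive or non-processive
#'
#' Applies the duration, net-displacement, and reversal-tolerance rules of
#' [processivity_params()] to each track. Displacement is measured along the
#' 1D microtubule-axis coordinate carried by the track.
#'
#' @param tracks Tibble with `track_id`, `time_s`, `position_um` (and
#'   optionally `mt_id`).
#' @param params A [processivity_params()] object.
#' @return One row per track: `track_id` (and `mt_id` if present),
#'   `duration_s`, `net_displacement_nm`, `max_reversal_um`, `processive`
#'   (logical), `label` (`"processive"` / `"non-processive"`).
#' @export
classify_processive <- function(tracks, params = processivity_params()) {
  stopifnot(all(c("track_id", "time_s", "position_um") %in% names(tracks)))
  keys <- intersect(c("track_id", "mt_id"), names(tracks))
  out <- tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::reframe(track_metrics(.data$time_s, .data$position_um))
  cmp <- if (params$strict) `>` else `>=`
  out |>
    dplyr::mutate(
      processive = cmp(.data$duration_s, params$min_duration_s) &
        cmp(abs(.data$net_displacement_nm), params$min_displacement_nm) &
        .data$max_reversal_um <= params$reversal_tolerance_um,
      label = ifelse(.data$processive, "processive", "non-processive")
    )
}

#' Normalized processive-event rate per microtubule
#'
#' Counts processive events on each microtubule and normalizes by
#' microtubule length (um), observation time (s), and motor amount (pM):
#' `rate = n_processive / (length_um * duration_s * conc_pM)`. Because the
#' per-second term is sometimes omitted when such rates are reported, the
#' length-and-concentration-only convention is returned alongside
#' (`rate_per_um_pM = n_processive / (length_um * conc_pM)`).
#'
#' @param classified Output of [classify_processive()] with an `mt_id`
#'   column.
#' @param microtubules Tibble `mt_id`, `length_um`, `duration_s`, `conc_pM`.
#' @return A list with `per_mt` (tibble: `mt_id`, `n_processive`, `rate`,
#'   `rate_per_um_pM`) and `summary` (mean and SEM of both conventions
#'   across microtubules).
#' @export
processive_event_rate <- function(classified, microtubules) {
  stopifnot("mt_id" %in% names(classified), "mt_id" %in% names(microtubules))
  check_positive(microtubules$length_um, "length_um")
  check_positive(microtubules$duration_s, "duration_s")
  check_positive(microtubules$conc_pM, "conc_pM")
  per_mt <- microtubules |>
    dplyr::left_join(
      classified |>
        dplyr::filter(.data$processive) |>
        dplyr::count(.data$mt_id, name = "n_processive"),
      by = "mt_id"
    ) |>
    dplyr::mutate(
      n_processive = dplyr::coalesce(.data$n_processive, 0L),
      rate = .data$n_processive /
        (.data$length_um * .data$duration_s * .data$conc_pM),
      rate_per_um_pM = .data$n_processive / (.data$length_um * .data$conc_pM)
    ) |>
    dplyr::select("mt_id", "n_processive", "rate", "rate_per_um_pM")
  n <- nrow(per_mt)
  sem <- function(x) if (n > 1) sd(x) / sqrt(n) else 0
  list(
    per_mt = per_mt,
    summary = tibble::tibble(
      rate_mean = mean(per_mt$rate), rate_sem = sem(per_mt$rate),
      rate_per_um_pM_mean = mean(per_mt$rate_per_um_pM),
      rate_per_um_pM_sem = sem(per_mt$rate_per_um_pM),
      n_mt = n
    )
  )
}

#' Gliding-assay velocity
#'
#' Per-track speed is the mean of `|delta position| / delta t` over
#' consecutive samples of a microtubule leading-edge track; the population
#' statistic is the mean and SEM of the per-track speeds. Tracks with a
#' single sample are skipped with a warning.
#'
#' @param tracks Tibble with `track_id`, `time_s`, `position_um`.
#' @return A list with `per_track` (tibble `track_id`, `velocity_um_s`,
#'   `n_intervals`) and `summary` (`velocity_mean`, `velocity_sem`,
#'   `n_tracks`).
#' @export
gliding_velocity <- function(tracks) {
  stopifnot(all(c("track_id", "time_s", "position_um") %in% names(tracks)))
  sizes <- dplyr::count(tracks, .data$track_id)
  if (any(sizes$n < 2)) {
    warn(sprintf(
      "%d track(s) with a single sample skipped.", sum(sizes$n < 2)
    ))
    tracks <- dplyr::semi_join(tracks, dplyr::filter(sizes, .data$n >= 2),
      by = "track_id"
    )
  }
  if (nrow(tracks) == 0) abort("no tracks with >= 2 samples.")
  per_track <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      velocity_um_s = mean(abs(diff(.data$position_um)) / diff(.data$time_s)),
      n_intervals = dplyr::n() - 1L
    )
  n <- nrow(per_track)
  list(
    per_track = per_track,
    summary = tibble::tibble(
      velocity_mean = mean(per_track$velocity_um_s),
      velocity_sem = if (n > 1) sd(per_track$velocity_um_s) / sqrt(n) else 0,
      n_tracks = n
    )
  )
}
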