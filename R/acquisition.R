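#' Acquisition parameters for a TIRF movie
#'
#' Bundles the camera timing and geometry that every kinetics and motility
#' computation depends on. The default timing (100 ms exposure + 25 ms readout
#' delay, i.e. a 125 ms frame cycle at 8 fps) and the default pixel size
#' (0.16 um) match a typical EMCCD single-molecule setup.
#'
#' @param exposure_s Camera exposure per frame, seconds.
#' @param delay_s Readout delay between frames, seconds.
#' @param pixel_size_um Edge length of one camera pixel in the sample plane,
#'   micrometres.
#' @param min_event_frames Minimum number of whole frames a binding event must
#'   span to be scored (default 2 frames = 0.25 s at the default cycle).
#' @return An object of class `acquisition_params`: a list with
#'   `exposure_s`, `delay_s`, `frame_cycle_s`, `pixel_size_um`,
#'   `min_event_frames`.
#' @export
#' @examples
#' acq <- acquisition_params()
#' frame_rate(acq) # 8 fps
acquisition_params <- function(exposure_s = 0.100, delay_s = 0.025,
                               pixel_size_um = 0.16, min_event_frames = 2L) {
  check_positive(exposure_s, "exposure_s")
  check_positive(delay_s, "delay_s", allow_zero = TRUE)
  check_positive(pixel_size_um, "pixel_size_um")
  if (min_event_frames < 1) abort("`min_event_frames` must be >= 1.")
  structure(
    list(
      exposure_s = exposure_s,
      delay_s = delay_s,
      frame_cycle_s = exposure_s + delay_s,
      pixel_size_um = pixel_size_um,
      min_event_frames = as.integer(min_event_frames)
    ),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> %.0f ms exposure + %.0f ms delay (%.3g fps), %.2f um px, min %d frames\n",
    x$exposure_s * 1000, x$delay_s * 1000, frame_rate(x),
    x$pixel_size_um, x$min_event_frames
  ))
  invisible(x)
}

#' Frame rate implied by the acquisition timing
#'
#' @param acquisition An [acquisition_params()] object.
#' @return Frames per second, `1 / frame_cycle_s`.
#' @export
frame_rate <- function(acquisition) {
  check_positive(acquisition$frame_cycle_s, "frame_cycle_s")
  1 / acquisition$frame_cycle_s
}

#' Minimum scoreable event duration
#'
#' The shortest dwell retained by [filter_events()]: `min_event_frames`
#' whole frame cycles (0.25 s at the defaults).
#'
#' @inheritParams frame_rate
#' @return Seconds.
#' @export
min_event_duration <- function(acquisition) {
  acquisition$min_event_frames * acquisition$frame_cycle_s
}
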