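# Synthetic fluorescence image stacks: Gaussian foci on a flat background.

#' Simulate a fluorescence z-stack with Gaussian foci
#'
#' Builds a z/y/x intensity array emulating a fixed-cell acquisition: a flat
#' `background_level` plus isotropic 2D Gaussian foci (amplitude at the peak
#' pixel, lateral SD `sigma_px`, confined to the focus's own z slice), with
#' optional shot-like Poisson noise or additive Gaussian noise. Intensities
#' are clipped to the 16-bit range \[0, 65535\]; clipping emits a warning.
#'
#' @param shape_zyx Integer vector `(n_z, n_y, n_x)`.
#' @param foci Data frame with columns `z`, `y`, `x` (1-based pixel
#'   coordinates inside the stack), `amplitude`, `sigma_px`. `NULL` or
#'   zero rows for a focus-free stack.
#' @param background_level Constant background intensity.
#' @param noise One of `"none"`, `"poisson"`, `"gaussian"`.
#' @param noise_sd Gaussian noise SD (used when `noise = "gaussian"`).
#' @param seed Integer seed.
#' @return A list of class `image_stack`: `data` (z,y,x array), `truth`
#'   (focus table with each focus's true integrated signal above background).
#' @export
simulate_cell_image <- function(shape_zyx = c(11, 64, 64), foci = NULL,
                                background_level = 100,
                                noise = c("none", "poisson", "gaussian"),
                                noise_sd = 5, seed = 1L) {
  noise <- match.arg(noise)
  check_positive(background_level, "background_level", allow_zero = TRUE)
  stopifnot(length(shape_zyx) == 3, all(shape_zyx >= 1))
  nz <- shape_zyx[1]; ny <- shape_zyx[2]; nx <- shape_zyx[3]
  img <- array(background_level, dim = c(nz, ny, nx))

  truth <- tibble::tibble(
    focus_id = integer(), z = integer(), y = integer(), x = integer(),
    amplitude = double(), sigma_px = double(), integrated_signal = double()
  )
  if (!is.null(foci) && nrow(foci) > 0) {
    stopifnot(all(c("z", "y", "x", "amplitude", "sigma_px") %in% names(foci)))
    if (any(foci$z < 1 | foci$z > nz | foci$y < 1 | foci$y > ny |
              foci$x < 1 | foci$x > nx)) {
      abort("all foci must lie inside the image bounds.")
    }
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    rows <- vector("list", nrow(foci))
    for (i in seq_len(nrow(foci))) {
      g <- foci$amplitude[i] *
        exp(-((yy - foci$y[i])^2 + (xx - foci$x[i])^2) / (2 * foci$sigma_px[i]^2))
      img[foci$z[i], , ] <- img[foci$z[i], , ] + g
      rows[[i]] <- tibble::tibble(
        focus_id = i, z = as.integer(foci$z[i]), y = as.integer(foci$y[i]),
        x = as.integer(foci$x[i]), amplitude = foci$amplitude[i],
        sigma_px = foci$sigma_px[i], integrated_signal = sum(g)
      )
    }
    truth <- dplyr::bind_rows(rows)
  }

  if (noise != "none") {
    withr::with_seed(as.integer(seed), {
      img[] <- if (noise == "poisson") {
        rpois(length(img), lambda = img)
      } else {
        img + rnorm(length(img), 0, noise_sd)
      }
    })
  }
  if (any(img < 0 | img > 65535)) {
    warn("intensities clipped to the 16-bit range [0, 65535].")
    img[img < 0] <- 0
    img[img > 65535] <- 65535
  }
  structure(list(data = img, truth = truth), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %s (z,y,x), %d ground-truth focus/foci\n",
    paste(d, collapse = " x "), nrow(x$truth)
  ))
  invisible(x)
}

#' Simulate a live-cell focus time course
#'
#' Generates per-timepoint 2D images (MAX-projection equivalents) in which
#' foci appear linearly after `t_on_s` and grow toward `amplitude`, on a flat
#' background — the structure live-focus recovery quantification assumes.
#'
#' @param n_timepoints Number of frames.
#' @param interval_s Time between frames, seconds (default 30 s).
#' @param shape_yx Image `(n_y, n_x)`.
#' @param foci Data frame `y`, `x`, `amplitude`, `sigma_px`, `t_on_s`.
#' @param background_level Constant background.
#' @param noise,noise_sd,seed As in [simulate_cell_image()].
#' @return List of class `image_timelapse`: `frames` (list of y,x matrices),
#'   `time_s`, `truth` (per-focus, per-timepoint true peak amplitude).
#' @export
simulate_focus_timelapse <- function(n_timepoints = 21, interval_s = 30,
                                     shape_yx = c(64, 64), foci,
                                     background_level = 100,
                                     noise = c("none", "poisson", "gaussian"),
                                     noise_sd = 5, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(c("y", "x", "amplitude", "sigma_px", "t_on_s") %in% names(foci)))
  time_s <- (seq_len(n_timepoints) - 1L) * interval_s
  ramp_s <- max(time_s) - foci$t_on_s # linear rise to full amplitude at movie end
  yy <- matrix(seq_len(shape_yx[1]), shape_yx[1], shape_yx[2])
  xx <- matrix(seq_len(shape_yx[2]), shape_yx[1], shape_yx[2], byrow = TRUE)

  truth <- tidyr::expand_grid(focus_id = seq_len(nrow(foci)), t_index = seq_len(n_timepoints)) |>
    dplyr::mutate(
      time_s = .env$time_s[.data$t_index],
      amplitude = pmax(0, pmin(1, (.data$time_s - foci$t_on_s[.data$focus_id]) /
        pmax(ramp_s[.data$focus_id], 1e-9))) * foci$amplitude[.data$focus_id]
    )

  frames <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_timepoints), function(ti) {
      fr <- matrix(background_level, shape_yx[1], shape_yx[2])
      for (i in seq_len(nrow(foci))) {
        a <- truth$amplitude[truth$focus_id == i & truth$t_index == ti]
        if (a > 0) {
          fr <- fr + a * exp(-((yy - foci$y[i])^2 + (xx - foci$x[i])^2) /
            (2 * foci$sigma_px[i]^2))
        }
      }
      if (noise == "poisson") {
        fr[] <- rpois(length(fr), lambda = fr)
      } else if (noise == "gaussian") {
        fr <- fr + rnorm(length(fr), 0, noise_sd)
      }
      fr
    })
  })
  structure(
    list(frames = frames, time_s = time_s, truth = truth,
         foci = tibble::as_tibble(foci)),
    class = "image_timelapse"
  )
}
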