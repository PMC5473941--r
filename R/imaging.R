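# ROI-based fluorescence quantification: projections, ROI statistics,
# background correction, live-focus time courses, and the nonparametric
# group-comparison workflow.

#' SUM projection of a z-stack window
#'
#' Pixelwise sum of the `n_slices` slices centred on `center_z` (default 11
#' slices, the window used around a centrosome or spindle pole). The window
#' must lie fully inside the stack; there is no silent truncation.
#'
#' @param stack An `image_stack` or a (z, y, x) array.
#' @param center_z Central slice index (1-based).
#' @param n_slices Odd number of slices to sum (default 11).
#' @return A 2D (y, x) matrix.
#' @export
sum_projection <- function(stack, center_z, n_slices = 11) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(length(dim(arr)) == 3)
  if (n_slices %% 2 == 0) abort("`n_slices` must be odd.")
  half <- (n_slices - 1) / 2
  z0 <- center_z - half; z1 <- center_z + half
  if (z0 < 1 || z1 > dim(arr)[1]) {
    abort(sprintf(
      "projection window [%d, %d] exceeds the stack's %d slices.",
      z0, z1, dim(arr)[1]
    ))
  }
  if (n_slices == 1) return(arr[z0, , ])
  apply(arr[z0:z1, , , drop = FALSE], c(2, 3), sum)
}

#' MAX projection of a z-stack
#'
#' Pixelwise maximum across all z slices (used per timepoint in live-cell
#' quantification).
#'
#' @inheritParams sum_projection
#' @return A 2D (y, x) matrix.
#' @export
max_projection <- function(stack) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(length(dim(arr)) == 3)
  apply(arr, c(2, 3), max)
}

roi_window <- function(center, size, limit) {
  start <- center - floor((size - 1) / 2)
  end <- start + size - 1L
  if (start < 1 || end > limit) {
    abort(sprintf("ROI [%d, %d] falls outside the image (1..%d).", start, end, limit))
  }
  start:end
}

#' Measure a square ROI on a 2D image
#'
#' Mean (default) or sum of a `size_px` x `size_px` window. Odd windows are
#' centred on the named pixel; even windows are anchored so the named centre
#' sits at 1-based index `size_px / 2` of the window (a 12 x 12 ROI places
#' the centre pixel 6th of 12).
#'
#' @param image 2D (y, x) matrix.
#' @param y,x Centre pixel (1-based).
#' @param size_px Window edge length (default 12).
#' @param statistic `"mean"` or `"sum"`.
#' @return Numeric scalar.
#' @export
measure_roi <- function(image, y, x, size_px = 12, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(length(dim(image)) == 2)
  win <- image[roi_window(y, size_px, nrow(image)),
               roi_window(x, size_px, ncol(image)), drop = FALSE]
  if (statistic == "mean") mean(win) else sum(win)
}

measure_roi_table <- function(image, rois, size_px, statistic) {
  vapply(
    seq_len(nrow(rois)),
    function(i) measure_roi(image, rois$y[i], rois$x[i], size_px, statistic),
    0
  )
}

#' Background-subtracted centrosome signal
#'
#' Fixed-cell convention for centrosome intensity: the ROI value at the
#' centrosome minus the MEAN of exactly three cytoplasmic background ROIs
#' of the same size. Negative corrected values are legitimate and passed
#' through.
#'
#' @param image 2D (y, x) matrix (typically a [sum_projection()]).
#' @param centrosome Data frame / list with `y`, `x`.
#' @param background Data frame with `y`, `x` — exactly 3 rows.
#' @param size_px ROI edge (default 12).
#' @param statistic Per-ROI statistic (default `"mean"`).
#' @return Tibble `raw`, `background`, `corrected`, `mode = "subtract"`.
#' @export
centrosome_signal <- function(image, centrosome, background, size_px = 12,
                              statistic = "mean") {
  if (nrow(background) != 3) {
    abort("exactly 3 cytoplasmic background ROIs are required.")
  }
  raw <- measure_roi(image, centrosome$y, centrosome$x, size_px, statistic)
  bg <- mean(measure_roi_table(image, background, size_px, statistic))
  tibble::tibble(raw = raw, background = bg, corrected = raw - bg, mode = "subtract")
}

#' Background-ratio spindle-pole signal
#'
#' Fixed-cell convention for spindle-pole intensity: the ROI value at the
#' pole divided by the MEDIAN of exactly three cytoplasmic background ROIs.
#'
#' @inheritParams centrosome_signal
#' @param pole Data frame / list with `y`, `x`.
#' @return Tibble `raw`, `background`, `corrected`, `mode = "ratio"`.
#' @export
pole_ratio <- function(image, pole, background, size_px = 12,
                       statistic = "mean") {
  if (nrow(background) != 3) {
    abort("exactly 3 cytoplasmic background ROIs are required.")
  }
  raw <- measure_roi(image, pole$y, pole$x, size_px, statistic)
  bg <- median(measure_roi_table(image, background, size_px, statistic))
  if (bg <= 0) abort("background median must be positive for ratio mode.")
  tibble::tibble(raw = raw, background = bg, corrected = raw / bg, mode = "ratio")
}

#' Live-cell focus intensity time course
#'
#' Quantifies focus recovery backwards in time: 3 x 3 ROIs are centred on
#' foci identified on the final frame, then tracked back frame by frame to
#' the nearest local maximum within a 1-pixel search radius. When a focus
#' disappears (its background-subtracted value drops to <= 0) its ROI is
#' frozen in place for all earlier timepoints. Each focus value has the
#' intensity of a same-sized cytoplasmic background ROI subtracted; the
#' summary per timepoint is the mean and SD across foci.
#'
#' @param frames List of 2D (y, x) matrices, one per timepoint (MAX
#'   projections), or an `image_timelapse`.
#' @param foci Data frame `focus_id`, `y`, `x` — positions on the final
#'   frame.
#' @param background Data frame / list with `y`, `x` for the cytoplasmic
#'   background ROI.
#' @param size_px ROI edge (default 3).
#' @param track Track foci backwards to the local maximum (default `TRUE`).
#' @return A list of class `foci_timecourse`: `per_focus` (tibble
#'   `focus_id`, `t_index`, `time_s`, `y`, `x`, `value`, `frozen`) and
#'   `summary` (tibble `t_index`, `time_s`, `mean`, `sd`, `n_foci`).
#' @export
foci_timecourse <- function(frames, foci, background, size_px = 3,
                            track = TRUE) {
  time_s <- NULL
  if (inherits(frames, "image_timelapse")) {
    time_s <- frames$time_s
    frames <- frames$frames
  }
  if (is.null(time_s)) time_s <- seq_along(frames) - 1
  if (nrow(foci) == 0) abort("at least one focus is required.")
  nt <- length(frames)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])

  rows <- vector("list", nrow(foci) * nt)
  k <- 0
  for (i in seq_len(nrow(foci))) {
    y <- foci$y[i]; x <- foci$x[i]
    frozen <- FALSE
    for (ti in rev(seq_len(nt))) {
      img <- frames[[ti]]
      if (track && ti < nt && !frozen) {
        # move to the brightest pixel within 1 px of the current centre
        ys <- max(1, y - 1):min(ny, y + 1)
        xs <- max(1, x - 1):min(nx, x + 1)
        nb <- img[ys, xs, drop = FALSE]
        idx <- which(nb == max(nb), arr.ind = TRUE)[1, ]
        y <- ys[idx[1]]; x <- xs[idx[2]]
      }
      val <- tryCatch(
        measure_roi(img, y, x, size_px) -
          measure_roi(img, background$y, background$x, size_px),
        error = function(e) NA_real_
      )
      if (!frozen && !is.na(val) && val <= 0 && ti < nt) frozen <- TRUE
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        focus_id = foci$focus_id[i], t_index = ti, time_s = time_s[ti],
        y = y, x = x, value = val, frozen = frozen
      )
    }
  }
  per_focus <- dplyr::arrange(dplyr::bind_rows(rows), .data$focus_id, .data$t_index)
  summary <- per_focus |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$t_index, .data$time_s) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      n_foci = dplyr::n(), .groups = "drop"
    )
  structure(list(per_focus = per_focus, summary = summary),
            class = "foci_timecourse")
}

#' Multi-experiment nonparametric group comparison
#'
#' The fixed-cell statistics workflow: within each independent experiment,
#' every condition is tested for normality (Shapiro-Wilk) and the set of
#' conditions for variance homogeneity (Bartlett); an omnibus
#' Kruskal-Wallis test asks whether any condition differs; all condition
#' pairs are then compared with a paired Wilcoxon signed-rank test (pairing
#' by within-experiment observation order; pairs of unequal length are
#' skipped with a warning). The reported p value for each pairwise
#' comparison is the MAXIMUM across experiments — the most conservative of
#' the replicate experiments.
#'
#' @param data Tibble with columns `value`, `condition`, `experiment`.
#' @return A list of class `group_comparison`: `normality`, `variance`
#'   (Bartlett per experiment), `omnibus` (Kruskal-Wallis per experiment),
#'   `pairwise` (per experiment), and `pairwise_max_p` (aggregated).
#' @export
group_compare <- function(data) {
  stopifnot(all(c("value", "condition", "experiment") %in% names(data)))
  if (dplyr::n_distinct(data$condition) < 2) {
    abort("at least 2 conditions are required.")
  }
  by_exp <- split(data, data$experiment)

  normality <- purrr::imap_dfr(by_exp, function(d, ex) {
    d |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        p_shapiro = tryCatch(shapiro.test(.data$value)$p.value,
          error = function(e) NA_real_
        ),
        n = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(experiment = ex, .before = 1)
  })
  variance <- purrr::imap_dfr(by_exp, function(d, ex) {
    tibble::tibble(
      experiment = ex,
      p_bartlett = tryCatch(
        bartlett.test(d$value, factor(d$condition))$p.value,
        error = function(e) NA_real_
      )
    )
  })
  omnibus <- purrr::imap_dfr(by_exp, function(d, ex) {
    kw <- kruskal.test(d$value, factor(d$condition))
    tibble::tibble(
      experiment = ex,
      statistic = unname(kw$statistic), p_kruskal = kw$p.value
    )
  })
  pairwise <- purrr::imap_dfr(by_exp, function(d, ex) {
    conds <- sort(unique(d$condition))
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- d$value[d$condition == pr[1]]
      b <- d$value[d$condition == pr[2]]
      if (length(a) != length(b)) {
        warn(sprintf(
          "experiment %s: conditions %s/%s have unequal n; paired Wilcoxon skipped.",
          ex, pr[1], pr[2]
        ))
        return(tibble::tibble(
          experiment = ex, condition_a = pr[1], condition_b = pr[2],
          p_wilcoxon = NA_real_
        ))
      }
      wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
      tibble::tibble(
        experiment = ex, condition_a = pr[1], condition_b = pr[2],
        p_wilcoxon = wt$p.value
      )
    })
  })
  pairwise_max_p <- pairwise |>
    dplyr::group_by(.data$condition_a, .data$condition_b) |>
    dplyr::summarise(
      p_reported = if (all(is.na(.data$p_wilcoxon))) NA_real_
        else max(.data$p_wilcoxon, na.rm = TRUE),
      n_experiments = sum(!is.na(.data$p_wilcoxon)), .groups = "drop"
    )
  structure(
    list(
      normality = normality, variance = variance, omnibus = omnibus,
      pairwise = pairwise, pairwise_max_p = pairwise_max_p
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\nKruskal-Wallis per experiment:\n")
  print(x$omnibus)
  cat("Pairwise paired Wilcoxon, max p across experiments:\n")
  print(x$pairwise_max_p)
  invisible(x)
}
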