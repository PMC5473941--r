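# EM population statistics: micrograph-resampling class proportions,
# motor-distance histograms, and orientation summaries.

#' Micrograph resampling plan
#'
#' The resampling scheme draws `micrographs_per_round` micrographs uniformly
#' without replacement per round, removes them from the pool, and repeats
#' for `n_rounds` rounds (defaults 25 x 9); class proportions are computed
#' per round and their mean and SEM reported across rounds.
#'
#' @param micrographs_per_round Micrographs drawn each round (default 25).
#' @param n_rounds Number of rounds (default 9).
#' @param seed Integer seed controlling the draw.
#' @return A list of class `resampling_plan`.
#' @export
resampling_plan <- function(micrographs_per_round = 25, n_rounds = 9, seed = 1L) {
  if (micrographs_per_round < 1 || n_rounds < 1) {
    abort("`micrographs_per_round` and `n_rounds` must be >= 1.")
  }
  structure(
    list(
      micrographs_per_round = as.integer(micrographs_per_round),
      n_rounds = as.integer(n_rounds),
      seed = as.integer(seed)
    ),
    class = "resampling_plan"
  )
}

assign_rounds <- function(micrographs, plan) {
  need <- plan$micrographs_per_round * plan$n_rounds
  if (length(micrographs) < need) {
    abort(sprintf(
      "resampling plan needs at least %d micrographs (%d per round x %d rounds); got %d.",
      need, plan$micrographs_per_round, plan$n_rounds, length(micrographs)
    ))
  }
  withr::with_seed(plan$seed, {
    picked <- sample(micrographs, need, replace = FALSE)
  })
  tibble::tibble(
    round = rep(seq_len(plan$n_rounds), each = plan$micrographs_per_round),
    micrograph_id = picked
  )
}

resample_proportions <- function(records, label_col, plan, micrographs, levels) {
  rounds <- assign_rounds(micrographs, plan)
  per_round <- rounds |>
    dplyr::left_join(
      records |>
        dplyr::count(.data$micrograph_id, .data[[label_col]]) |>
        tidyr::pivot_wider(
          names_from = dplyr::all_of(label_col), values_from = "n",
          values_fill = 0L
        ),
      by = "micrograph_id"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(levels), ~ dplyr::coalesce(.x, 0L)))
  for (lv in setdiff(levels, names(per_round))) per_round[[lv]] <- 0L

  round_stats <- per_round |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(levels), sum, .names = "count_{.col}"),
      n_micrographs = dplyr::n()
    ) |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::starts_with("count_"))))
  props <- round_stats |>
    dplyr::transmute(
      .data$round,
      dplyr::across(dplyr::starts_with("count_"), ~ .x / .data$total,
        .names = "{sub('count_', 'prop_', .col)}"
      )
    )
  summary <- purrr::map_dfr(levels, function(lv) {
    p <- props[[paste0("prop_", lv)]]
    cnt <- round_stats[[paste0("count_", lv)]]
    tibble::tibble(
      label = lv,
      mean_proportion = mean(p),
      sem = if (length(p) > 1) sd(p) / sqrt(length(p)) else 0,
      mean_particles_per_micrograph = mean(cnt / round_stats$n_micrographs)
    )
  })
  list(summary = summary, per_round = dplyr::left_join(round_stats, props, by = "round"),
       rounds = rounds, n_rounds = plan$n_rounds)
}

#' Conformational-class proportions by micrograph resampling
#'
#' Estimates the phi / open / ambiguous population proportions and their
#' SEM: per round, `micrographs_per_round` micrographs are drawn without
#' replacement (never reused across rounds), class counts are summed over
#' the drawn micrographs, and the per-round proportion is class count over
#' total count — ambiguous particles stay in the denominator. The reported
#' mean and SEM are taken across the `n_rounds` per-round proportions.
#'
#' @param records Tibble of particle records with `micrograph_id` and
#'   `class_label` columns.
#' @param plan A [resampling_plan()].
#' @param micrographs Optional full micrograph id pool; defaults to the ids
#'   present in `records` (supply explicitly if zero-particle micrographs
#'   exist).
#' @return A list of class `resampling_summary`: `summary` (tibble `label`,
#'   `mean_proportion`, `sem`, `mean_particles_per_micrograph`),
#'   `per_round`, `rounds` (the round-by-micrograph draw log), `n_rounds`.
#' @export
class_proportions_resampled <- function(records, plan = resampling_plan(),
                                        micrographs = NULL) {
  stopifnot(all(c("micrograph_id", "class_label") %in% names(records)))
  levels <- c("phi", "open", "ambiguous")
  if (!all(records$class_label %in% levels)) {
    abort("`class_label` must be one of 'phi', 'open', 'ambiguous'.")
  }
  micrographs <- micrographs %||% attr(records, "micrographs") %||%
    unique(records$micrograph_id)
  out <- resample_proportions(records, "class_label", plan, micrographs, levels)
  structure(out, class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf("<resampling_summary> %d rounds\n", x$n_rounds))
  print(x$summary)
  invisible(x)
}

#' Inter-motor distance histogram
#'
#' Bins the motor-domain separation of each 2D class into fixed-width
#' intervals (default 2.5 nm) and sums the per-class particle counts in each
#' bin. Bins are left-closed, right-open, `[k*w, (k+1)*w)`, starting at 0; a
#' distance exactly on an edge falls in the upper bin.
#'
#' @param geometries Tibble with `distance_nm` and `particle_count`
#'   (e.g. from [simulate_pair_geometry()]).
#' @param bin_width_nm Bin width, nm (default 2.5).
#' @return Tibble `bin_start_nm`, `bin_end_nm`, `particles`; empty
#'   intermediate bins are included with zero counts.
#' @export
distance_histogram <- function(geometries, bin_width_nm = 2.5) {
  stopifnot(all(c("distance_nm", "particle_count") %in% names(geometries)))
  if (any(geometries$distance_nm < 0)) abort("distances must be nonnegative.")
  if (any(geometries$particle_count < 0)) abort("particle counts must be >= 0.")
  check_positive(bin_width_nm, "bin_width_nm")
  idx <- floor(geometries$distance_nm / bin_width_nm)
  counts <- tapply(geometries$particle_count, idx, sum)
  k <- seq(0, max(idx))
  particles <- rep(0, length(k))
  particles[as.integer(names(counts)) + 1L] <- as.numeric(counts)
  tibble::tibble(
    bin_start_nm = k * bin_width_nm,
    bin_end_nm = (k + 1) * bin_width_nm,
    particles = particles
  )
}

#' Motor-domain orientation summary
#'
#' Pools particle counts over all records to estimate the proportions of
#' inverted, parallel, and ambiguous stalk orientations. When a
#' [resampling_plan()] and per-record `micrograph_id` are available, the SEM
#' is estimated with the same without-replacement micrograph resampling
#' scheme as [class_proportions_resampled()]; otherwise pooled proportions
#' are returned with multinomial standard errors.
#'
#' @param records Tibble with `orientation_label` and either
#'   `particle_count` (class-level records) or one row per particle.
#' @param plan Optional [resampling_plan()] (requires `micrograph_id`).
#' @return Tibble `label`, `proportion`, `sem`, `n_particles` (pooled mode),
#'   or a `resampling_summary` (resampled mode).
#' @export
orientation_summary <- function(records, plan = NULL) {
  stopifnot("orientation_label" %in% names(records))
  levels <- c("inverted", "parallel", "ambiguous")
  if (nrow(records) == 0) abort("no orientation-labelled records supplied.")
  if (!all(records$orientation_label %in% levels)) {
    abort("`orientation_label` must be one of 'inverted', 'parallel', 'ambiguous'.")
  }
  if (!is.null(plan)) {
    if (!"micrograph_id" %in% names(records)) {
      abort("resampled orientation SEM requires a `micrograph_id` column.")
    }
    out <- resample_proportions(
      records, "orientation_label", plan,
      unique(records$micrograph_id), levels
    )
    return(structure(out, class = "resampling_summary"))
  }
  w <- if ("particle_count" %in% names(records)) records$particle_count else rep(1, nrow(records))
  total <- sum(w)
  purrr::map_dfr(levels, function(lv) {
    n <- sum(w[records$orientation_label == lv])
    p <- n / total
    tibble::tibble(
      label = lv, proportion = p,
      sem = sqrt(p * (1 - p) / total), n_particles = n
    )
  })
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Classify a motor pair's stalk orientation
#'
#' Geometric surrogate for visual orientation assignment: given the stalk
#' direction vector of each motor domain and the inter-motor axis (from
#' motor A to motor B), the pair is `inverted` when each stalk points toward
#' the opposite motor within `angle_tol_deg`, `parallel` when the two stalk
#' vectors are mutually aligned within the tolerance, and `ambiguous`
#' otherwise.
#'
#' @param stalk_a,stalk_b Numeric length-2 stalk direction vectors (nonzero).
#' @param inter_motor_axis Vector from motor A to motor B (nonzero).
#' @param angle_tol_deg Angular tolerance, degrees (default 20).
#' @return `"inverted"`, `"parallel"`, or `"ambiguous"`.
#' @export
classify_pair_orientation <- function(stalk_a, stalk_b, inter_motor_axis,
                                      angle_tol_deg = 20) {
  if (sum(stalk_a^2) == 0 || sum(stalk_b^2) == 0 || sum(inter_motor_axis^2) == 0) {
    abort("stalk and axis vectors must be nonzero.")
  }
  toward_b <- angle_deg(stalk_a, inter_motor_axis) <= angle_tol_deg
  toward_a <- angle_deg(stalk_b, -inter_motor_axis) <= angle_tol_deg
  if (toward_b && toward_a) return("inverted")
  if (angle_deg(stalk_a, stalk_b) <= angle_tol_deg) return("parallel")
  "ambiguous"
}
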