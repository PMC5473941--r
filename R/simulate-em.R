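# Synthetic negative-stain / cryo-EM quantification inputs: per-micrograph
# particle class labels and motor-pair geometries.

#' Simulate a per-micrograph particle population
#'
#' Emulates the per-micrograph class-assignment tables behind conformational
#' population counts: the particle count on each micrograph is Poisson with
#' mean `mean_particles_per_micrograph`, and each particle's conformational
#' label (phi / open / ambiguous) is multinomial with probabilities
#' `class_probs`. The default probabilities reflect a wild-type dynein
#' preparation in which roughly three quarters of molecules are in the
#' auto-inhibited phi form.
#'
#' @param n_micrographs Number of micrographs (>= 1).
#' @param mean_particles_per_micrograph Poisson mean particle count.
#' @param class_probs Named numeric vector of probabilities for
#'   `phi`, `open`, `ambiguous`; must sum to 1.
#' @param seed Integer seed.
#' @return A tibble of `ParticleRecord`s with columns `micrograph_id`,
#'   `particle_id`, `class_label`. Attribute `micrographs` carries the full
#'   micrograph id universe (including zero-particle micrographs); attribute
#'   `truth` the generating probabilities.
#' @export
simulate_particle_population <- function(n_micrographs,
                                         mean_particles_per_micrograph = 40,
                                         class_probs = c(phi = 0.75, open = 0.22, ambiguous = 0.03),
                                         seed = 1L) {
  if (n_micrographs < 1) abort("`n_micrographs` must be >= 1.")
  check_positive(mean_particles_per_micrograph, "mean_particles_per_micrograph")
  check_prob_vector(class_probs, "class_probs")
  labels <- names(class_probs) %||% c("phi", "open", "ambiguous")

  withr::with_seed(as.integer(seed), {
    counts <- rpois(n_micrographs, mean_particles_per_micrograph)
    ids <- sprintf("mic%04d", seq_len(n_micrographs))
    out <- tibble::tibble(
      micrograph_id = rep(ids, counts),
      particle_id = sequence(counts),
      class_label = sample(labels, sum(counts), replace = TRUE, prob = class_probs)
    )
  })
  attr(out, "micrographs") <- ids
  attr(out, "truth") <- list(class_probs = class_probs)
  out
}

#' Simulate motor-pair geometries for 2D classes
#'
#' Emits one motor-domain center pair per 2D class: the inter-motor distance
#' is uniform on `distance_range_nm`, the per-class particle count is Poisson
#' with mean `mean_particles_per_class`, and the stalk-orientation label
#' (inverted / parallel / ambiguous) is multinomial with
#' `orientation_probs`. Defaults model spontaneously open dynein, whose
#' motor separation spans roughly 10-45 nm and whose stalks predominantly
#' point toward each other; `state = "ddb"` switches to the tighter 15-25 nm
#' range and parallel-dominated orientations of the dynein-dynactin-BICD2N
#' complex.
#'
#' @param state `"open"` or `"ddb"`; selects default ranges and orientation
#'   probabilities.
#' @param n_classes Number of 2D classes.
#' @param mean_particles_per_class Poisson mean particles per class.
#' @param distance_range_nm Length-2 vector `(min, max)`, nm; may be
#'   degenerate (`min == max`) but not reversed.
#' @param orientation_probs Named probabilities for `inverted`, `parallel`,
#'   `ambiguous`; sums to 1.
#' @param seed Integer seed.
#' @return A tibble of `MotorPairGeometry` rows: `class_id`,
#'   `particle_count`, `ax`, `ay`, `bx`, `by` (motor centers, nm),
#'   `distance_nm`, `orientation_label`; attribute `truth` holds the
#'   generating parameters.
#' @export
simulate_pair_geometry <- function(state = c("open", "ddb"),
                                   n_classes = 100,
                                   mean_particles_per_class = 100,
                                   distance_range_nm = NULL,
                                   orientation_probs = NULL,
                                   seed = 1L) {
  state <- match.arg(state)
  distance_range_nm <- distance_range_nm %||%
    if (state == "open") c(10, 45) else c(15, 25)
  orientation_probs <- orientation_probs %||%
    if (state == "open") {
      c(inverted = 0.52, parallel = 0.15, ambiguous = 0.33)
    } else {
      c(inverted = 0.04, parallel = 0.47, ambiguous = 0.49)
    }
  if (length(distance_range_nm) != 2 || any(distance_range_nm <= 0) ||
      diff(distance_range_nm) < 0) {
    abort("`distance_range_nm` must be positive and ordered (min <= max).")
  }
  check_prob_vector(orientation_probs, "orientation_probs")
  if (n_classes < 1) abort("`n_classes` must be >= 1.")

  withr::with_seed(as.integer(seed), {
    d <- runif(n_classes, distance_range_nm[1], distance_range_nm[2])
    theta <- runif(n_classes, 0, 2 * pi)
    out <- tibble::tibble(
      class_id = seq_len(n_classes),
      particle_count = rpois(n_classes, mean_particles_per_class),
      ax = 0, ay = 0,
      bx = d * cos(theta), by = d * sin(theta),
      distance_nm = sqrt(.data$bx^2 + .data$by^2),
      orientation_label = sample(names(orientation_probs), n_classes,
        replace = TRUE, prob = orientation_probs
      )
    )
  })
  attr(out, "truth") <- list(
    state = state, distance_range_nm = distance_range_nm,
    orientation_probs = orientation_probs
  )
  out
}
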