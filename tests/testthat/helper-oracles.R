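# Independent brute-force oracles. Each recomputes a quantity with plain
# loops and first principles, never calling the implementation under test.

oracle_survival <- function(dwells, grid) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    n_at_least <- 0
    for (d in dwells) if (d >= grid[i] - 1e-12) n_at_least <- n_at_least + 1
    out[i] <- 100 * n_at_least / length(dwells)
  }
  out
}

oracle_processive <- function(time_s, position_um, min_dur, min_disp_nm, rev_tol_um) {
  o <- order(time_s)
  time_s <- time_s[o]; position_um <- position_um[o]
  dur <- time_s[length(time_s)] - time_s[1]
  net <- position_um[length(position_um)] - position_um[1]
  dir <- if (net >= 0) 1 else -1
  max_rev <- 0
  run_max <- -Inf
  for (p in position_um * dir) {
    run_max <- max(run_max, p)
    max_rev <- max(max_rev, run_max - p)
  }
  dur > min_dur && abs(net) * 1000 > min_disp_nm && max_rev <= rev_tol_um
}

oracle_roi <- function(image, y, x, size, statistic = "mean") {
  start_y <- y - floor((size - 1) / 2)
  start_x <- x - floor((size - 1) / 2)
  acc <- c()
  for (i in start_y:(start_y + size - 1)) {
    for (j in start_x:(start_x + size - 1)) acc <- c(acc, image[i, j])
  }
  if (statistic == "mean") mean(acc) else sum(acc)
}

oracle_sum_projection <- function(arr, center_z, n_slices) {
  half <- (n_slices - 1) / 2
  out <- matrix(0, dim(arr)[2], dim(arr)[3])
  for (y in seq_len(dim(arr)[2])) {
    for (x in seq_len(dim(arr)[3])) {
      s <- 0
      for (z in (center_z - half):(center_z + half)) s <- s + arr[z, y, x]
      out[y, x] <- s
    }
  }
  out
}

oracle_histogram <- function(distances, counts, w) {
  k_max <- max(floor(distances / w))
  out <- numeric(k_max + 1)
  for (i in seq_along(distances)) {
    k <- floor(distances[i] / w)
    out[k + 1] <- out[k + 1] + counts[i]
  }
  out
}

random_track <- function(n = NULL) {
  n <- n %||% sample(2:30, 1)
  tibble::tibble(
    track_id = "t1",
    time_s = (seq_len(n) - 1) * 0.125,
    position_um = cumsum(rnorm(n, mean = sample(c(-0.08, 0, 0.08), 1), sd = 0.05))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
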