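#' Collision-angle events between particle pairs
#'
#' An encounter is the first recorded frame at which a pair's distance
#' drops below `encounter_distance`.  The incoming angle `theta_in` is the
#' angle between the two particles' displacement vectors over the
#' `lookback` recorded frames ending at the encounter; `theta_out` is the
#' same over the `lookahead` frames after it.  Both are reported in degrees
#' on `[0, 180]`, together with nematically folded versions
#' (`min(theta, 180 - theta)` on `[0, 90]`), since for gliding filaments
#' parallel and antiparallel alignment are mechanically equivalent.
#' Encounters whose windows fall outside the movie, or where a particle did
#' not move over a window, are skipped with a message.
#'
#' @param x A `swarm_trajectory` or long frame table with stable particle
#'   ids.
#' @param encounter_distance Distance threshold defining an encounter.
#' @param lookback,lookahead Window lengths in recorded frames.
#' @return A tibble `id_a`, `id_b`, `step`, `theta_in`, `theta_out`,
#'   `theta_in_folded`, `theta_out_folded`.
#' @export
collision_events <- function(x, encounter_distance = 0.2,
                             lookback = 10, lookahead = 10) {
  df <- swarm_frames(x)
  steps <- sort(unique(df$step))
  ids <- sort(unique(df$id))
  n <- length(ids); nt <- length(steps)
  X <- matrix(NA_real_, n, nt); Y <- matrix(NA_real_, n, nt)
  ii <- match(df$id, ids); tt <- match(df$step, steps)
  X[cbind(ii, tt)] <- df$x
  Y[cbind(ii, tt)] <- df$y
  if (anyNA(X)) abort("every particle must appear in every frame")

  npair <- n * (n - 1) / 2
  first_seen <- rep(NA_integer_, npair)
  pk <- function(i, j) (i - 1L) * n - i * (i + 1L) %/% 2L + j  # i < j
  for (t in seq_len(nt)) {
    d <- as.matrix(stats::dist(cbind(X[, t], Y[, t])))
    close <- which(d < encounter_distance & upper.tri(d), arr.ind = TRUE)
    if (nrow(close) > 0) {
      keys <- pk(close[, 1], close[, 2])
      new <- is.na(first_seen[keys])
      first_seen[keys[new]] <- t
    }
  }
  hit <- which(!is.na(first_seen))
  if (length(hit) == 0) return(empty_collisions())

  # decode pair keys
  res <- list(); skipped <- 0L
  for (k in hit) {
    i <- 1L
    while (pk(i, n) < k) i <- i + 1L
    j <- k - pk(i, i + 1L) + i + 1L
    t0 <- first_seen[k]
    if (t0 - lookback < 1 || t0 + lookahead > nt) { skipped <- skipped + 1L; next }
    va <- c(X[i, t0] - X[i, t0 - lookback], Y[i, t0] - Y[i, t0 - lookback])
    vb <- c(X[j, t0] - X[j, t0 - lookback], Y[j, t0] - Y[j, t0 - lookback])
    wa <- c(X[i, t0 + lookahead] - X[i, t0], Y[i, t0 + lookahead] - Y[i, t0])
    wb <- c(X[j, t0 + lookahead] - X[j, t0], Y[j, t0 + lookahead] - Y[j, t0])
    tin <- angle_between(va, vb); tout <- angle_between(wa, wb)
    if (is.na(tin) || is.na(tout)) { skipped <- skipped + 1L; next }
    res[[length(res) + 1L]] <- tibble::tibble(
      id_a = ids[i], id_b = ids[j], step = steps[t0],
      theta_in = tin, theta_out = tout,
      theta_in_folded = min(tin, 180 - tin),
      theta_out_folded = min(tout, 180 - tout))
  }
  if (skipped > 0) {
    inform(sprintf("collision_events: skipped %d encounter(s) with windows outside the movie or zero displacement", skipped))
  }
  if (length(res) == 0) return(empty_collisions())
  dplyr::bind_rows(res)
}

angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  cs <- sum(a * b) / (na * nb)
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

empty_collisions <- function() {
  tibble::tibble(id_a = integer(), id_b = integer(), step = integer(),
                 theta_in = numeric(), theta_out = numeric(),
                 theta_in_folded = numeric(), theta_out_folded = numeric())
}
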