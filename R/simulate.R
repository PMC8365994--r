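#' Initialise a condensed inoculum of gliding particles
#'
#' Particles are placed uniformly at random on a disk centred at the origin,
#' emulating a drop of cell suspension inoculated on an unbounded surface.
#' Headings are uniform on `[0, 2*pi)`; rotation rates are drawn from the
#' stationary distribution `N(omega0, sigma_omega)` so early dynamics are not
#' dominated by a rotation-rate transient (`omega_init = "cold"` starts every
#' particle exactly at `omega0` instead).
#'
#' @param params A [swarm_params()] object.
#' @param n Number of particles (`>= 1`).
#' @param radius Inoculum disk radius (model length units, `> 0`).
#'   Defaults to five interaction ranges.
#' @param seed Optional integer seed; the same seed reproduces the state
#'   bit for bit.
#' @param omega_init `"stationary"` (default) or `"cold"`.
#' @return A tibble with columns `id`, `x`, `y`, `theta`, `omega` and a
#'   `step` attribute equal to 0.
#' @examples
#' s0 <- init_swarm(swarm_params(), n = 50, radius = 5, seed = 1)
#' max(sqrt(s0$x^2 + s0$y^2)) <= 5
#' @export
init_swarm <- function(params = swarm_params(), n = 1000,
                       radius = 5 * params$l, seed = NULL,
                       omega_init = c("stationary", "cold")) {
  stopifnot(inherits(params, "swarm_params"))
  omega_init <- match.arg(omega_init)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive particle count")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be > 0")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  omega <- if (omega_init == "stationary") {
    rnorm(n, params$omega0, params$sigma_omega)
  } else {
    rep(params$omega0, n)
  }
  st <- tibble::tibble(
    id = seq_len(n),
    x = r * cos(a), y = r * sin(a),
    theta = runif(n, 0, 2 * pi),
    omega = omega
  )
  attr(st, "step") <- 0L
  st
}

#' Neighbour bands of a swarm state
#'
#' Classifies every interacting pair by Euclidean distance on the unbounded
#' plane: *repulsive* if `r_ij < r_rep`, *annulus* (alignment + attraction)
#' if `r_rep < r_ij < l`.  The inequalities are strict: a pair exactly on a
#' band boundary interacts in neither band.  Coincident pairs
#' (`r_ij < 1e-9`) get a deterministic pseudo-random unit direction derived
#' from their indices and are treated as repulsive.
#'
#' @param state A swarm state tibble (columns `id`, `x`, `y`, `theta`,
#'   `omega`).
#' @param params A [swarm_params()] object.
#' @return A list of class `neighbor_sets` with elements `pairs` (tibble
#'   `i`, `j`, `r_ij`, `ex`, `ey`, `band`, both orientations, `ex`/`ey` the
#'   unit vector from `i` toward `j`) and `n_annulus` (integer vector, the
#'   annulus neighbour count `N_i` per particle).
#' @examples
#' s <- tibble::tibble(id = 1:2, x = c(0, 0.5), y = 0, theta = 0, omega = 0)
#' neighbor_sets(s, swarm_params())$n_annulus
#' @export
neighbor_sets <- function(state, params = swarm_params()) {
  check_state(state)
  pr <- tibble::as_tibble(
    neighbor_pairs_cpp(state$x, state$y, params$r_rep, params$l)
  )
  # mirror: e_ji = -e_ij
  pairs <- dplyr::bind_rows(
    pr,
    dplyr::mutate(pr, tmp = .data$i, i = .data$j, j = .data$tmp,
                  ex = -.data$ex, ey = -.data$ey, tmp = NULL)
  )
  pairs$band <- c("repulsive", "annulus")[pairs$band]
  pairs <- dplyr::arrange(pairs, .data$i, .data$j)
  n_ann <- integer(nrow(state))
  ann <- pairs[pairs$band == "annulus", ]
  if (nrow(ann) > 0) {
    tb <- table(factor(ann$i, levels = seq_len(nrow(state))))
    n_ann <- as.integer(tb)
  }
  structure(list(pairs = pairs, n_annulus = n_ann),
            class = "neighbor_sets")
}

check_state <- function(state) {
  need <- c("id", "x", "y", "theta", "omega")
  miss <- setdiff(need, names(state))
  if (length(miss) > 0) {
    abort(paste0("state is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(state) < 1) abort("state must contain at least one particle")
  num <- unlist(state[c("x", "y", "theta", "omega")], use.names = FALSE)
  if (!all(is.finite(num))) abort("state contains non-finite values")
  invisible(state)
}

#' Ornstein-Uhlenbeck rotation-rate update
#'
#' One step of the discrete mean-reverting rotation-rate process,
#' `omega' = omega - (omega - omega0)/tau + sqrt(2/tau) * sigma_omega * xi`,
#' applied elementwise.  Its stationary mean is `omega0` and its stationary
#' variance is `sigma_omega^2 * 2*tau/(2*tau - 1)`.
#'
#' @param omega Numeric vector of current rotation rates.
#' @param params A [swarm_params()] object.
#' @param xi Standard-normal draws, same length as `omega`.
#' @return The updated rotation rates.
#' @export
ou_update <- function(omega, params, xi) {
  if (length(omega) != length(xi)) abort("`omega` and `xi` lengths differ")
  if (!all(is.finite(omega)) || !all(is.finite(xi))) {
    abort("non-finite rotation rates or noise draws")
  }
  omega - (omega - params$omega0) / params$tau +
    sqrt(2 / params$tau) * params$sigma_omega * xi
}

#' Nematic heading update
#'
#' `theta' = theta + omega' + (align_gain / N_i) * sum sin 2(theta_j - theta_i)`
#' over annulus neighbours, with the alignment sum defined as 0 when a
#' particle has no annulus neighbours.  All neighbour headings are
#' previous-step values (synchronous update).  Returned headings are wrapped
#' to `[0, 2*pi)`.
#'
#' @param state Swarm state tibble at time t.
#' @param nbrs [neighbor_sets()] computed from the same state.
#' @param omega_new Updated rotation rates (time t+1).
#' @param params A [swarm_params()] object.
#' @return Numeric vector of updated headings.
#' @export
heading_update <- function(state, nbrs, omega_new, params) {
  check_state(state)
  n <- nrow(state)
  ann <- nbrs$pairs[nbrs$pairs$band == "annulus", ]
  align <- numeric(n)
  if (nrow(ann) > 0) {
    s <- sin(2 * (state$theta[ann$j] - state$theta[ann$i]))
    agg <- rowsum(s, ann$i)
    idx <- as.integer(rownames(agg))
    align[idx] <- agg[, 1] * params$align_gain / nbrs$n_annulus[idx]
  }
  (state$theta + omega_new + align) %% (2 * pi)
}

#' Position update with self-propulsion and pairwise forces
#'
#' `r' = r + v0 * e(theta') + v0 * sum_rep k_rep (r_ij - r_rep) e_ij +
#' (v0 / N_i) * sum_ann (k_att / r_ij) e_ij`.  Since `e_ij` points from `i`
#' toward `j`, the repulsive factor (negative inside `r_rep`) pushes `i`
#' away from `j` and the attraction pulls it toward `j`; the attraction sum
#' is 0 when `N_i = 0`.
#'
#' @param state Swarm state tibble at time t.
#' @param nbrs [neighbor_sets()] computed from the same state.
#' @param theta_new Updated headings (time t+1).
#' @param params A [swarm_params()] object.
#' @return A two-column matrix of updated positions.
#' @export
position_update <- function(state, nbrs, theta_new, params) {
  check_state(state)
  n <- nrow(state)
  fx <- numeric(n); fy <- numeric(n)
  rep_p <- nbrs$pairs[nbrs$pairs$band == "repulsive", ]
  if (nrow(rep_p) > 0) {
    f <- params$k_rep * (rep_p$r_ij - params$r_rep)
    agx <- rowsum(f * rep_p$ex, rep_p$i)
    agy <- rowsum(f * rep_p$ey, rep_p$i)
    idx <- as.integer(rownames(agx))
    fx[idx] <- fx[idx] + agx[, 1]
    fy[idx] <- fy[idx] + agy[, 1]
  }
  ann <- nbrs$pairs[nbrs$pairs$band == "annulus", ]
  if (nrow(ann) > 0) {
    fa <- params$k_att / ann$r_ij
    agx <- rowsum(fa * ann$ex, ann$i)
    agy <- rowsum(fa * ann$ey, ann$i)
    idx <- as.integer(rownames(agx))
    fx[idx] <- fx[idx] + agx[, 1] / nbrs$n_annulus[idx]
    fy[idx] <- fy[idx] + agy[, 1] / nbrs$n_annulus[idx]
  }
  cbind(x = state$x + params$v0 * (cos(theta_new) + fx),
        y = state$y + params$v0 * (sin(theta_new) + fy))
}

#' Advance the swarm by one step
#'
#' Synchronous update in fixed order: neighbour bands from positions at t,
#' then the rotation-rate update (with fresh standard-normal draws in
#' particle-index order), then headings using the *new* rotation rates and
#' *old* neighbour headings, then positions using the new headings and
#' forces evaluated at the old positions.
#'
#' @param state Swarm state tibble.
#' @param params A [swarm_params()] object.
#' @param xi Optional per-particle standard-normal draws; drawn from the
#'   current RNG stream when omitted.
#' @return The successor state (step attribute incremented).
#' @examples
#' p <- swarm_params(omega0 = 0, sigma_omega = 0)
#' s <- tibble::tibble(id = 1L, x = 0, y = 0, theta = 0, omega = 0)
#' swarm_step(s, p)[, c("x", "y")]  # moves by exactly v0 along +x
#' @export
swarm_step <- function(state, params = swarm_params(), xi = NULL) {
  check_state(state)
  n <- nrow(state)
  if (is.null(xi)) xi <- rnorm(n)
  if (length(xi) != n) abort("`xi` must have one draw per particle")
  res <- swarm_step_cpp(state$x, state$y, state$theta, state$omega, xi,
                        params$v0, params$l, params$r_rep, params$omega0,
                        params$sigma_omega, params$tau, params$k_rep,
                        params$k_att, params$align_gain)
  out <- tibble::tibble(id = state$id, x = res$x, y = res$y,
                        theta = res$theta, omega = res$omega)
  step0 <- attr(state, "step")
  attr(out, "step") <- if (is.null(step0)) 1L else step0 + 1L
  out
}

#' Run a seeded swarm simulation
#'
#' Iterates [swarm_step()] from a condensed inoculum (or a supplied initial
#' state) and records frames every `record_stride` steps, always including
#' step 0 and the final step.  All randomness flows from `seed`, so the same
#' configuration and seed reproduce the trajectory exactly.
#'
#' @inheritParams init_swarm
#' @param n_steps Number of steps to simulate (`>= 0`).  The published
#'   simulations run 2000 steps.
#' @param record_stride Steps between recorded frames.
#' @param state0 Optional initial state tibble (overrides `n`, `radius`,
#'   `omega_init`).
#' @return A `swarm_trajectory`: list with `frames` (tibble `step`, `id`,
#'   `x`, `y`, `theta`, `omega`), `params`, `seed`, `record_stride`, `n`,
#'   `radius`.
#' @examples
#' tr <- run_swarm(swarm_params(), n = 30, radius = 2, n_steps = 50,
#'                 record_stride = 10, seed = 1)
#' unique(tr$frames$step)
#' @export
run_swarm <- function(params = swarm_params(), n = 1000,
                      radius = 5 * params$l, n_steps = 2000,
                      record_stride = 10, seed = NULL, state0 = NULL,
                      omega_init = c("stationary", "cold")) {
  stopifnot(inherits(params, "swarm_params"))
  if (n_steps < 0) abort("`n_steps` must be >= 0")
  if (record_stride < 1) abort("`record_stride` must be >= 1")
  omega_init <- match.arg(omega_init)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0)) {
    state0 <- init_swarm(params, n = n, radius = radius,
                         omega_init = omega_init)
  } else {
    check_state(state0)
    n <- nrow(state0)
    radius <- NA_real_
  }
  n <- nrow(state0)
  x <- state0$x; y <- state0$y; th <- state0$theta; om <- state0$omega
  rec_steps <- unique(c(seq(0L, n_steps, by = record_stride), n_steps))
  frames <- vector("list", length(rec_steps))
  make_frame <- function(step) {
    tibble::tibble(step = step, id = state0$id, x = x, y = y,
                   theta = th, omega = om)
  }
  k <- 1L
  frames[[k]] <- make_frame(0L)
  if (n_steps > 0) {
    for (t in seq_len(n_steps)) {
      xi <- rnorm(n)
      res <- swarm_step_cpp(x, y, th, om, xi,
                            params$v0, params$l, params$r_rep, params$omega0,
                            params$sigma_omega, params$tau, params$k_rep,
                            params$k_att, params$align_gain)
      x <- res$x; y <- res$y; th <- res$theta; om <- res$omega
      if (t %in% rec_steps) {
        k <- k + 1L
        frames[[k]] <- make_frame(as.integer(t))
      }
    }
  }
  new_swarm_trajectory(
    frames = dplyr::bind_rows(frames[seq_len(k)]),
    params = params, seed = seed, record_stride = as.integer(record_stride),
    n = n, radius = radius
  )
}

new_swarm_trajectory <- function(frames, params, seed, record_stride,
                                 n, radius) {
  structure(list(frames = frames, params = params,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 record_stride = record_stride, n = n, radius = radius),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  steps <- unique(x$frames$step)
  cat(sprintf(
    "<swarm_trajectory> %d particles, %d frames (steps %d..%d, stride %d), seed %s\n",
    x$n, length(steps), min(steps), max(steps), x$record_stride,
    format(x$seed)))
  invisible(x)
}

#' @export
as.data.frame.swarm_trajectory <- function(x, ...) as.data.frame(x$frames)

#' @importFrom tibble as_tibble
#' @export
as_tibble.swarm_trajectory <- function(x, ...) x$frames

#' Coerce to a long frame table
#'
#' Accepts a `swarm_trajectory` or a long data frame with columns `step`,
#' `id`, `x`, `y` (and optionally `theta`, `omega`) and returns the frame
#' tibble.  All analysis functions funnel their input through this.
#'
#' @param x Trajectory object or data frame.
#' @return A tibble of per-particle records ordered by `step` then `id`.
#' @export
swarm_frames <- function(x) {
  if (inherits(x, "swarm_trajectory")) return(x$frames)
  if (!is.data.frame(x)) abort("expected a swarm_trajectory or a data frame")
  miss <- setdiff(c("step", "id", "x", "y"), names(x))
  if (length(miss) > 0) {
    abort(paste0("frame table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  dplyr::arrange(tibble::as_tibble(x), .data$step, .data$id)
}

#' Simulate the rotation-rate process alone
#'
#' Iterates the mean-reverting rotation-rate recursion for a single particle
#' and returns the whole series.  Used for calibration checks of the
#' stationary mean, stationary spread, and correlation time.
#'
#' @param params A [swarm_params()] object.
#' @param n_steps Series length.
#' @param seed Optional integer seed.
#' @param omega_init Starting value; defaults to the process mean `omega0`.
#' @return Numeric vector of `n_steps` successive rotation rates
#'   (the initial value is not included).
#' @examples
#' w <- simulate_rotation_rate(swarm_params(), 1e4, seed = 1)
#' mean(w); sd(w)  # near omega0 and sigma_omega
#' @export
simulate_rotation_rate <- function(params = swarm_params(), n_steps = 1e6,
                                   seed = NULL, omega_init = params$omega0) {
  if (!is.null(seed)) set.seed(seed)
  a <- 1 - 1 / params$tau
  drive <- params$omega0 / params$tau +
    sqrt(2 / params$tau) * params$sigma_omega * rnorm(n_steps)
  as.numeric(stats::filter(drive, a, method = "recursive", init = omega_init))
}
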