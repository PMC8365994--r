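#' Model parameters for the gliding-filament swarm
#'
#' Bundles the constants of the self-propelled particle model: each particle
#' glides at mean speed `v0` in the direction of its heading, the heading
#' drifts with an individual rotation rate that follows a discrete
#' Ornstein-Uhlenbeck process (mean `omega0`, stationary spread close to
#' `sigma_omega`, memory `tau` steps), headings of annulus neighbours
#' (`r_rep < r < l`) couple nematically (through `sin 2(theta_j - theta_i)`,
#' so parallel and antiparallel are equivalent), and neighbours exert a
#' short-range linear repulsion (inside `r_rep`) or a `1/r` attraction
#' (in the annulus).  All quantities are dimensionless model units.
#'
#' The defaults are the published constants for *Pseudanabaena* collective
#' gliding: `v0 = 0.1`, `l = 1`, `r_rep = 0.2`, `omega0 = 5e-4`,
#' `sigma_omega = 0.2`, `tau = 500`, `k_rep = 10`, `k_att = 0.1`.
#'
#' @param v0 Mean gliding speed (length units per step).  Must be positive.
#' @param l Interaction range, the "filament length" (length units).
#' @param r_rep Repulsion range; must satisfy `0 < r_rep < l`.
#' @param omega0 Mean rotation rate (radians per step).  A nonzero value
#'   biases every particle toward circling with radius roughly `v0/omega0`.
#' @param sigma_omega Rotation-rate noise scale (radians per step), `>= 0`.
#' @param tau Rotation-rate correlation time in steps, `> 1`.
#' @param k_rep Repulsion coefficient, `>= 0`.
#' @param k_att Attraction coefficient, `>= 0`.
#' @param align_gain Multiplier on the nematic alignment sum.  The model as
#'   published has unit coupling; this knob exists for exploration only and
#'   defaults to `1`.
#'
#' @return An object of class `swarm_params` (a named list).
#' @examples
#' p <- swarm_params()
#' p$v0
#' swarm_params(omega0 = 0, sigma_omega = 0)  # noise-free straight glider
#' @export
swarm_params <- function(v0 = 0.1, l = 1.0, r_rep = 0.2, omega0 = 5e-4,
                         sigma_omega = 0.2, tau = 500, k_rep = 10,
                         k_att = 0.1, align_gain = 1.0) {
  p <- list(v0 = v0, l = l, r_rep = r_rep, omega0 = omega0,
            sigma_omega = sigma_omega, tau = tau, k_rep = k_rep,
            k_att = k_att, align_gain = align_gain)
  validate_swarm_params(p)
  structure(p, class = "swarm_params")
}

validate_swarm_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) {
      abort(sprintf("parameter `%s` must be a single finite number", nm))
    }
  }
  if (p$v0 <= 0) abort("`v0` must be > 0")
  if (p$r_rep <= 0 || p$r_rep >= p$l) abort("`r_rep` must satisfy 0 < r_rep < l")
  if (p$tau <= 1) abort("`tau` must be > 1")
  if (p$sigma_omega < 0) abort("`sigma_omega` must be >= 0")
  if (p$k_rep < 0) abort("`k_rep` must be >= 0")
  if (p$k_att < 0) abort("`k_att` must be >= 0")
  invisible(p)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("<swarm_params>\n")
  cat(sprintf("  speed v0=%g  ranges r_rep=%g < l=%g\n", x$v0, x$r_rep, x$l))
  cat(sprintf("  rotation omega0=%g sd=%g tau=%g\n",
              x$omega0, x$sigma_omega, x$tau))
  cat(sprintf("  forces k_rep=%g k_att=%g  align_gain=%g\n",
              x$k_rep, x$k_att, x$align_gain))
  invisible(x)
}

#' @export
as.list.swarm_params <- function(x, ...) unclass(x)
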