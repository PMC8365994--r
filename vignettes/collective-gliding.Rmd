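---
title: "Modelling and measuring collective gliding of filamentous cyanobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring collective gliding of filamentous cyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoswarm)
```

Filamentous cyanobacteria such as *Pseudanabaena* glide on solid surfaces
and self-organise into scattered colonies: dense comet-like clusters that
wander roughly in straight lines, and disk-like clusters whose members
circulate on a closed orbit so the aggregate stays put. `cyanoswarm`
implements a minimal self-propelled particle model that reproduces these
behaviours, together with the measurement machinery used to characterise
them: cluster detection and tracking, occupancy ("passing count") maps,
kymographs, radial speed profiles, collision-angle statistics, particle
image velocimetry (PIV), and heavy-tail inference for cluster-size
distributions.

## The model

Each particle `i` carries a position `r_i`, a heading `theta_i` and an
individual rotation rate `omega_i`. Per time step:

1. **Rotation rate** (discrete Ornstein–Uhlenbeck process):
   `omega' = omega - (omega - omega0)/tau + sqrt(2/tau) * sigma_omega * xi`,
   with `xi` a standard normal draw. The process reverts to the mean rate
   `omega0` with memory `tau` steps; its stationary SD is
   `sigma_omega * sqrt(2 tau / (2 tau - 1))`, i.e. about `1.001 *
   sigma_omega` at the default `tau = 500`. Biologically this encodes the
   observation that a filament's curvature of motion persists over long
   times — the ingredient that lets a bent cluster close into a circular
   orbit.
2. **Heading** (nematic alignment):
   `theta' = theta + omega' + (1/N_i) * sum sin 2(theta_j - theta_i)` over
   the `N_i` neighbours in the annulus `r_rep < r_ij < l`. The `sin 2(.)`
   coupling makes parallel and antiparallel headings equivalent, matching
   how colliding filaments align into bundles regardless of polarity. When
   `N_i = 0` the alignment sum is defined as 0.
3. **Position**:
   `r' = r + v0 e(theta') + v0 * sum_rep k_rep (r_ij - r_rep) e_ij +
   (v0/N_i) * sum_ann (k_att / r_ij) e_ij`, with `e_ij` the unit vector
   from `i` toward `j`. Pairs closer than `r_rep` repel linearly; annulus
   neighbours attract with a `1/r` kernel, normalised by `N_i` so that
   attraction does not grow without bound in dense clusters.

The update is synchronous and runs on an unbounded plane from a condensed
disk-shaped inoculum, emulating a drop of cell suspension at the centre of
a plate. All quantities are dimensionless model units; no mapping to hours
or micrometres is asserted anywhere.

```{r params}
swarm_params()
```

The defaults are the published constants of the model
(`v0 = 0.1`, `l = 1`, `r_rep = 0.2`, `omega0 = 5e-4`, `sigma_omega = 0.2`,
`tau = 500`, `k_rep = 10`, `k_att = 0.1`).

### Design choices the equations leave open

Several details are not pinned down by the printed equations; the package
fixes them as follows and exposes the relevant knobs:

* **Orientation of `e_ij`** — chosen from `i` toward `j`, which makes the
  repulsion term (negative factor inside `r_rep`) push particles apart and
  the attraction term pull them together, consistent with the printed
  signs.
* **Band boundaries** — the band inequalities are strict; a pair exactly at
  `r_rep` or `l` interacts in neither band. This follows the inequalities
  literally; it is a measure-zero event.
* **`N_i = 0`** — both `1/N_i` sums are defined as zero.
* **Update order** — `omega` first, then `theta` using the *new* `omega`
  and the *old* neighbour headings, then `r` using the *new* heading and
  forces evaluated at the *old* positions, matching the time indices in
  the update rules.
* **Alignment gain** — the printed heading rule has unit nematic coupling.
  Under it an isolated pair's angle difference obeys
  `delta -> delta - 2 sin 2 delta`, which does not contract to zero — the
  map overshoots. It is implemented literally; an `align_gain` knob exists
  for exploration and defaults to 1, never silently changed.
* **Particle count and inoculum radius** — not part of the model
  constants; defaults `n = 1000` and `radius = 5 l`, always echoed in run
  metadata.
* **Rotation-rate initialisation** — a stationary draw
  `N(omega0, sigma_omega)` by default so early dynamics are not dominated
  by an `omega` transient; a cold start at `omega0` is available
  (`omega_init = "cold"`).
* **Coincident particles** — pairs closer than 1e-9 get a deterministic
  pseudo-random repulsion direction derived from their indices, so
  degenerate configurations resolve reproducibly.
* **RNG** — one master seed; per-step noise is drawn in particle-index
  order, so a run is reproducible bit for bit from its config.

### What the simulation reproduces, and what it does not

At the default constants a 2000-step, 1000-particle run condenses into
scattered dense clusters, most of which wander; circular orbits occur but
are transient. That matches the qualitative published finding; the model
deliberately omits mucilage (EPS) trail-following, cell growth, filament
elongation and phototaxis, so long-lived rotating disks and
history-dependent speed-ups on old trails are *not* expected from it.
Tests passing on this generator therefore validate the machinery on the
minimal physics only, not those biological effects.

```{r run, eval = FALSE}
tr <- run_swarm(swarm_params(), n = 1000, radius = 5, n_steps = 2000,
                record_stride = 10, seed = 1)
autoplot(tr)
```

## Cluster analytics

Real colonies are segmented from photographs; for point particles the
package uses single-linkage connected components with an inclusive
threshold, default `2 * r_rep` (`detect_clusters()`). Cluster sizes can be
member counts or occupied-cell areas on a grid (`cluster_sizes()`) —
both conventions are supported because image-based colony sizes are areas.

Tracking (`link_tracks()`) matches clusters between consecutive frames by
nearest centroid, processed in descending size order with a `max_jump`
gate; when clusters merge, the continuation follows the nearest (in
practice the larger) parent, matching how large colonies absorb small
ones.

The wandering/rotating distinction is visual in the field; here it is
operationalised (`classify_tracks()`) over a trailing window as

* `straightness` = net centroid displacement / centroid path length, and
* `spin` = mean normalised angular momentum of members about the centroid
  (member displacement relative to the cluster's own translation);

a track point is *rotating* when `straightness < 0.5` and `|spin| > 0.3`,
*wandering* when `straightness >= 0.5`, otherwise unclassified. Both
thresholds and the window are exposed; the defaults classify the two
analytic fixtures (rigid rotation, rigid translation) correctly for any
window of at least 10 points.

`passing_count_map()` binarises occupancy per frame (a cell counts once
per frame no matter how many particles share it), sums over frames and
reports `log10` counts. Never-visited cells are masked (`NA`) rather than
set to 0, because `log10(1) = 0` would collide with once-visited cells.
`kymograph()` projects particles within a half-width of a line segment
into bins, one row per frame, top row first — stationary rotating clusters
appear as vertical traces, passing comets as slanted ones.
`radial_speed_profile()` pairs per-particle speeds with distance from a
centre, the rigid-rotation diagnostic `v(R) = omega R`.

`collision_events()` finds the first frame a pair comes within an
encounter distance and measures the angle between the two displacement
vectors over a lookback window before (incoming) and a lookahead window
after (outgoing), in degrees on [0, 180]. Because parallel and
antiparallel alignment are mechanically equivalent for filaments, folded
angles (`min(theta, 180 - theta)`) are reported alongside; both
conventions are emitted because published outgoing-angle plots can be read
either way (antiparallel co-motion at 180 unfolded or 90 after a
half-fold), and the package does not assert one. The default windows of 10
recorded frames mirror the 10-pixel construction lines used for real
filaments in spirit; an exact correspondence is impossible for point
particles.

## Heavy-tail inference for cluster sizes

Cluster-size distributions are compared against a continuous power law and
a truncated log-normal, both fitted above a lower cut-off `xmin`:

* `fit_power_law()` — for each candidate cut-off (every distinct observed
  value) the tail exponent has the closed-form MLE
  `alpha = 1 + n_tail / sum log(x/xmin)`; the cut-off minimising the
  Kolmogorov–Smirnov distance between tail and fit is selected, ties going
  to the smallest candidate. The continuous (not discrete) form is used
  because colony sizes are image areas; a discrete variant is out of
  scope.
* `fit_lognormal()` — the log-normal conditioned on `x >= xmin`, with
  `(meanlog, sdlog)` from bounded numerical likelihood maximisation
  (L-BFGS-B inside a broad fixed box around the tail's log-moments;
  deterministic settings). The same KS scan selects `xmin`, with the
  candidate set capped at 400 quantile-spaced distinct values to keep the
  scan affordable — the power-law scan remains exhaustive. Near the
  power-law-mimicking limit (`meanlog -> -Inf` with `sdlog` growing in
  step) the likelihood flattens; a boundary solution is accepted there
  because the density is numerically indistinguishable from the limit.
  Whether the published analysis reused the power-law cut-off for the
  log-normal or re-scanned is not stated; both modes are supported
  (`xmin` argument), neither asserted.
* `bootstrap_gof()` — semiparametric bootstrap: each replicate draws tail
  values from the fitted model with probability `n_tail/n` and resamples
  the observed below-cut-off values otherwise, then re-fits with full
  cut-off re-estimation. `p` is the fraction of replicates whose KS
  distance reaches the data's. The conventional rule (reject the family
  when `p < 0.1`) is reported as a flag, never applied automatically.
* `vuong_compare()` — both families re-estimated on the common tail above
  the larger cut-off; the normalised sum of pointwise log-likelihood
  ratios is referred to the standard normal. A positive statistic favours
  the first fit; `p > 0.1` is flagged inconclusive. How differing cut-offs
  should be handled is not specified anywhere; the common-tail-with-refit
  convention used here is the standard one and is recorded in every
  result. Note that on KS-selected tails the truncated log-normal can
  approximate a power law closely, so the test is often honestly
  inconclusive — as it also was for the published simulated cluster sizes.

Degenerate inputs (all tail values equal, fewer than two tail points,
zero spread on the log scale) raise errors naming the problem; the
optimiser's settings and convergence are checked, with non-convergence
reported rather than silently accepted.

```{r fits, eval = FALSE}
sizes <- cluster_sizes(detect_clusters(final_frame, linkage = 0.4))
fp <- fit_power_law(sizes)
fl <- fit_lognormal(sizes)
vuong_compare(fp, fl)
```

## Rasterisation and PIV

`rasterize_frame()` renders a particle field to an image: binary occupancy
or unit-mass Gaussian kernels (the latter gives the smooth sub-pixel
texture PIV needs). `piv_field()` implements windowed cross-correlation
with the published analysis settings as defaults — interrogation window
128 px, vector spacing 64 px, correlation threshold 0.6. The correlation
contract is zero-mean cross-correlation normalised by the overlapping
energy, computed by FFT, peak search within half a window, and a 3-point
Gaussian sub-pixel fit (parabolic fallback where a logarithm is
undefined). Windows below the correlation threshold, or featureless ones,
are masked, never zero-filled. The external plugin used on real movies
does not document its exact normalisation, so numerical identity with it
is not claimed; single-pass correlation (no window deformation) is
sufficient for the displacements of interest here. On synthetic textures
the implementation recovers uniform shifts to better than 0.2 px RMS and
the angular speed of a rigidly rotated raster to within 5% via the
speed-versus-radius slope.

## Problem sizes used in the checks

The package's own verification uses: a single 1e6-step rotation-rate
series (moments and autocorrelation against the closed forms), 2e4-step
single-particle orbits against the chord-geometry radius
`v0 / (2 sin(omega0/2))`, 5000-step two-particle spacing runs,
oracle comparisons at up to 500 particles, tail-fit recovery at 5000
samples over 10 seeds, bootstrap level checks at 50 replicates of
(n = 400, 60 bootstrap draws), and three full 1000-particle, 2000-step
default-scenario runs. These sizes were chosen so the whole suite runs
comfortably on a laptop while leaving the Monte-Carlo error of each check
well inside its assertion.

## Known limitations

* The brute-force `O(n^2)` neighbour loop in compiled code is ample for
  thousands of particles but not for millions; spatial binning would be
  the next step.
* Track linking is greedy and frame-local; long occlusions or splits
  produce new track identities rather than re-identifications.
* Collision events are detected on recorded frames, so very fast
  encounters between recording strides can be missed.
* The wandering/rotating classifier is a deliberately simple
  operationalisation; its thresholds are honest knobs, not fitted
  constants.
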