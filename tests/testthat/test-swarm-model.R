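test_that("default parameters are the published model constants", {
  p <- swarm_params()
  expect_equal(unlist(p[c("v0", "l", "r_rep", "omega0", "sigma_omega",
                          "tau", "k_rep", "k_att")]),
               c(v0 = 0.1, l = 1.0, r_rep = 0.2, omega0 = 0.0005,
                 sigma_omega = 0.2, tau = 500, k_rep = 10, k_att = 0.1))
  expect_equal(p$align_gain, 1.0)
  expect_error(swarm_params(v0 = -1), "v0")
  expect_error(swarm_params(r_rep = 1.5), "r_rep")
  expect_error(swarm_params(tau = 0.5), "tau")
  expect_error(swarm_params(sigma_omega = -0.1), "sigma_omega")
})

test_that("initial inoculum is confined, seeded, and validated", {
  s <- init_swarm(table2, n = 100, radius = 5, seed = 1)
  expect_equal(nrow(s), 100)
  expect_true(all(sqrt(s$x^2 + s$y^2) <= 5))
  expect_true(all(s$theta >= 0 & s$theta < 2 * pi))
  s2 <- init_swarm(table2, n = 100, radius = 5, seed = 1)
  expect_identical(s, s2)
  expect_error(init_swarm(table2, n = 0, radius = 5), "n")
  expect_error(init_swarm(table2, n = 10, radius = 0), "radius")
  cold <- init_swarm(table2, n = 10, radius = 5, seed = 1,
                     omega_init = "cold")
  expect_true(all(cold$omega == table2$omega0))
})

test_that("neighbour bands follow the strict distance definitions", {
  # distance 0.5: mutual annulus neighbours
  nb <- neighbor_sets(make_state(c(0, 0.5), c(0, 0)), table2)
  expect_equal(nb$n_annulus, c(1L, 1L))
  expect_true(all(nb$pairs$band == "annulus"))
  # distance 0.1: mutual repulsive, N = 0
  nb <- neighbor_sets(make_state(c(0, 0.1), c(0, 0)), table2)
  expect_equal(nb$n_annulus, c(0L, 0L))
  expect_true(all(nb$pairs$band == "repulsive"))
  # distance 1.5: no interaction
  nb <- neighbor_sets(make_state(c(0, 1.5), c(0, 0)), table2)
  expect_equal(nrow(nb$pairs), 0L)
  # exactly on a boundary: neither band
  nb <- neighbor_sets(make_state(c(0, table2$r_rep), c(0, 0)), table2)
  expect_equal(nrow(nb$pairs), 0L)
  # e_ij antisymmetry and unit length
  st <- make_state(c(0, 0.3, 0.6), c(0, 0.1, -0.2))
  pr <- neighbor_sets(st, table2)$pairs
  expect_equal(sqrt(pr$ex^2 + pr$ey^2), rep(1, nrow(pr)))
  flip <- dplyr::inner_join(pr, pr, by = c(i = "j", j = "i"))
  expect_equal(flip$ex.x, -flip$ex.y)
  expect_equal(flip$ey.x, -flip$ey.y)
})

test_that("neighbour search agrees with the all-pairs oracle", {
  withr::with_seed(7, {
    for (n in c(50, 200, 500)) {
      st <- make_state(runif(n, 0, 8), runif(n, 0, 8))
      got <- neighbor_sets(st, table2)$pairs
      want <- brute_neighbor_bands(st, table2)
      got <- got[order(got$i, got$j), ]
      want <- want[order(want$i, want$j), ]
      expect_equal(got$i, want$i)
      expect_equal(got$j, want$j)
      expect_equal(got$r_ij, want$r_ij)
      expect_equal(got$band, want$band)
    }
  })
})

test_that("coincident particles get a deterministic repulsive direction", {
  st <- make_state(c(1, 1), c(2, 2))
  nb1 <- neighbor_sets(st, table2)
  nb2 <- neighbor_sets(st, table2)
  expect_identical(nb1$pairs, nb2$pairs)
  expect_true(all(nb1$pairs$band == "repulsive"))
  expect_equal(sqrt(nb1$pairs$ex^2 + nb1$pairs$ey^2), rep(1, 2))
})

test_that("rotation-rate update matches the recursion arithmetic", {
  expect_equal(ou_update(0.1, table2, 0), 0.1 - (0.1 - 0.0005) / 500)
  expect_equal(ou_update(0.0005, table2, 1),
               0.0005 + sqrt(2 / 500) * 0.2, tolerance = 1e-12)
  # fixed point with zero noise amplitude
  p0 <- swarm_params(sigma_omega = 0)
  expect_equal(ou_update(p0$omega0, p0, 1), p0$omega0)
  expect_error(ou_update(c(0.1, NA), table2, c(0, 0)), "finite")
  expect_error(ou_update(0.1, table2, c(0, 0)), "length")
})

test_that("heading update applies nematic alignment with the N=0 contract", {
  s <- make_state(c(0, 0.5), c(0, 0), theta = c(0, pi / 8))
  nb <- neighbor_sets(s, table2)
  expect_equal(heading_update(s, nb, c(0, 0), table2)[1], sin(pi / 4))
  # perpendicular neighbour contributes sin(pi) = 0
  s2 <- make_state(c(0, 0.5), c(0, 0), theta = c(0, pi / 2))
  nb2 <- neighbor_sets(s2, table2)
  expect_equal(heading_update(s2, nb2, c(0, 0), table2)[1], 0)
  # no neighbours: theta advances by omega only
  s3 <- make_state(0, 0, theta = 1)
  nb3 <- neighbor_sets(s3, table2)
  expect_equal(heading_update(s3, nb3, 0.01, table2), 1.01)
})

test_that("position update composes propulsion, repulsion and attraction", {
  # repulsion: j at 0.1 pushes i to (-0.1, 0.1) given theta' = pi/2
  s <- make_state(c(0, 0.1), c(0, 0), theta = c(pi / 2, 0))
  nb <- neighbor_sets(s, table2)
  r <- position_update(s, nb, c(pi / 2, 0), table2)
  expect_equal(unname(r[1, ]), c(-0.1, 0.1), tolerance = 1e-12)
  # attraction: j at 0.5 pulls i to (0.02, 0.1)
  s2 <- make_state(c(0, 0.5), c(0, 0), theta = c(pi / 2, 0))
  nb2 <- neighbor_sets(s2, table2)
  r2 <- position_update(s2, nb2, c(pi / 2, 0), table2)
  expect_equal(unname(r2[1, ]), c(0.02, 0.1), tolerance = 1e-12)
  # isolated particle: pure self-propulsion
  s3 <- make_state(0, 0)
  r3 <- position_update(s3, neighbor_sets(s3, table2), 0, table2)
  expect_equal(unname(r3[1, ]), c(0.1, 0), tolerance = 1e-15)
})

test_that("one compiled step equals the composition of the R updates", {
  withr::with_seed(11, {
    st <- make_state(runif(40, 0, 3), runif(40, 0, 3),
                     theta = runif(40, 0, 2 * pi),
                     omega = rnorm(40, 0, 0.2))
    xi <- rnorm(40)
    nb <- neighbor_sets(st, table2)
    om <- ou_update(st$omega, table2, xi)
    th <- heading_update(st, nb, om, table2)
    # headings wrapped in both routes
    pos <- position_update(st, nb, th, table2)
    got <- swarm_step(st, table2, xi = xi)
    expect_equal(got$omega, om, tolerance = 1e-12)
    expect_equal(got$theta, th, tolerance = 1e-12)
    expect_equal(got$x, unname(pos[, 1]), tolerance = 1e-12)
    expect_equal(got$y, unname(pos[, 2]), tolerance = 1e-12)
  })
})

test_that("a lone noise-free particle self-propels exactly and circles at the closed-form radius", {
  p <- swarm_params(omega0 = 0, sigma_omega = 0)
  st <- make_state(0, 0)
  tr <- run_swarm(p, n_steps = 200, record_stride = 1, state0 = st)
  d <- sqrt(diff(tr$frames$x)^2 + diff(tr$frames$y)^2)
  expect_equal(d, rep(p$v0, 200), tolerance = 1e-14)
  # constant turning: circle of radius v0 / (2 sin(omega0/2))
  p2 <- swarm_params(sigma_omega = 0)          # omega0 = 5e-4
  st2 <- make_state(0, 0, omega = p2$omega0)
  tr2 <- run_swarm(p2, n_steps = 20000, record_stride = 20, state0 = st2)
  r_hat <- fit_circle_radius(tr2$frames$x, tr2$frames$y)
  r_exp <- p2$v0 / (2 * sin(p2$omega0 / 2))
  expect_lt(abs(r_hat / r_exp - 1), 0.01)
})

test_that("rotation-rate process has the stationary moments and memory of the linear recursion", {
  w <- simulate_rotation_rate(table2, n_steps = 2e5, seed = 42)
  sd_stat <- table2$sigma_omega *
    sqrt(2 * table2$tau / (2 * table2$tau - 1))
  # integrated autocorrelation time ~ 2*tau - 1 inflates both standard errors
  se_mean <- sd_stat * sqrt((2 * table2$tau - 1) / length(w))
  expect_lt(abs(mean(w) - table2$omega0), 3 * se_mean)
  se_sd <- sd_stat * sqrt(table2$tau / length(w))
  expect_lt(abs(sd(w) - sd_stat), 3 * se_sd)
  ac <- acf(w, lag.max = 2000, plot = FALSE)$acf[-1]
  fit <- nls(ac ~ exp(-k / tf), data = data.frame(k = 1:2000, ac = ac),
             start = list(tf = table2$tau))
  tau_ref <- -1 / log(1 - 1 / table2$tau)
  expect_lt(abs(coef(fit)[["tf"]] / tau_ref - 1), 0.05)
})

test_that("noise-free dynamics are equivariant under translation and rotation", {
  p <- swarm_params(sigma_omega = 0)
  withr::with_seed(3, {
    st <- make_state(runif(30, 0, 3), runif(30, 0, 3),
                     theta = runif(30, 0, 2 * pi), omega = p$omega0)
  })
  xi <- rep(0, 30)
  base <- st
  for (k in 1:20) base <- swarm_step(base, p, xi = xi)
  # translation
  shifted <- dplyr::mutate(st, x = x + 11, y = y - 4)
  for (k in 1:20) shifted <- swarm_step(shifted, p, xi = xi)
  expect_equal(shifted$x, base$x + 11, tolerance = 1e-9)
  expect_equal(shifted$y, base$y - 4, tolerance = 1e-9)
  # rotation by phi about the origin
  phi <- 0.7
  rot <- rotate_points(st, phi)
  rot$theta <- (st$theta + phi) %% (2 * pi)
  for (k in 1:20) rot <- swarm_step(rot, p, xi = xi)
  base_rot <- rotate_points(base, phi)
  expect_equal(rot$x, base_rot$x, tolerance = 1e-9)
  expect_equal(rot$y, base_rot$y, tolerance = 1e-9)
})

test_that("an aligned pair settles to a mean spacing at the repulsion range", {
  p <- swarm_params(omega0 = 0, sigma_omega = 0)
  st <- make_state(c(0, 0), c(0, 0.5))       # separation perpendicular to motion
  tr <- run_swarm(p, n_steps = 5000, record_stride = 1, state0 = st)
  w <- tidyr::pivot_wider(tr$frames[, c("step", "id", "y")],
                          names_from = "id", values_from = "y")
  sep <- abs(w[["2"]] - w[["1"]])
  expect_lt(abs(mean(tail(sep, 1000)) - p$r_rep), 0.05)
})

test_that("run_swarm records strides, honours n_steps = 0 and is seed-deterministic", {
  tr0 <- run_swarm(table2, n = 5, radius = 1, n_steps = 0, seed = 1)
  expect_equal(unique(tr0$frames$step), 0L)
  tr <- run_swarm(table2, n = 20, radius = 2, n_steps = 55,
                  record_stride = 10, seed = 9)
  expect_equal(unique(tr$frames$step), c(0L, 10L, 20L, 30L, 40L, 50L, 55L))
  tr2 <- run_swarm(table2, n = 20, radius = 2, n_steps = 55,
                   record_stride = 10, seed = 9)
  expect_identical(tr$frames, tr2$frames)
  expect_error(run_swarm(table2, n = 10, n_steps = -1), "n_steps")
})
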