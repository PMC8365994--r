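test_that("single-linkage detection labels chains, singletons and matches the oracle", {
  pts <- make_state(c(0, 0.15, 0.35), c(0, 0, 0))
  expect_equal(detect_clusters(pts, linkage = 0.2)$cluster, c(1L, 1L, 1L))
  pts2 <- make_state(c(0, 0.15, 0.35, 5), c(0, 0, 0, 5))
  lab2 <- detect_clusters(pts2, linkage = 0.2)$cluster
  expect_equal(lab2, c(1L, 1L, 1L, 2L))   # singleton is its own cluster
  # empty input is an empty frame, not an error
  expect_equal(nrow(detect_clusters(make_state(numeric(0), numeric(0)), 0.2)), 0L)
  withr::with_seed(5, {
    for (rep in 1:3) {
      n <- sample(100:500, 1)
      df <- make_state(runif(n, 0, 10), runif(n, 0, 10))
      got <- detect_clusters(df, linkage = 0.3)$cluster
      want <- igraph_components(df$x, df$y, 0.3)
      expect_true(same_partition(got, want))
    }
  })
})

test_that("labels form a partition ordered by size and respect linkage monotonicity", {
  withr::with_seed(8, {
    df <- make_state(runif(200, 0, 6), runif(200, 0, 6))
  })
  lab <- detect_clusters(df, linkage = 0.4)
  sizes <- as.integer(table(lab$cluster))
  expect_equal(sum(sizes), 200L)                    # partition
  expect_true(all(diff(sizes) <= 0))                # descending size order
  n_clusters <- sapply(c(0.1, 0.2, 0.4, 0.8, 1.6),
                       function(L) max(detect_clusters(df, L)$cluster))
  expect_true(all(diff(n_clusters) <= 0))           # monotone in linkage
})

test_that("cluster sizes support count and occupied-cell area modes", {
  one <- detect_clusters(make_state(0.1, 0.1), linkage = 1)
  expect_equal(cluster_sizes(one, "area", cell_size = 0.5), 0.25)
  seven <- detect_clusters(make_state(seq(0, 0.6, by = 0.1), rep(0, 7)),
                           linkage = 0.2)
  expect_equal(cluster_sizes(seven, "count"), 7)
  # occupancy, not multiplicity: two particles in one cell
  two <- detect_clusters(make_state(c(0.1, 0.2), c(0.1, 0.2)), linkage = 1)
  expect_equal(cluster_sizes(two, "area", cell_size = 0.5), 0.25)
  expect_error(cluster_sizes(two, "area"), "cell_size")
})

test_that("track linking follows drifting clusters and terminates lost ones", {
  # one blob drifting 0.5 per frame
  blob <- function(cx, step) {
    tibble::tibble(step = step, id = 1:5, x = cx + c(0, 0.1, -0.1, 0, 0),
                   y = c(0, 0, 0, 0.1, -0.1))
  }
  frames <- dplyr::bind_rows(lapply(0:9, function(k) blob(0.5 * k, k)))
  tk <- link_tracks(detect_clusters(frames, 0.5), max_jump = 2)
  expect_equal(length(unique(tk$track)), 1L)
  expect_equal(nrow(tk), 10L)
  # two distant stationary clusters stay on separate tracks
  two <- dplyr::bind_rows(lapply(0:4, function(k) {
    tibble::tibble(step = k, id = 1:4,
                   x = c(0, 0.1, 10, 10.1), y = 0)
  }))
  tk2 <- link_tracks(detect_clusters(two, 0.5), max_jump = 2)
  expect_equal(length(unique(tk2$track)), 2L)
  by_tr <- split(tk2$cx, tk2$track)
  expect_true(all(vapply(by_tr, function(v) diff(range(v)) < 1e-9, TRUE)))
  # a cluster that disappears mid-movie terminates at its last sighting
  gone <- dplyr::bind_rows(
    lapply(0:4, function(k) tibble::tibble(step = k, id = 1:2, x = c(0, 20), y = 0)),
    lapply(5:8, function(k) tibble::tibble(step = k, id = 1, x = 0, y = 0)))
  tk3 <- link_tracks(detect_clusters(gone, 0.5), max_jump = 2)
  lengths <- table(tk3$track)
  expect_equal(sort(as.integer(lengths)), c(5L, 9L))
})

test_that("centroid speeds use distance over elapsed time", {
  tk <- tibble::tibble(track = 1L, step = c(0, 1), cx = c(0, 3), cy = c(0, 4))
  expect_equal(centroid_speed(tk)$speed, 5)
  expect_equal(centroid_speed(tk, frame_interval = 2)$speed, 2.5)
  still <- tibble::tibble(track = 1L, step = c(0, 1), cx = 1, cy = 1)
  expect_equal(centroid_speed(still)$speed, 0)
  single <- tibble::tibble(track = 1L, step = 0, cx = 0, cy = 0)
  expect_error(centroid_speed(single), "two points")
})

test_that("rigid rotation classifies as rotating and rigid translation as wandering", {
  ring <- function(phase, step) {
    a <- seq(0, 2 * pi, length.out = 13)[-13] + phase
    tibble::tibble(step = step, id = 1:12, x = 2 * cos(a), y = 2 * sin(a))
  }
  rot_frames <- dplyr::bind_rows(lapply(0:30, function(k) ring(0.2 * k, k)))
  blob <- function(cx, step) {
    tibble::tibble(step = step, id = 1:6,
                   x = cx + c(0, 0.1, 0.2, 0, 0.1, 0.2),
                   y = c(0, 0, 0, 0.1, 0.1, 0.1))
  }
  tra_frames <- dplyr::bind_rows(lapply(0:30, function(k) blob(0.4 * k, k)))
  for (win in c(10, 20)) {
    rot <- classify_tracks(link_tracks(detect_clusters(rot_frames, 1.2),
                                       max_jump = 2), window = win)
    expect_true(all(rot$label[rot$label != "unclassified"] == "rotating"))
    expect_true(any(rot$label == "rotating"))
    tra <- classify_tracks(link_tracks(detect_clusters(tra_frames, 0.5),
                                       max_jump = 2), window = win)
    expect_true(all(tra$label[tra$label != "unclassified"] == "wandering"))
    expect_true(any(tra$label == "wandering"))
  }
  # track shorter than the window stays unclassified
  short <- classify_tracks(link_tracks(detect_clusters(
    dplyr::bind_rows(lapply(0:3, function(k) ring(0.2 * k, k))), 1.2),
    max_jump = 2), window = 10)
  expect_true(all(short$label == "unclassified"))
})

test_that("passing-count maps binarise per frame, sum, log-transform and mask", {
  still <- dplyr::bind_rows(lapply(1:100, function(k) {
    tibble::tibble(step = k, id = 1L, x = 0.5, y = 0.5)
  }))
  pc <- passing_count_map(still, cell_size = 1,
                          extent = list(xlim = c(0, 3), ylim = c(0, 3)))
  expect_equal(pc[1, 1], log10(100))
  expect_true(all(is.na(pc[-1])))            # untouched cells masked, not 0
  # ten distinct cells visited once each -> value 0 = log10(1)
  walk <- tibble::tibble(step = 1:10, id = 1L, x = seq(0.5, 9.5, 1), y = 0.5)
  pcw <- passing_count_map(walk, cell_size = 1,
                           extent = list(xlim = c(0, 10), ylim = c(0, 1)))
  expect_equal(sum(pcw == 0, na.rm = TRUE), 10L)
  # binarise-then-sum: two particles sharing a cell count once per frame
  pair <- dplyr::bind_rows(lapply(1:50, function(k) {
    tibble::tibble(step = k, id = 1:2, x = c(0.2, 0.8), y = 0.5)
  }))
  pcp <- passing_count_map(pair, cell_size = 1,
                           extent = list(xlim = c(0, 1), ylim = c(0, 1)))
  expect_equal(attr(pcp, "counts")[1, 1], 50)
  # conservation: total visits never exceed frames x particles
  expect_lte(sum(10^pc, na.rm = TRUE), 100)
  expect_equal(sum(10^pcw, na.rm = TRUE), 10)  # equality for one particle, fresh cells
})

test_that("kymographs trace moving and stationary particles", {
  mover <- tibble::tibble(step = 0:9, id = 1L, x = seq(0.5, 9.5, 1), y = 0)
  km <- kymograph(mover, p0 = c(0, 0), p1 = c(10, 0), half_width = 0.5,
                  bins = 10)
  expect_equal(dim(km), c(10L, 10L))
  expect_equal(diag(unclass(km)), rep(1, 10))      # diagonal ridge
  expect_equal(sum(km), 10)
  fixed <- tibble::tibble(step = 0:9, id = 1L, x = 3.5, y = 0)
  kf <- kymograph(fixed, p0 = c(0, 0), p1 = c(10, 0), half_width = 0.5,
                  bins = 10)
  expect_true(all(kf[, 4] == 1) && sum(kf) == 10)  # vertical trace
  far <- tibble::tibble(step = 0:9, id = 1L, x = 5, y = 3)
  expect_true(all(kymograph(far, c(0, 0), c(10, 0), 0.5, bins = 10) == 0))
  expect_error(kymograph(mover, c(0, 0), c(0, 0)), "distinct")
})

test_that("kymograph of particle frames equals the kymograph of the rasterised stack", {
  withr::with_seed(21, {
    # one particle per occupied cell, so binary occupancy = particle count
    frames <- dplyr::bind_rows(lapply(0:5, function(k) {
      cells <- sample(20 * 4, 30)
      tibble::tibble(step = k, id = 1:30,
                     x = (cells - 1) %% 20 + 0.5,
                     y = (cells - 1) %/% 20 - 2 + 0.5)
    }))
  })
  ext <- list(xlim = c(0, 20), ylim = c(-2, 2))
  stack <- lapply(sort(unique(frames$step)), function(s) {
    rasterize_frame(frames[frames$step == s, ], cell_size = 1, extent = ext,
                    mode = "binary")
  })
  a <- kymograph(frames, p0 = c(0, 0), p1 = c(20, 0), half_width = 2,
                 bins = 20)
  b <- kymograph(stack, p0 = c(0, 0), p1 = c(20, 0), half_width = 2,
                 bins = 20)
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
})

test_that("radial speed profiles recover rigid-body rotation", {
  withr::with_seed(13, {
    r <- sqrt(runif(100, 0, 1)) * 100
    a <- runif(100, 0, 2 * pi)
    df0 <- tibble::tibble(id = 1:100, x = r * cos(a), y = r * sin(a))
  })
  omega <- 0.01
  df1 <- rotate_points(df0, omega)
  prof <- radial_speed_profile(df0, df1, center = c(0, 0), delta = 1)
  # v = 2 sin(omega/2) R ~ omega R; slope of the least-squares line within 1%
  slope <- coef(lm(speed ~ 0 + radius, data = prof))[[1]]
  expect_lt(abs(slope / (2 * sin(omega / 2)) - 1), 0.01)
  expect_lt(abs(slope / omega - 1), 0.01)
  # particle at the centre does not move
  ctr <- radial_speed_profile(tibble::tibble(id = 1, x = 0, y = 0),
                              tibble::tibble(id = 1, x = 0, y = 0))
  expect_equal(ctr$speed, 0)
  # v(R) = omega R at a known radius
  one0 <- tibble::tibble(id = 1, x = 50, y = 0)
  one1 <- rotate_points(one0, omega)
  expect_equal(radial_speed_profile(one0, one1)$speed, 2 * sin(omega / 2) * 50,
               tolerance = 1e-9)
  expect_error(radial_speed_profile(df0, df0[1:10, ]), "match")
})
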