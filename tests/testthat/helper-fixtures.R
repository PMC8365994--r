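# Shared fixtures and independent oracles (deliberately naive versions,
# separate from the implementations they check).

table2 <- swarm_params()

# all-pairs neighbour bands, straight from the band definitions
brute_neighbor_bands <- function(state, params) {
  n <- nrow(state)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((state$x[j] - state$x[i])^2 + (state$y[j] - state$y[i])^2)
    band <- if (d < params$r_rep) "repulsive"
    else if (d > params$r_rep && d < params$l) "annulus"
    else NA_character_
    if (!is.na(band)) {
      out[[length(out) + 1]] <- data.frame(i = i, j = j, r_ij = d, band = band)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), r_ij = numeric(),
                      band = character()))
  }
  do.call(rbind, out)
}

# connected components at threshold via igraph (independent route)
igraph_components <- function(x, y, linkage) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  adj <- (d <= linkage)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# least-squares circle through a point cloud (Kasa fit)
fit_circle_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  co <- qr.solve(A, x^2 + y^2)
  sqrt(co[3] + co[1]^2 + co[2]^2)
}

# rigid rotation of a point set about a centre
rotate_points <- function(df, angle, center = c(0, 0)) {
  rx <- df$x - center[1]; ry <- df$y - center[2]
  dplyr::mutate(df,
                x = center[1] + cos(angle) * rx - sin(angle) * ry,
                y = center[2] + sin(angle) * rx + cos(angle) * ry)
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

make_state <- function(x, y, theta = 0, omega = 0) {
  tibble::tibble(id = seq_along(x), x = x, y = y,
                 theta = rep_len(theta, length(x)),
                 omega = rep_len(omega, length(x)))
}
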